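#' Tirosh-style score from an explicit control assignment
#'
#' For each cell, the mean over retained signature genes of (signature gene
#' expression minus mean control-gene expression). The divisor is the number
#' of retained signature genes.
#'
#' @param x Validated expression matrix (cells x genes).
#' @param sig `gene_signature` or character vector; only genes covered by
#'   `controls$retained` contribute.
#' @param controls A `control_assignment` covering every retained gene.
#' @return Named numeric vector of per-cell scores.
#' @export
score_tirosh <- function(x, sig, controls) {
  sig <- .as_signature(sig)
  retained <- controls$retained
  if (length(retained) == 0L) stop("no retained signature genes to score")
  missing <- setdiff(retained, names(controls$controls))
  if (length(missing)) {
    stop("control assignment lacks control sets for: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  n <- nrow(x)
  total <- numeric(n)
  for (s in retained) {
    ctrl <- controls$controls[[s]]
    ctrl_mean <- Matrix::rowMeans(x[, ctrl, drop = FALSE])
    total <- total + (as.numeric(x[, s]) - ctrl_mean)
  }
  out <- total / length(retained)
  names(out) <- rownames(x)
  out
}

#' Adjusted Neighborhood Scoring of one signature
#'
#' Composition of [exclude_top_expressed()], [controls_ans()] and
#' [score_tirosh()]: highly expressed signature genes are excluded, each
#' remaining gene receives its best-matching expression-neighborhood control
#' window, and the per-cell score is the mean signature-minus-control
#' difference. Deterministic.
#'
#' @inheritParams score_tirosh
#' @param config `control_config` with `strategy = "ans"`.
#' @return List with `scores` (named per-cell vector), `controls` (the
#'   `control_assignment`), and `excluded` (data.frame of excluded genes
#'   with reasons).
#' @export
score_ans <- function(x, sig, config = control_config(strategy = "ans")) {
  sig <- .as_signature(sig)
  ca <- controls_ans(x, sig, config)
  scores <- score_tirosh(x, gene_signature(sig$name, ca$retained), ca)
  list(scores = scores, controls = ca, excluded = ca$excluded)
}

#' UCell rank-based scoring
#'
#' Per cell, all genes are ranked by decreasing expression with averaged
#' ties; ranks beyond `max_rank` are clamped to `max_rank + 1`. With `m`
#' signature genes and rank sum `R`, the Mann-Whitney statistic is
#' `U = R - m(m+1)/2` and the score is `1 - U / (m * max_rank)`, which lies
#' in `[0, 1]`. Scores of a cell depend only on that cell's expression
#' profile, so they are unaffected by which other cells are present.
#'
#' @param x Validated expression matrix.
#' @param sig `gene_signature` or character vector.
#' @param max_rank Rank clamp (default 1500); must be >= signature size.
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
score_ucell <- function(x, sig, max_rank = 1500L) {
  sig <- .as_signature(sig)
  genes <- sig$genes
  m <- length(genes)
  if (m > max_rank) {
    stop("signature size (", m, ") exceeds max_rank (", max_rank, ")")
  }
  xd <- .dense(x)
  sig_idx <- match(genes, colnames(xd))
  if (anyNA(sig_idx)) {
    stop("signature genes absent from matrix: ",
         paste(genes[is.na(sig_idx)][seq_len(min(5L, sum(is.na(sig_idx))))],
               collapse = ", "))
  }
  scores <- apply(xd, 1L, function(row) {
    r <- rank(-row, ties.method = "average")
    r[r > max_rank] <- max_rank + 1
    u <- sum(r[sig_idx]) - m * (m + 1) / 2
    1 - u / (m * max_rank)
  })
  names(scores) <- rownames(x)
  scores
}

#' JASMINE scoring (likelihood or odds-ratio variant)
#'
#' Per cell, two components are computed over the expressed (nonzero)
#' genes: (1) the mean rank of expressed signature genes among all expressed
#' genes (ascending by expression, averaged ties), divided by the number of
#' expressed genes (0 when no signature gene is expressed); and (2) an
#' enrichment value from the per-cell 2x2 expressed/non-expressed x
#' signature/non-signature table, either an odds ratio `a*h / (b*g)` or a
#' likelihood `a*(g+h) / (g*(a+b))`. Both components are min-max normalized
#' to `[0, 1]` across all cells, and the score is their average.
#'
#' Zero-denominator guards: a cell with no expressed signature gene
#' (`a = 0`) gets enrichment 0; a cell whose denominator vanishes while
#' `a > 0` (all signature genes expressed, or no expressed non-signature
#' genes) is assigned the maximum enrichment observed among well-defined
#' cells (message logged). A component constant across all cells min-max
#' normalizes to all zeros, with a warning.
#'
#' @param x Validated expression matrix.
#' @param sig `gene_signature` or character vector.
#' @param mode `"likelihood"` (Jasmine_LH) or `"odds_ratio"` (Jasmine_OR).
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
score_jasmine <- function(x, sig, mode = c("likelihood", "odds_ratio")) {
  mode <- match.arg(mode)
  sig <- .as_signature(sig)
  if (nrow(x) < 2L) stop("JASMINE needs at least 2 cells (min-max normalization)")
  xd <- .dense(x)
  sig_idx <- match(sig$genes, colnames(xd))
  if (anyNA(sig_idx)) {
    stop("signature genes absent from matrix: ",
         paste(sig$genes[is.na(sig_idx)][1L], collapse = ", "))
  }
  m <- length(sig_idx)
  p <- ncol(xd)
  n <- nrow(xd)
  rm_comp <- numeric(n)
  enr <- numeric(n)
  undefined <- logical(n)
  for (j in seq_len(n)) {
    row <- xd[j, ]
    expressed <- row > 0
    n_exp <- sum(expressed)
    a <- sum(expressed[sig_idx])
    b <- m - a
    g <- n_exp - a
    h <- (p - m) - g
    # rank component: ranks among expressed genes, ascending by expression
    if (a > 0L) {
      idx_exp <- which(expressed)
      r <- rank(row[idx_exp], ties.method = "average")
      rm_comp[j] <- mean(r[idx_exp %in% sig_idx]) / n_exp
    } else {
      rm_comp[j] <- 0
    }
    # enrichment component
    if (a == 0L) {
      enr[j] <- 0
    } else if (mode == "odds_ratio") {
      if (b == 0L || g == 0L) undefined[j] <- TRUE
      else enr[j] <- (a * h) / (b * g)
    } else {
      if (g == 0L) undefined[j] <- TRUE
      else enr[j] <- (a * (g + h)) / (g * (a + b))
    }
  }
  if (any(undefined)) {
    mx <- if (all(undefined)) 1 else max(enr[!undefined])
    enr[undefined] <- mx
    message(sum(undefined), " cell(s) had an undefined enrichment denominator; ",
            "assigned the maximum defined enrichment")
  }
  norm01 <- function(v, label) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) {
      warning("JASMINE ", label, " component is constant across cells; ",
              "normalized to zeros")
      return(numeric(length(v)))
    }
    (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  out <- (norm01(rm_comp, "rank") + norm01(enr, "enrichment")) / 2
  names(out) <- rownames(x)
  out
}

.SCORING_METHODS <- c("ans", "seurat", "scanpy_bins", "seurat_ag",
                      "seurat_lvg", "ucell", "jasmine_lh", "jasmine_or")

# Score one signature (already restricted to matrix genes) with one method.
.score_one <- function(x, sig, method, control_size = 100L, n_bins = 25L,
                       max_rank = 1500L, seed = NULL) {
  sig <- .as_signature(sig)
  switch(method,
    ans = score_ans(x, sig,
                    control_config(control_size, n_bins, "ans"))$scores,
    seurat = score_tirosh(x, sig, controls_bin_sampled(
      x, sig, control_config(control_size, n_bins, "bin_sampled", seed = seed))),
    scanpy_bins = score_tirosh(x, sig, controls_bin_sampled(
      x, sig, control_config(control_size, n_bins, "bin_sampled", seed = seed,
                             pooled_bins = TRUE))),
    seurat_ag = score_tirosh(x, sig, controls_all_genes(
      x, sig, control_config(control_size, n_bins, "bin_all_genes"))),
    seurat_lvg = score_tirosh(x, sig, controls_least_variable(
      x, sig, control_config(control_size, n_bins, "bin_least_variable"))),
    ucell = score_ucell(x, sig, max_rank = max_rank),
    jasmine_lh = score_jasmine(x, sig, mode = "likelihood"),
    jasmine_or = score_jasmine(x, sig, mode = "odds_ratio"),
    stop("unknown scoring method: ", method)
  )
}

#' Score a set of signatures with one method
#'
#' Scores every signature on the full matrix with the same method and
#' parameters (scoring all cells of all samples together is the recommended
#' mode for control-based methods). Signature genes absent from the matrix
#' are dropped with a warning; per-signature failures are collected and
#' reported together.
#'
#' @param x Validated expression matrix.
#' @param signatures A single signature or a (optionally named) list of
#'   `gene_signature` objects / character vectors.
#' @param method One of `"ans"`, `"seurat"` (per-gene sampled bins),
#'   `"scanpy_bins"` (pooled sampled bins), `"seurat_ag"`, `"seurat_lvg"`,
#'   `"ucell"`, `"jasmine_lh"`, `"jasmine_or"`.
#' @param control_size,n_bins Control-based method parameters.
#' @param max_rank UCell rank clamp.
#' @param seed Seed for the sampled-bin strategies.
#' @param drop_overlap If `TRUE`, genes shared by two or more signatures are
#'   removed from all of them before scoring.
#' @return A `score_matrix`: numeric matrix cells x signatures with
#'   attributes `method`, `params`, and `exclusions` (per-signature reports).
#' @export
score_all <- function(x, signatures, method = .SCORING_METHODS,
                      control_size = 100L, n_bins = 25L, max_rank = 1500L,
                      seed = NULL, drop_overlap = FALSE) {
  method <- match.arg(method)
  if (inherits(signatures, "gene_signature") || is.character(signatures)) {
    signatures <- list(signatures)
  }
  sigs <- vector("list", length(signatures))
  for (i in seq_along(signatures)) {
    nm <- names(signatures)[i]
    if (is.null(nm) || !nzchar(nm)) {
      nm <- if (inherits(signatures[[i]], "gene_signature"))
        signatures[[i]]$name else paste0("signature_", i)
    }
    sigs[[i]] <- .as_signature(signatures[[i]], nm)
  }
  if (length(sigs) < 1L) stop("at least one signature required")
  if (drop_overlap && length(sigs) > 1L) {
    all_genes <- unlist(lapply(sigs, `[[`, "genes"))
    shared <- unique(all_genes[duplicated(all_genes)])
    if (length(shared)) {
      message("dropping ", length(shared), " gene(s) shared between signatures")
      sigs <- lapply(sigs, function(s)
        gene_signature(s$name, setdiff(s$genes, shared)))
    }
  }
  out <- matrix(NA_real_, nrow(x), length(sigs),
                dimnames = list(rownames(x), vapply(sigs, `[[`, "", "name")))
  exclusions <- list()
  errors <- character()
  for (i in seq_along(sigs)) {
    res <- tryCatch({
      restricted <- intersect_signature(sigs[[i]], x)$signature
      if (method == "ans") {
        r <- score_ans(x, restricted,
                       control_config(control_size, n_bins, "ans"))
        exclusions[[restricted$name]] <- r$excluded
        r$scores
      } else {
        .score_one(x, restricted, method, control_size, n_bins, max_rank, seed)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(sigs[[i]]$name, ": ", conditionMessage(res)))
    } else {
      out[, i] <- res
    }
  }
  if (length(errors)) {
    stop("scoring failed for ", length(errors), " signature(s):\n  ",
         paste(errors, collapse = "\n  "))
  }
  structure(out, class = c("score_matrix", class(out)), method = method,
            params = list(control_size = control_size, n_bins = n_bins,
                          max_rank = max_rank, seed = seed,
                          drop_overlap = drop_overlap),
            exclusions = exclusions)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x), " cells x ", ncol(x), " signatures (method=",
      attr(x, "method"), ")\n", sep = "")
  invisible(x)
}
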