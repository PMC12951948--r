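#' Control-selection configuration
#'
#' Bundles the parameters shared by all control-gene strategies: the control
#' set size `c`, the number of expression bins, the strategy name, and the
#' random seed used by the sampled-bin strategy.
#'
#' @param control_size Control set size `c` (default 100 genes).
#' @param n_bins Number of expression bins (default 25).
#' @param strategy One of `"ans"`, `"bin_sampled"`, `"bin_all_genes"`,
#'   `"bin_least_variable"`.
#' @param seed Integer seed for `bin_sampled`; `NULL` leaves the RNG state
#'   untouched (results then depend on the ambient RNG).
#' @param lvg_raw_dispersion If `TRUE`, the least-variable-genes strategy
#'   ranks genes by the raw variance/mean dispersion instead of the
#'   within-bin z-scored ("seurat"-flavor normalized) dispersion.
#' @param pooled_bins If `TRUE`, `bin_sampled` draws one control set per
#'   expression bin shared by all signature genes of that bin, instead of an
#'   independent draw per signature gene.
#' @return A list of class `control_config`.
#' @export
control_config <- function(control_size = 100L, n_bins = 25L,
                           strategy = c("ans", "bin_sampled", "bin_all_genes",
                                        "bin_least_variable"),
                           seed = NULL, lvg_raw_dispersion = FALSE,
                           pooled_bins = FALSE) {
  strategy <- match.arg(strategy)
  control_size <- as.integer(control_size)
  n_bins <- as.integer(n_bins)
  stopifnot(control_size >= 1L, n_bins >= 1L)
  structure(list(control_size = control_size, n_bins = n_bins,
                 strategy = strategy, seed = seed,
                 lvg_raw_dispersion = isTRUE(lvg_raw_dispersion),
                 pooled_bins = isTRUE(pooled_bins)),
            class = "control_config")
}

#' Per-gene mean expression profile, sorted by nondecreasing mean
#'
#' Computes the arithmetic mean expression of every gene over all cells and
#' returns the genes sorted by nondecreasing mean. The sort is stable: genes
#' with tied means keep their original column order, which makes every
#' downstream bin and window selection deterministic.
#'
#' @param x Validated expression matrix (cells x genes).
#' @param exclude Optional character vector of genes to drop from the
#'   profile (used to build the signature-free profile for the ANS windows).
#' @return Object of class `mean_profile`: list with `gene_ids` and `means`
#'   (parallel, nondecreasing).
#' @export
mean_expression <- function(x, exclude = NULL) {
  mu <- Matrix::colMeans(x)
  if (!is.null(exclude)) {
    missing <- setdiff(exclude, names(mu))
    if (length(missing)) {
      stop("excluded genes not in matrix: ", paste(head(missing, 5L), collapse = ", "))
    }
    mu <- mu[!(names(mu) %in% exclude)]
  }
  ord <- order(mu, seq_along(mu))  # stable: ties keep original gene order
  structure(list(gene_ids = names(mu)[ord], means = unname(mu[ord])),
            class = "mean_profile")
}

#' @export
print.mean_profile <- function(x, ...) {
  cat("<mean_profile> ", length(x$means), " genes, mean range [",
      format(min(x$means)), ", ", format(max(x$means)), "]\n", sep = "")
  invisible(x)
}

#' Partition a sorted mean-expression profile into equally sized bins
#'
#' Contiguous rank-based partition of the sorted profile into `n_bins`
#' groups whose sizes differ by at most one gene. When the gene count is not
#' divisible by `n_bins`, the extra genes go to the lowest-expression bins
#' (a fixed, documented convention). Bins are numbered 1..`n_bins` in order
#' of increasing expression.
#'
#' @param profile A `mean_profile`.
#' @param n_bins Number of bins; must not exceed the number of genes.
#' @return Named integer vector: gene id -> bin index (1-based).
#' @export
bin_genes <- function(profile, n_bins) {
  stopifnot(inherits(profile, "mean_profile"))
  n_bins <- as.integer(n_bins)
  p <- length(profile$gene_ids)
  if (n_bins > p) stop("n_bins (", n_bins, ") exceeds number of genes (", p, ")")
  base <- p %/% n_bins
  rem <- p %% n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0L) sizes[seq_len(rem)] <- base + 1L
  bins <- rep.int(seq_len(n_bins), sizes)
  names(bins) <- profile$gene_ids
  bins
}

# Shared scaffolding for the bin-based strategies: profile over all genes,
# bin map, and per-signature-gene bin membership.
.bin_context <- function(x, sig_genes, config) {
  profile <- mean_expression(x)
  bins <- bin_genes(profile, config$n_bins)
  list(profile = profile, bins = bins, sig_bin = bins[sig_genes])
}

.new_assignment <- function(controls, retained, excluded, config) {
  structure(list(controls = controls, retained = retained,
                 excluded = excluded, config = config),
            class = "control_assignment")
}

#' @export
print.control_assignment <- function(x, ...) {
  sizes <- lengths(x$controls)
  cat("<control_assignment> strategy=", x$config$strategy, ": ",
      length(x$retained), " signature genes",
      if (nrow(x$excluded)) paste0(" (", nrow(x$excluded), " excluded)"),
      ", control sizes ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

.empty_exclusion <- function() {
  data.frame(gene = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Sampled-bin control genes (classic Tirosh / Seurat strategy)
#'
#' For each signature gene, draws `c` non-signature genes uniformly without
#' replacement from that gene's expression bin. If a bin holds fewer than
#' `c` eligible genes, all of them are taken (with a warning). Deterministic
#' for a fixed `config$seed`.
#'
#' With `config$pooled_bins = TRUE` a single draw is made per expression bin
#' and shared by all signature genes falling in that bin (the pooled variant
#' used by some toolkit implementations).
#'
#' @param x Validated expression matrix.
#' @param sig `gene_signature` or character vector (restricted to matrix
#'   genes beforehand by the caller or via [intersect_signature()]).
#' @param config A `control_config` with `strategy = "bin_sampled"`.
#' @return A `control_assignment`.
#' @export
controls_bin_sampled <- function(x, sig, config = control_config(strategy = "bin_sampled")) {
  sig <- .as_signature(sig)
  ctx <- .bin_context(x, sig$genes, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  controls <- vector("list", length(sig$genes))
  names(controls) <- sig$genes
  pooled <- list()
  for (i in seq_along(sig$genes)) {
    s <- sig$genes[i]
    b <- ctx$sig_bin[[s]]
    key <- as.character(b)
    if (config$pooled_bins && !is.null(pooled[[key]])) {
      controls[[i]] <- pooled[[key]]
      next
    }
    eligible <- names(ctx$bins)[ctx$bins == b]
    eligible <- setdiff(eligible, sig$genes)
    if (length(eligible) == 0L) {
      stop("no eligible control genes in expression bin ", b,
           " for signature gene '", s, "'")
    }
    if (length(eligible) <= config$control_size) {
      if (length(eligible) < config$control_size) {
        warning("bin ", b, " holds only ", length(eligible),
                " eligible control genes (< c = ", config$control_size,
                ") for signature gene '", s, "'; taking all")
      }
      chosen <- eligible
    } else {
      chosen <- sample(eligible, config$control_size)
    }
    controls[[i]] <- chosen
    if (config$pooled_bins) pooled[[key]] <- chosen
  }
  .new_assignment(controls, sig$genes, .empty_exclusion(), config)
}

#' All-genes-in-bin control genes (Seurat_AG strategy)
#'
#' Every signature gene receives all non-signature genes of its expression
#' bin as controls; the control size parameter `c` is ignored and control
#' sets may differ in size across signature genes.
#'
#' @inheritParams controls_bin_sampled
#' @return A `control_assignment`.
#' @export
controls_all_genes <- function(x, sig, config = control_config(strategy = "bin_all_genes")) {
  sig <- .as_signature(sig)
  ctx <- .bin_context(x, sig$genes, config)
  controls <- lapply(sig$genes, function(s) {
    b <- ctx$sig_bin[[s]]
    eligible <- setdiff(names(ctx$bins)[ctx$bins == b], sig$genes)
    if (length(eligible) == 0L) {
      stop("expression bin ", b, " holds no non-signature genes for '", s, "'")
    }
    eligible
  })
  names(controls) <- sig$genes
  .new_assignment(controls, sig$genes, .empty_exclusion(), config)
}

#' Per-gene dispersion, "seurat" flavor
#'
#' Dispersion of each gene computed on the expm1 (de-logged) scale as
#' variance/mean, then z-scored within 20 mean-expression bins (the
#' normalized dispersion of the standard highly-variable-genes routine).
#' With `raw = TRUE` the un-normalized variance/mean ratio is returned.
#'
#' Degenerate cases: genes with zero mean get dispersion 0; dispersion bins
#' whose standard deviation is 0 (or that hold a single gene) get z-score 0.
#'
#' @param x Validated expression matrix (log scale).
#' @param raw Return raw variance/mean instead of the within-bin z-score.
#' @param n_disp_bins Number of mean bins for the z-scoring (default 20).
#' @return Named numeric vector of dispersions, one per gene.
#' @export
gene_dispersion <- function(x, raw = FALSE, n_disp_bins = 20L) {
  xd <- .dense(x)
  ex <- expm1(xd)
  mu <- colMeans(ex)
  v <- apply(ex, 2L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (raw) return(disp)
  # z-score within bins of (log1p) mean expression
  lmu <- log1p(mu)
  brk <- unique(quantile(lmu, probs = seq(0, 1, length.out = n_disp_bins + 1L)))
  grp <- cut(lmu, breaks = brk, include.lowest = TRUE)
  z <- disp
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) { z[idx] <- 0; next }
    s <- sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  z
}

#' Least-variable-genes control selection (Seurat_LVG strategy)
#'
#' Each signature gene receives the `c` non-signature genes of its
#' expression bin with the smallest dispersion (ties broken by profile
#' order, i.e. by increasing mean expression). Deterministic.
#'
#' @inheritParams controls_bin_sampled
#' @return A `control_assignment`.
#' @export
controls_least_variable <- function(x, sig,
                                    config = control_config(strategy = "bin_least_variable")) {
  sig <- .as_signature(sig)
  ctx <- .bin_context(x, sig$genes, config)
  disp <- gene_dispersion(x, raw = config$lvg_raw_dispersion)
  controls <- lapply(sig$genes, function(s) {
    b <- ctx$sig_bin[[s]]
    eligible <- setdiff(names(ctx$bins)[ctx$bins == b], sig$genes)
    if (length(eligible) == 0L) {
      stop("expression bin ", b, " holds no non-signature genes for '", s, "'")
    }
    if (length(eligible) < config$control_size) {
      warning("bin ", b, " holds only ", length(eligible),
              " eligible control genes (< c = ", config$control_size,
              ") for signature gene '", s, "'; taking all")
      return(eligible)
    }
    d <- disp[eligible]
    eligible[order(d, seq_along(d))][seq_len(config$control_size)]
  })
  names(controls) <- sig$genes
  .new_assignment(controls, sig$genes, .empty_exclusion(), config)
}

#' Exclude signature genes among the most highly expressed genes
#'
#' ANS cannot build a centered control window for genes at the very top of
#' the expression distribution, so signature genes ranked within the top
#' `floor(c/2)` genes by mean expression (over all genes of the matrix) are
#' removed before control construction. Ranking ties at the boundary are
#' resolved by the stable sort order of the mean profile.
#'
#' @param sig `gene_signature` or character vector.
#' @param x Validated expression matrix.
#' @param config A `control_config` (only `control_size` is used).
#' @return List with `signature` (retained genes, original order) and
#'   `excluded` (data.frame of gene, reason).
#' @export
exclude_top_expressed <- function(sig, x, config = control_config()) {
  sig <- .as_signature(sig)
  profile <- mean_expression(x)
  n_top <- config$control_size %/% 2L
  top <- if (n_top > 0L) tail(profile$gene_ids, n_top) else character()
  drop <- sig$genes %in% top
  excluded <- data.frame(gene = sig$genes[drop],
                         reason = rep("top_expressed", sum(drop)),
                         stringsAsFactors = FALSE)
  retained <- sig$genes[!drop]
  if (length(retained) == 0L) {
    stop("all genes of signature '", sig$name, "' fall in the top ", n_top,
         " expressed genes; adjust the size of either the signature or the control sets")
  }
  list(signature = gene_signature(sig$name, retained), excluded = excluded)
}

#' Adjusted-neighborhood control selection (ANS)
#'
#' For each retained signature gene, the control set is the contiguous
#' window of `c` genes in the signature-free sorted mean profile whose
#' average mean expression is closest to the signature gene's mean
#' expression; ties go to the lower-expression window. Signature genes in
#' the top `floor(c/2)` expressed genes are excluded first
#' (see [exclude_top_expressed()]). Fully deterministic.
#'
#' Window means over the sorted profile are nondecreasing, so the objective
#' is unimodal in the window index; the implementation nevertheless scans
#' all windows, whose means it obtains from a single cumulative sum.
#'
#' @inheritParams controls_bin_sampled
#' @param config A `control_config` with `strategy = "ans"`.
#' @return A `control_assignment` (controls only for retained genes;
#'   `excluded` carries the top-expression exclusions).
#' @export
controls_ans <- function(x, sig, config = control_config(strategy = "ans")) {
  sig <- .as_signature(sig)
  kept <- exclude_top_expressed(sig, x, config)
  retained <- kept$signature$genes
  c_size <- config$control_size
  profile_all <- mean_expression(x)
  gene_mean <- setNames(profile_all$means, profile_all$gene_ids)
  tilde <- mean_expression(x, exclude = sig$genes)  # signature-free profile
  n_avail <- length(tilde$means)
  if (n_avail < c_size) {
    stop("control size (", c_size, ") exceeds available non-signature genes (",
         n_avail, ")")
  }
  cs <- cumsum(tilde$means)
  n_win <- n_avail - c_size + 1L
  wmeans <- (cs[seq(c_size, n_avail)] - c(0, cs[seq_len(n_win - 1L)])) / c_size
  controls <- lapply(retained, function(s) {
    k <- which.min(abs(gene_mean[[s]] - wmeans))  # first index on ties
    tilde$gene_ids[seq(k, k + c_size - 1L)]
  })
  names(controls) <- retained
  .new_assignment(controls, retained, kept$excluded, config)
}
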