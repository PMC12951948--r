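# Vectorized class-vs-rest rank-sum statistics for every gene: U statistic,
# tie-corrected normal z, two-sided p, and expm1-scale log2 fold-change.
# Shared by marker selection and by noise-pool construction.
.rank_sum_table <- function(x, labels, class) {
  xd <- .dense(x)
  n <- nrow(xd)
  in_cl <- labels == class
  n1 <- sum(in_cl); n0 <- n - n1
  ranks <- apply(xd, 2L, rank, ties.method = "average")
  r1 <- colSums(ranks[in_cl, , drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  # tie correction per gene
  tie_term <- apply(xd, 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  z <- ifelse(sigma > 0, (u - mu) / sigma, 0)
  p <- 2 * stats::pnorm(-abs(z))
  m1 <- colMeans(expm1(xd[in_cl, , drop = FALSE]))
  m0 <- colMeans(expm1(xd[!in_cl, , drop = FALSE]))
  log2fc <- log2((m1 + 1e-9) / (m0 + 1e-9))
  data.frame(gene = colnames(xd), U = unname(u), z = unname(z),
             p_value = unname(p), p_adj = p.adjust(unname(p), "BH"),
             log2fc = unname(log2fc), stringsAsFactors = FALSE)
}

#' Rank-sum (Wilcoxon) marker selection per class
#'
#' For each class, tests every gene class-vs-rest with the tie-corrected
#' normal approximation of the rank-sum test, adjusts p-values with
#' Benjamini-Hochberg, filters by adjusted p and log2 fold-change (computed
#' on expm1-scale means with a 1e-9 pseudocount), and keeps the `n_top`
#' genes with the largest test z-score.
#'
#' @param x Validated expression matrix.
#' @param labels Per-cell class labels (>= 2 classes; classes with fewer
#'   than 3 cells are skipped with a warning).
#' @param n_top Markers kept per class (default 100).
#' @param p_adj_max Adjusted p-value cutoff (default 0.05).
#' @param min_log2fc Minimum log2 fold-change (default 0: upregulated only).
#' @return Named list of `gene_signature` objects (classes possibly absent
#'   if skipped or no gene passed the filters).
#' @export
select_markers_wilcoxon <- function(x, labels, n_top = 100L,
                                    p_adj_max = 0.05, min_log2fc = 0) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  out <- list()
  for (cl in classes) {
    if (sum(labels == cl) < 3L) {
      warning("class '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    tab <- .rank_sum_table(x, labels, cl)
    keep <- tab$p_adj < p_adj_max & tab$log2fc > min_log2fc
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) {
      warning("no marker passed the filters for class '", cl, "'")
      next
    }
    tab <- tab[order(-tab$z), , drop = FALSE]
    out[[cl]] <- gene_signature(cl, head(tab$gene, n_top))
  }
  out
}

#' Candidate noise genes for signature-corruption experiments
#'
#' Genes that carry no class signal under the rank-sum test: adjusted
#' p-value above `p_min` and absolute log2 fold-change at most
#' `max_abs_log2fc` for the tested class against the rest.
#'
#' @param x Validated expression matrix.
#' @param labels Per-cell class labels.
#' @param class The class whose signal the pool must lack.
#' @param p_min Lower bound on adjusted p (default 0.01).
#' @param max_abs_log2fc Upper bound on |log2FC| (default 0.5).
#' @return Character vector of gene ids.
#' @export
noise_gene_pool <- function(x, labels, class, p_min = 0.01,
                            max_abs_log2fc = 0.5) {
  tab <- .rank_sum_table(x, labels, class)
  tab$gene[tab$p_adj > p_min & abs(tab$log2fc) <= max_abs_log2fc]
}

#' Control-gene selection bias scan over highly expressed genes
#'
#' Scores each gene in the top `top_fraction` of genes by mean expression as
#' a single-gene signature with each requested control-based method, and
#' reports the mean and standard deviation of the per-cell scores. On a
#' homogeneous dataset any deviation of the mean from zero measures control
#' selection bias. Genes that ANS cannot score (the top `floor(c/2)`
#' exclusion zone) are reported with `NA`.
#'
#' @param x Validated expression matrix (a single-cell-type dataset makes
#'   the zero-expectation interpretation valid).
#' @param methods Subset of `c("ans", "seurat", "seurat_ag", "seurat_lvg")`.
#' @param top_fraction Fraction of highest-expressed genes scanned
#'   (default 0.08).
#' @param control_size,n_bins Control parameters.
#' @param seed Seed for the sampled-bin strategy.
#' @return data.frame with one row per gene x method: `gene`,
#'   `mean_expression`, `expression_rank` (1 = lowest scanned), `method`,
#'   `mean_score`, `sd_score`; genes ordered by increasing mean expression.
#' @export
control_bias_scan <- function(x, methods = c("ans", "seurat", "seurat_ag",
                                             "seurat_lvg"),
                              top_fraction = 0.08, control_size = 100L,
                              n_bins = 25L, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  profile <- mean_expression(x)
  p <- length(profile$gene_ids)
  n_scan <- floor(top_fraction * p)
  if (n_scan < 1L) stop("top_fraction yields no genes to scan")
  scanned <- tail(profile$gene_ids, n_scan)       # increasing mean order
  scanned_mean <- tail(profile$means, n_scan)
  n_excl <- control_size %/% 2L
  ans_excluded <- tail(profile$gene_ids, n_excl)
  bins <- bin_genes(profile, n_bins)
  disp <- if ("seurat_lvg" %in% methods) gene_dispersion(x) else NULL
  if (!is.null(seed)) set.seed(seed)

  tilde_means <- setNames(profile$means, profile$gene_ids)
  res <- list()
  for (mi in seq_along(methods)) {
    method <- methods[mi]
    ms <- rep(NA_real_, n_scan)
    sds <- rep(NA_real_, n_scan)
    for (i in seq_len(n_scan)) {
      g <- scanned[i]
      ctrl <- switch(method,
        ans = {
          if (g %in% ans_excluded) NULL else {
            keep <- profile$gene_ids != g
            ids <- profile$gene_ids[keep]
            mus <- profile$means[keep]
            cs <- cumsum(mus)
            nw <- length(mus) - control_size + 1L
            wm <- (cs[seq(control_size, length(mus))] -
                     c(0, cs[seq_len(nw - 1L)])) / control_size
            k <- which.min(abs(scanned_mean[i] - wm))
            ids[seq(k, k + control_size - 1L)]
          }
        },
        seurat = {
          eligible <- setdiff(names(bins)[bins == bins[[g]]], g)
          if (length(eligible) <= control_size) eligible
          else sample(eligible, control_size)
        },
        seurat_ag = setdiff(names(bins)[bins == bins[[g]]], g),
        seurat_lvg = {
          eligible <- setdiff(names(bins)[bins == bins[[g]]], g)
          if (length(eligible) <= control_size) eligible
          else {
            d <- disp[eligible]
            eligible[order(d, seq_along(d))][seq_len(control_size)]
          }
        })
      if (is.null(ctrl)) next
      sc <- as.numeric(x[, g]) - Matrix::rowMeans(x[, ctrl, drop = FALSE])
      ms[i] <- mean(sc)
      sds[i] <- sd(sc)
    }
    res[[mi]] <- data.frame(gene = scanned, mean_expression = scanned_mean,
                            expression_rank = seq_len(n_scan),
                            method = method, mean_score = ms, sd_score = sds,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Joint versus per-sample scoring, with a batch-effect test
#'
#' Scores one signature twice: once on all cells together ("joint") and
#' once per sample ("per_sample", control selection restricted to the
#' sample's cells). For each mode it reports the per-sample per-class mean
#' scores, the across-sample variance of the tested class's means, and the
#' two-sided Mann-Whitney p-value comparing the tested class's sample means
#' between the two batch groups (when batch ids are available).
#'
#' @param x Validated expression matrix.
#' @param sig Signature to score.
#' @param method Scoring method name as in [score_all()].
#' @param sample_id,batch_id,labels Per-cell sample, batch and class
#'   vectors (batch may be `NULL` to skip the test).
#' @param target_class Class whose sample means are compared (default the
#'   signature's name).
#' @param ... Further parameters for [score_all()].
#' @return List with `means` (data.frame mode x sample x class),
#'   `variance` (named: joint, per_sample), `batch_p` (named two-sided
#'   Mann-Whitney p-values, or `NULL`).
#' @export
joint_vs_per_sample <- function(x, sig, method, sample_id, batch_id = NULL,
                                labels, target_class = NULL, ...) {
  sig <- .as_signature(sig)
  if (is.null(target_class)) target_class <- sig$name
  stopifnot(length(sample_id) == nrow(x), length(labels) == nrow(x))
  samples <- unique(sample_id)
  if (length(samples) < 2L) stop("need at least 2 samples")

  joint <- as.numeric(score_all(x, sig, method = method, ...))
  per <- numeric(nrow(x))
  for (s in samples) {
    rows <- sample_id == s
    per[rows] <- as.numeric(score_all(x[rows, , drop = FALSE], sig,
                                      method = method, ...))
  }
  collect <- function(scores, mode) {
    df <- aggregate(score ~ sample + class,
                    data = data.frame(score = scores, sample = sample_id,
                                      class = labels),
                    FUN = mean)
    df$mode <- mode
    df
  }
  means <- rbind(collect(joint, "joint"), collect(per, "per_sample"))
  target <- means[means$class == target_class, , drop = FALSE]
  if (nrow(target) == 0L) stop("no cells of target class '", target_class, "'")
  variance <- c(
    joint = var(target$score[target$mode == "joint"]),
    per_sample = var(target$score[target$mode == "per_sample"]))
  batch_p <- NULL
  if (!is.null(batch_id)) {
    batch_of_sample <- tapply(as.character(batch_id), sample_id,
                              function(v) v[1L])
    groups <- unique(batch_of_sample)
    if (length(groups) == 2L) {
      batch_p <- vapply(c("joint", "per_sample"), function(mode) {
        sub <- target[target$mode == mode, , drop = FALSE]
        b <- batch_of_sample[sub$sample]
        wilcox.test(sub$score[b == groups[1L]],
                    sub$score[b == groups[2L]])$p.value
      }, numeric(1))
    }
  }
  list(means = means, variance = variance, batch_p = batch_p)
}

#' Minimal signature length achieving perfect binary separation
#'
#' Scores growing prefixes of a ranked marker list and reports the smallest
#' length whose scores reach AUCROC 1 against the binary truth. For
#' control-based methods, genes for which no valid control set can exist
#' (the `floor(c/2)` lowest- or highest-expressed genes) are removed from
#' the list first. Stops at the first prefix reaching AUCROC 1.
#'
#' @param x Validated expression matrix.
#' @param ranked_genes Character vector, most informative gene first.
#' @param truth Binary per-cell truth (logical or two-level).
#' @param method Scoring method name.
#' @param control_size,n_bins,max_rank,seed Method parameters.
#' @return List: `minimal_length` (full list length when never separating),
#'   `separating` (logical), `auc` (AUCROC per tested length),
#'   `genes_used` (the filtered ranked list).
#' @export
signature_length_sweep <- function(x, ranked_genes, truth, method,
                                   control_size = 100L, n_bins = 25L,
                                   max_rank = 1500L, seed = NULL) {
  if (length(unique(as.character(truth))) < 2L) {
    stop("truth must contain both classes")
  }
  genes <- ranked_genes
  if (method %in% c("ans", "seurat", "scanpy_bins", "seurat_ag", "seurat_lvg")) {
    profile <- mean_expression(x)
    half <- control_size %/% 2L
    invalid <- c(head(profile$gene_ids, half), tail(profile$gene_ids, half))
    genes <- setdiff(genes, invalid)
  }
  if (length(genes) == 0L) stop("no genes left after control-validity filtering")
  aucs <- numeric(0)
  for (len in seq_along(genes)) {
    sc <- as.numeric(score_all(x, gene_signature("prefix", genes[seq_len(len)]),
                               method = method, control_size = control_size,
                               n_bins = n_bins, max_rank = max_rank,
                               seed = seed))
    aucs[len] <- binary_auc(sc, truth, "roc")
    if (aucs[len] >= 1) {
      return(list(minimal_length = len, separating = TRUE, auc = aucs,
                  genes_used = genes))
    }
  }
  list(minimal_length = length(genes), separating = FALSE, auc = aucs,
       genes_used = genes)
}

#' Robustness of scoring to unrelated genes in the signature
#'
#' Starting from a pure signature, progressively replaces its genes with
#' random genes from a noise pool (nested replacements within a run) and
#' records the AUCROC of the corrupted signature's scores at each
#' replacement level, over `n_runs` independent runs. Deterministic given
#' `seed`.
#'
#' @param x Validated expression matrix.
#' @param pure_sig Signature of informative genes.
#' @param noise_pool Character vector of replacement genes, disjoint from
#'   the signature and at least as large.
#' @param truth Binary per-cell truth.
#' @param method Scoring method name.
#' @param n_runs Number of simulation runs (default 20).
#' @param levels Integer vector of replacement counts to evaluate (default
#'   `0:m`).
#' @param seed RNG seed.
#' @param ... Further parameters for [score_all()].
#' @return data.frame: `run`, `n_replaced`, `noise_fraction`, `auc`.
#' @export
noise_robustness <- function(x, pure_sig, noise_pool, truth, method,
                             n_runs = 20L, levels = NULL, seed = 1L, ...) {
  pure_sig <- .as_signature(pure_sig)
  m <- length(pure_sig$genes)
  if (any(noise_pool %in% pure_sig$genes)) {
    stop("noise pool must be disjoint from the pure signature")
  }
  if (length(noise_pool) < m) {
    stop("noise pool (", length(noise_pool), ") smaller than signature (", m, ")")
  }
  if (is.null(levels)) levels <- 0:m
  stopifnot(all(levels >= 0L), all(levels <= m))
  set.seed(seed)
  out <- vector("list", n_runs * length(levels))
  row <- 0L
  for (r in seq_len(n_runs)) {
    replace_order <- sample(m)           # nested corruption order
    replacement <- sample(noise_pool, m)
    for (lv in levels) {
      genes <- pure_sig$genes
      if (lv > 0L) genes[replace_order[seq_len(lv)]] <- replacement[seq_len(lv)]
      sc <- as.numeric(score_all(x, gene_signature("corrupted", genes),
                                 method = method, ...))
      row <- row + 1L
      out[[row]] <- data.frame(run = r, n_replaced = lv,
                               noise_fraction = lv / m,
                               auc = binary_auc(sc, truth, "roc"))
    }
  }
  do.call(rbind, out)
}
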