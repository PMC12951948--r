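# Small in-code fixtures shared across test files.

# Random log-normal-ish expression matrix with unique ids.
random_matrix <- function(n = 20L, p = 15L, seed = 1L, sparsity = 0) {
  set.seed(seed)
  m <- matrix(rlnorm(n * p, 0, 1), n, p,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("g%03d", seq_len(p))))
  if (sparsity > 0) m[runif(n * p) < sparsity] <- 0
  validate_matrix(m)
  m
}

# Matrix whose gene means are exactly `means` (single cell).
matrix_with_means <- function(means, gene_ids = NULL) {
  p <- length(means)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(p))
  m <- matrix(means, nrow = 1L, dimnames = list("c1", gene_ids))
  validate_matrix(m)
  m
}

# Independent enumeration oracle for the neighborhood window search:
# all windows of size c over the signature-free sorted profile, mean by
# mean(), leftmost argmin of |target - window mean|.
oracle_ans_window <- function(tilde_means, tilde_ids, c_size, target) {
  n_win <- length(tilde_means) - c_size + 1L
  best_k <- 1L
  best_d <- Inf
  for (k in seq_len(n_win)) {
    d <- abs(target - mean(tilde_means[k:(k + c_size - 1L)]))
    if (d < best_d) { best_d <- d; best_k <- k }
  }
  tilde_ids[best_k:(best_k + c_size - 1L)]
}

# Independent UCell oracle: explicit sort-based ranking with averaged ties.
oracle_ucell_cell <- function(row, sig_idx, max_rank) {
  ord <- order(-row)
  r <- numeric(length(row))
  i <- 1L
  while (i <= length(row)) {
    j <- i
    while (j < length(row) && row[ord[j + 1L]] == row[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r[r > max_rank] <- max_rank + 1
  m <- length(sig_idx)
  u <- sum(r[sig_idx]) - m * (m + 1) / 2
  1 - u / (m * max_rank)
}

# Independent JASMINE oracle following the two-component recipe literally.
oracle_jasmine <- function(x, sig_idx, mode) {
  n <- nrow(x); p <- ncol(x); m <- length(sig_idx)
  rm_c <- numeric(n); enr <- numeric(n); undef <- logical(n)
  for (j in seq_len(n)) {
    row <- x[j, ]
    exp_idx <- which(row > 0)
    a <- sum(exp_idx %in% sig_idx); b <- m - a
    g <- length(exp_idx) - a; h <- (p - m) - g
    rm_c[j] <- if (a > 0) {
      r <- rank(row[exp_idx], ties.method = "average")
      mean(r[exp_idx %in% sig_idx]) / length(exp_idx)
    } else 0
    if (a == 0) enr[j] <- 0
    else if (mode == "odds_ratio") {
      if (b == 0 || g == 0) undef[j] <- TRUE else enr[j] <- a * h / (b * g)
    } else {
      if (g == 0) undef[j] <- TRUE else enr[j] <- a * (g + h) / (g * (a + b))
    }
  }
  if (any(undef)) enr[undef] <- if (all(undef)) 1 else max(enr[!undef])
  mm <- function(v) {
    rg <- range(v)
    if (rg[1] == rg[2]) numeric(length(v)) else (v - rg[1]) / diff(rg)
  }
  (mm(rm_c) + mm(enr)) / 2
}
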