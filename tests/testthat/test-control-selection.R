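test_that("mean_expression matches brute-force column means, sorted stably", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  pr <- mean_expression(m)
  expect_equal(pr$means, c(2, 3))
  expect_identical(pr$gene_ids, c("g1", "g2"))

  r <- random_matrix(20, 15, seed = 7)
  pr <- mean_expression(r)
  manual <- sapply(colnames(r), function(g) mean(r[, g]))
  ord <- order(manual)  # no ties with continuous draws
  expect_equal(pr$means, unname(manual[ord]))
  expect_identical(pr$gene_ids, names(manual)[ord])
  expect_true(all(diff(pr$means) >= 0))

  # all-zero gene first; tied means keep original column order
  z <- cbind(r, zzz = 0)[, c(ncol(r) + 1L, seq_len(ncol(r)))]
  colnames(z)[1] <- "zzz"
  expect_identical(mean_expression(validate_matrix(z))$gene_ids[1], "zzz")
  tied <- matrix(1, 1, 4, dimnames = list("c1", c("d", "b", "c", "a")))
  expect_identical(mean_expression(tied)$gene_ids, c("d", "b", "c", "a"))
})

test_that("bin_genes partitions into near-equal contiguous bins, extras to low bins", {
  pr100 <- mean_expression(matrix_with_means(seq_len(100) / 10))
  b <- bin_genes(pr100, 25)
  expect_true(all(table(b) == 4))
  expect_identical(unname(b[1]), 1L)
  expect_identical(unname(b[100]), 25L)

  pr10 <- mean_expression(matrix_with_means(1:10))
  expect_equal(as.integer(table(bin_genes(pr10, 3))), c(4L, 3L, 3L))

  # tied means: bins follow original gene order
  prt <- mean_expression(matrix_with_means(rep(1, 6), gene_ids = letters[1:6]))
  bt <- bin_genes(prt, 2)
  expect_identical(names(bt)[bt == 1L], c("a", "b", "c"))

  expect_error(bin_genes(pr10, 11), "exceeds")
})

test_that("controls_bin_sampled draws in-bin non-signature genes, reproducibly", {
  m <- random_matrix(10, 60, seed = 2)
  sig <- gene_signature("s", colnames(m)[c(5, 20, 41)])
  cfg <- control_config(control_size = 5, n_bins = 4,
                        strategy = "bin_sampled", seed = 11)
  ca <- controls_bin_sampled(m, sig, cfg)
  bins <- bin_genes(mean_expression(m), 4)
  for (s in sig$genes) {
    ctrl <- ca$controls[[s]]
    expect_length(ctrl, 5)
    expect_true(all(bins[ctrl] == bins[[s]]))       # same bin
    expect_length(intersect(ctrl, sig$genes), 0)    # disjoint from signature
  }
  expect_identical(ca, controls_bin_sampled(m, sig, cfg))  # seed determinism

  # bin with exactly c eligible genes: whole bin, no randomness
  cfg2 <- control_config(control_size = 14, n_bins = 4,
                         strategy = "bin_sampled", seed = 1)
  ca2 <- suppressWarnings(controls_bin_sampled(m, sig, cfg2))
  b <- bins[[sig$genes[1]]]
  expect_setequal(ca2$controls[[sig$genes[1]]],
                  setdiff(names(bins)[bins == b], sig$genes))
})

test_that("controls_all_genes returns full bins minus the signature", {
  m <- random_matrix(10, 40, seed = 4)
  bins <- bin_genes(mean_expression(m), 5)
  sig_genes <- c(names(bins)[bins == 2L][1:2], names(bins)[bins == 4L][1])
  sig <- gene_signature("s", sig_genes)
  ca <- controls_all_genes(m, sig, control_config(n_bins = 5,
                                                  strategy = "bin_all_genes"))
  # both signature genes of bin 2 share the same 6-gene control set
  b2 <- setdiff(names(bins)[bins == 2L], sig_genes)
  expect_setequal(ca$controls[[sig_genes[1]]], b2)
  expect_setequal(ca$controls[[sig_genes[2]]], b2)
  expect_setequal(ca$controls[[sig_genes[3]]],
                  setdiff(names(bins)[bins == 4L], sig_genes))
  # union of all controls = union of touched bins minus signature
  touched <- unique(bins[sig_genes])
  expect_setequal(unique(unlist(ca$controls)),
                  setdiff(names(bins)[bins %in% touched], sig_genes))
})

test_that("controls_least_variable picks the c smallest-dispersion in-bin genes", {
  m <- random_matrix(30, 40, seed = 9)
  m[, "g010"] <- 1  # constant gene: dispersion 0, ranked first in its bin
  validate_matrix(m)
  cfg <- control_config(control_size = 3, n_bins = 2,
                        strategy = "bin_least_variable")
  sig <- gene_signature("s", "g001")
  ca <- controls_least_variable(m, sig, cfg)
  bins <- bin_genes(mean_expression(m), 2)
  disp <- gene_dispersion(m)
  eligible <- setdiff(names(bins)[bins == bins[["g001"]]], "g001")
  expected <- eligible[order(disp[eligible], seq_along(eligible))][1:3]
  expect_identical(ca$controls[["g001"]], expected)
  if (bins[["g010"]] == bins[["g001"]]) {
    expect_true("g010" %in% ca$controls[["g001"]])
  }
  # raw dispersion flag changes the ranking statistic, not the contract
  cfg_raw <- control_config(control_size = 3, n_bins = 2,
                            strategy = "bin_least_variable",
                            lvg_raw_dispersion = TRUE)
  ca_raw <- controls_least_variable(m, sig, cfg_raw)
  draw <- gene_dispersion(m, raw = TRUE)
  expect_identical(ca_raw$controls[["g001"]],
                   eligible[order(draw[eligible], seq_along(eligible))][1:3])
})

test_that("exclude_top_expressed removes exactly the top floor(c/2) ranked genes", {
  means <- seq_len(200) / 100  # gene g200 is highest expressed
  m <- matrix_with_means(means)
  # c = 100: top 50 genes are g151..g200
  r30 <- exclude_top_expressed(gene_signature("s", c("g171", "g001")), m,
                               control_config(control_size = 100))
  expect_identical(r30$excluded$gene, "g171")   # rank 30 from top: excluded
  expect_identical(r30$signature$genes, "g001")

  r51 <- exclude_top_expressed(gene_signature("s", c("g150", "g001")), m,
                               control_config(control_size = 100))
  expect_identical(nrow(r51$excluded), 0L)      # rank 51 from top: retained

  r2 <- exclude_top_expressed(gene_signature("s", c("g200", "g199")), m,
                              control_config(control_size = 2))
  expect_identical(r2$excluded$gene, "g200")    # only the single top gene

  expect_error(
    exclude_top_expressed(gene_signature("s", c("g200", "g199")), m,
                          control_config(control_size = 100)),
    "signature or the control")
})

test_that("controls_ans matches the hand-worked window example", {
  # non-signature means (0, 0.1, 0.2, 0.9, 1.0), signature mean 0.16, c = 2:
  # window means are 0.05, 0.15, 0.55, 0.95; |0.16 - 0.15| = 0.01 wins
  m <- matrix_with_means(c(0, 0.1, 0.2, 0.9, 1.0, 0.16),
                         gene_ids = c("w1", "w2", "w3", "w4", "w5", "s"))
  ca <- controls_ans(m, gene_signature("sig", "s"),
                     control_config(control_size = 2, strategy = "ans"))
  expect_identical(ca$controls[["s"]], c("w2", "w3"))

  # signature mean below every non-signature mean: leftmost window
  m2 <- matrix_with_means(c(0.5, 0.6, 0.7, 0.8, 0.01),
                          gene_ids = c("w1", "w2", "w3", "w4", "s"))
  ca2 <- controls_ans(m2, gene_signature("sig", "s"),
                      control_config(control_size = 2, strategy = "ans"))
  expect_identical(ca2$controls[["s"]], c("w1", "w2"))

  expect_error(
    controls_ans(random_matrix(5, 10, seed = 1),
                 gene_signature("s", sprintf("g%03d", 1:8)),
                 control_config(control_size = 5, strategy = "ans")),
    "exceeds available")
})

test_that("ANS window means are nondecreasing and controls exclude the signature", {
  for (seed in 1:10) {
    m <- random_matrix(8, 80, seed = seed)
    sig <- gene_signature("s", sample(colnames(m), 6))
    cfg <- control_config(control_size = 10, strategy = "ans")
    tilde <- mean_expression(m, exclude = sig$genes)
    wm <- vapply(seq_len(length(tilde$means) - 9L),
                 function(k) mean(tilde$means[k:(k + 9L)]), numeric(1))
    expect_true(all(diff(wm) >= 0))
    ca <- controls_ans(m, sig, cfg)
    for (s in ca$retained) {
      expect_length(intersect(ca$controls[[s]], sig$genes), 0)
      expect_length(ca$controls[[s]], 10)
    }
    expect_setequal(c(ca$retained, ca$excluded$gene), sig$genes)
  }
})
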