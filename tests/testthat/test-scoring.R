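test_that("score_tirosh matches the signature-minus-control formula", {
  # constant cell: every term X_js - controlMean is zero
  m <- matrix(2, 3, 6, dimnames = list(paste0("c", 1:3), paste0("g", 1:6)))
  validate_matrix(m)
  ca <- structure(list(controls = list(g1 = c("g3", "g4"), g2 = c("g5", "g6")),
                       retained = c("g1", "g2"),
                       excluded = data.frame(gene = character(),
                                             reason = character()),
                       config = control_config()),
                  class = "control_assignment")
  expect_equal(unname(score_tirosh(m, c("g1", "g2"), ca)), rep(0, 3))

  # each signature gene exceeds its control mean by delta: score = delta
  m2 <- m
  m2[, c("g1", "g2")] <- 2 + 0.7
  validate_matrix(m2)
  expect_equal(unname(score_tirosh(m2, c("g1", "g2"), ca)), rep(0.7, 3))

  # random instance vs literal term-by-term evaluation
  r <- random_matrix(10, 30, seed = 21)
  sig_genes <- colnames(r)[c(2, 9, 17)]
  set.seed(5)
  ctrl <- lapply(sig_genes, function(s)
    sample(setdiff(colnames(r), sig_genes), 4))
  names(ctrl) <- sig_genes
  ca2 <- structure(list(controls = ctrl, retained = sig_genes,
                        excluded = data.frame(gene = character(),
                                              reason = character()),
                        config = control_config()),
                   class = "control_assignment")
  got <- score_tirosh(r, sig_genes, ca2)
  manual <- numeric(nrow(r))
  for (j in seq_len(nrow(r))) {
    terms <- vapply(sig_genes, function(s)
      r[j, s] - mean(r[j, ctrl[[s]]]), numeric(1))
    manual[j] <- mean(terms)
  }
  expect_equal(unname(got), manual)
})

test_that("score_ans composes exclusion, window controls and Tirosh scoring", {
  m <- random_matrix(12, 60, seed = 31)
  sig <- gene_signature("s", colnames(m)[c(3, 12, 25, 48)])
  cfg <- control_config(control_size = 8, strategy = "ans")
  res <- score_ans(m, sig, cfg)
  # against the enumeration oracle, gene by gene
  kept <- exclude_top_expressed(sig, m, cfg)
  tilde <- mean_expression(m, exclude = sig$genes)
  mu <- Matrix::colMeans(m)
  for (s in kept$signature$genes) {
    expect_identical(res$controls$controls[[s]],
                     oracle_ans_window(tilde$means, tilde$gene_ids, 8, mu[[s]]))
  }
  expect_equal(res$scores,
               score_tirosh(m, kept$signature, res$controls))
  expect_identical(res$excluded$gene, kept$excluded$gene)
})

test_that("UCell: closed-form cases and brute-force rank oracle", {
  # signature holds the top-m ranks: U = 0, score exactly 1
  m <- matrix_with_means(10:1)
  top <- mean_expression(m)$gene_ids[10:8]  # three highest genes
  expect_equal(unname(score_ucell(m, gene_signature("s", top), max_rank = 5)), 1)

  # single gene ranked beyond max_rank: score exactly 0
  m2 <- matrix_with_means(10:1)  # g010 has value 1, rank 10
  expect_equal(unname(score_ucell(m2, gene_signature("s", "g010"),
                                  max_rank = 5)), 0)

  expect_error(score_ucell(m, gene_signature("s", colnames(m)[1:8]),
                           max_rank = 5), "max_rank")

  # random instances (with ties from sparsity) vs the independent oracle
  for (seed in 1:8) {
    r <- random_matrix(6, 40, seed = seed, sparsity = 0.3)
    genes <- sample(colnames(r), 5)
    got <- score_ucell(r, gene_signature("s", genes), max_rank = 20)
    sig_idx <- match(genes, colnames(r))
    manual <- vapply(seq_len(nrow(r)), function(j)
      oracle_ucell_cell(r[j, ], sig_idx, 20), numeric(1))
    expect_equal(unname(got), manual)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("UCell scores are unchanged by deleting other cells; Tirosh scores are not", {
  r <- random_matrix(20, 50, seed = 77, sparsity = 0.2)
  sig <- gene_signature("s", colnames(r)[1:5])
  full <- score_ucell(r, sig, max_rank = 30)
  subset_rows <- rownames(r)[1:7]
  sub <- score_ucell(r[subset_rows, ], sig, max_rank = 30)
  expect_equal(full[subset_rows], sub)

  # constructed example where cell deletion changes the mean profile enough
  # to move a control window: ANS scores of remaining cells change
  cfg <- control_config(control_size = 10, strategy = "ans")
  r2 <- r
  r2[8:20, colnames(r)[6:15]] <- r2[8:20, colnames(r)[6:15]] + 3
  validate_matrix(r2)
  full_ans <- score_ans(r2, sig, cfg)$scores
  sub_ans <- score_ans(r2[subset_rows, ], sig, cfg)$scores
  expect_false(isTRUE(all.equal(full_ans[subset_rows], sub_ans)))
})

test_that("JASMINE: two-cell construction and literal-recipe oracle", {
  # cell A expresses the signature top-ranked, cell B not at all
  m <- matrix(c(1, 2, 3, 4,
                1, 2, 0, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), c("g1", "g2", "s1", "s2")))
  validate_matrix(m)
  sc <- score_jasmine(m, gene_signature("s", c("s1", "s2")), "likelihood")
  expect_equal(unname(sc), c(1, 0))

  # cell with no expressed signature gene has rank component 0 pre-normalization
  # (cell B above drives the minimum, hence its normalized score of 0)

  for (seed in 1:6) {
    r <- random_matrix(8, 30, seed = seed, sparsity = 0.4)
    genes <- sample(colnames(r), 6)
    sig_idx <- match(genes, colnames(r))
    for (mode in c("likelihood", "odds_ratio")) {
      got <- suppressMessages(
        score_jasmine(r, gene_signature("s", genes), mode))
      expect_equal(unname(got), oracle_jasmine(r, sig_idx, mode))
      expect_true(all(got >= 0 & got <= 1))
    }
  }
})

test_that("score_all: single-signature consistency, ranges, overlap dropping", {
  d <- generate_dataset(synthetic_config(
    n_genes = 300L, cell_types = c(a = 40L, b = 40L), markers_per_type = 8L,
    seed = 3))
  m <- d$matrix
  sig1 <- d$signatures$a
  sm <- score_all(m, list(sig1), method = "ucell", max_rank = 200)
  expect_equal(sm[, 1], score_ucell(m, sig1, max_rank = 200))
  expect_true(all(sm >= 0 & sm <= 1))

  both <- score_all(m, d$signatures, method = "ans", control_size = 20)
  expect_identical(colnames(both), c("a", "b"))

  # overlapping signatures: the shared gene is dropped from both
  shared <- setdiff(colnames(m), unlist(lapply(d$signatures, `[[`, "genes")))[1]
  s_over <- list(x = gene_signature("x", c(sig1$genes[1:4], shared)),
                 y = gene_signature("y", c(shared, d$signatures$b$genes[1:4])))
  sm2 <- suppressMessages(score_all(m, s_over, method = "ucell",
                                    max_rank = 200, drop_overlap = TRUE))
  no_shared <- list(x = gene_signature("x", sig1$genes[1:4]),
                    y = gene_signature("y", d$signatures$b$genes[1:4]))
  sm3 <- score_all(m, no_shared, method = "ucell", max_rank = 200)
  expect_equal(unclass(sm2), unclass(sm3), ignore_attr = TRUE)
})

test_that("deterministic methods are bitwise reproducible; bin_sampled given seed", {
  m <- random_matrix(15, 80, seed = 8, sparsity = 0.2)
  sigs <- list(s1 = colnames(m)[1:6], s2 = colnames(m)[11:16])
  for (method in c("ans", "seurat_ag", "seurat_lvg", "ucell",
                   "jasmine_lh", "jasmine_or")) {
    a <- suppressMessages(score_all(m, sigs, method = method,
                                    control_size = 10, n_bins = 4,
                                    max_rank = 40))
    b <- suppressMessages(score_all(m, sigs, method = method,
                                    control_size = 10, n_bins = 4,
                                    max_rank = 40))
    expect_identical(unclass(a), unclass(b))
  }
  a <- score_all(m, sigs, method = "seurat", control_size = 10, n_bins = 4,
                 seed = 123)
  b <- score_all(m, sigs, method = "seurat", control_size = 10, n_bins = 4,
                 seed = 123)
  expect_identical(unclass(a), unclass(b))
})

test_that("Tirosh-family scores are invariant under a per-cell constant shift", {
  m <- random_matrix(10, 60, seed = 13)
  sig <- list(s = colnames(m)[c(4, 9, 30)])
  shifted <- m
  shifted[3, ] <- shifted[3, ] + 5  # shift one whole cell
  validate_matrix(shifted)
  for (method in c("ans", "seurat_ag")) {
    a <- score_all(m, sig, method = method, control_size = 8, n_bins = 3)
    b <- score_all(shifted, sig, method = method, control_size = 8, n_bins = 3)
    expect_equal(b[3, 1], a[3, 1])
    expect_equal(b[-3, 1], a[-3, 1])
  }
  a <- score_all(m, sig, method = "seurat", control_size = 8, n_bins = 3,
                 seed = 4)
  b <- score_all(shifted, sig, method = "seurat", control_size = 8, n_bins = 3,
                 seed = 4)
  expect_equal(b[3, 1], a[3, 1])
})
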