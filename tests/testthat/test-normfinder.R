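nf_groups <- function(n_case, n_ctrl) {
  setNames(rep(c("tumour", "normal"), c(n_case, n_ctrl)),
           paste0("s", seq_len(n_case + n_ctrl)))
}

test_that("constant expression gives zero variance and zero stability", {
  v <- matrix(2^c(1, 1, 1, 1, 1, 1,
                  3, 3, 3, 3, 3, 3,
                  0, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  res <- normfinder_rank(rq_from_matrix(v), groups = nf_groups(3, 3))
  expect_equal(res$table$stability, rep(0, 3))
  expect_equal(res$gamma2, 0)
  expect_equal(res$table$dtilde_g1, rep(0, 3))   # gamma2 = 0 forces 0
})

test_that("stability values match the loop-based oracle on random panels", {
  for (seed in 1:8) {
    g <- sample(3:6, 1)
    rq <- random_rq(g, 10, seed = 500 + seed)
    groups <- nf_groups(5, 5)
    res <- normfinder_rank(rq, groups = groups)
    oracle <- oracle_normfinder(log2(rq$values), groups[colnames(rq$values)])
    expect_equal(setNames(res$table$stability, res$table$gene),
                 oracle$rho[order(names(oracle$rho))][res$table$gene],
                 tolerance = 1e-12)
    expect_equal(res$gamma2, oracle$gamma2, tolerance = 1e-12)
  }
})

test_that("best-pair search agrees exactly with brute-force enumeration", {
  for (seed in 1:8) {
    g <- sample(4:6, 1)
    rq <- random_rq(g, 12, seed = 700 + seed)
    groups <- nf_groups(6, 6)
    bp <- normfinder_best_pair(rq, groups = groups)
    oracle <- oracle_best_pair(log2(rq$values), groups[colnames(rq$values)])
    expect_equal(bp$pair, oracle$pair)
    expect_equal(bp$pair_stability, oracle$rho, tolerance = 1e-12)
  }
})

test_that("a duplicated gene pairs with itself at its own stability", {
  set.seed(2)
  v <- 2^matrix(rnorm(4 * 10), 4, 10,
                dimnames = list(c("a", "a2", "b", "c"), paste0("s", 1:10)))
  v["a2", ] <- v["a", ]
  rq <- rq_from_matrix(v)
  groups <- nf_groups(5, 5)
  res <- normfinder_rank(rq, groups = groups)
  # the composite of a gene with its duplicate, within the same 4-gene
  # panel context, has exactly the single gene's stability
  setup_rho <- res$table$stability[res$table$gene == "a"]
  comp <- normfinder_best_pair(rq, groups = groups)
  dup_row <- comp$pair_table[comp$pair_table$gene_a == "a" &
                               comp$pair_table$gene_b == "a2", ]
  expect_equal(dup_row$stability, setup_rho, tolerance = 1e-12)
})

test_that("opposite group effects cancel in a pair", {
  set.seed(5)
  n <- 12
  groups <- nf_groups(6, 6)
  eps <- matrix(rnorm(4 * n, 0, 0.1), 4, n)
  shift <- c(1, -1, 0, 0)   # log2 units, applied to tumour samples
  y <- 25 + eps + outer(shift, as.numeric(groups == "tumour"))
  dimnames(y) <- list(c("up", "down", "f1", "f2"), names(groups))
  rq <- rq_from_matrix(2^y)
  res <- normfinder_rank(rq, groups = groups)
  bp <- normfinder_best_pair(rq, groups = groups)
  pt <- bp$pair_table
  cancel <- pt$stability[pt$gene_a == "down" & pt$gene_b == "up"]
  rho <- setNames(res$table$stability, res$table$gene)
  expect_lt(cancel, rho["up"])
  expect_lt(cancel, rho["down"])
})

test_that("stability is invariant to gene rescaling, sample shifts and label swap", {
  rq <- random_rq(5, 14, seed = 900)
  groups <- nf_groups(7, 7)
  base <- normfinder_rank(rq, groups = groups)$table$stability

  scaled <- rq
  scaled$values["g1", ] <- scaled$values["g1", ] * 9.7
  expect_equal(normfinder_rank(scaled, groups = groups)$table$stability,
               base, tolerance = 1e-12)

  shifted <- rq
  shifted$values[, 3] <- shifted$values[, 3] * 2^1.7   # whole-sample shift
  expect_equal(normfinder_rank(shifted, groups = groups)$table$stability,
               base, tolerance = 1e-12)

  swapped <- setNames(ifelse(groups == "tumour", "normal", "tumour"),
                      names(groups))
  expect_equal(normfinder_rank(rq, groups = swapped)$table$stability,
               base, tolerance = 1e-12)
})

test_that("stability rises with a gene's intra-group noise", {
  mean_rho <- sapply(c(0.2, 0.8, 1.6), function(noise) {
    mean(sapply(1:50, function(seed) {
      gp <- rbind(gene_plan("probe", 25, intra_sd = noise),
                  gene_plan("r1", 24, intra_sd = 0.3),
                  gene_plan("r2", 26, intra_sd = 0.3),
                  gene_plan("r3", 27, intra_sd = 0.3))
      cfg <- study_config(gp, n_tumour = 6, n_normal = 6,
                          sample_shift_sd = 0.5, replicate_sd = 0.1,
                          n_replicates = 2, seed = 40 + seed)
      x <- sim_to_rq(cfg)
      res <- normfinder_rank(x$rq, groups = x$samples)
      res$table$stability[res$table$gene == "probe"]
    }))
  })
  expect_true(mean_rho[1] < mean_rho[2])
  expect_true(mean_rho[2] < mean_rho[3])
})

test_that("preconditions are enforced", {
  rq <- random_rq(2, 6, seed = 1)
  expect_error(normfinder_rank(rq, groups = nf_groups(3, 3)), "3 genes")
  rq5 <- random_rq(5, 4, seed = 1)
  expect_error(normfinder_rank(rq5, groups = nf_groups(2, 2)),
               ">= 3 samples")
  one_group <- setNames(rep("tumour", 8), paste0("s", 1:8))
  rq8 <- random_rq(4, 8, seed = 2)
  expect_error(normfinder_rank(rq8, groups = one_group), "2 groups")
})
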