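test_that("the global mean profile averages qualifying assays per sample", {
  cq <- matrix(c(20, 25, 30), ncol = 1,
               dimnames = list(c("g1", "g2", "g3"), "s1"))
  prof <- global_mean_profile(agg_from_matrix(cq))
  expect_equal(prof$global_mean_cq, 25)
  expect_equal(prof$n_assays_used, 3L)
})

test_that("the below-cutoff rule excludes Cq at the cutoff (strict <)", {
  cq <- matrix(c(20, 34.9, 35.0), ncol = 1,
               dimnames = list(c("g1", "g2", "g3"), "s1"))
  prof <- global_mean_profile(agg_from_matrix(cq),
                              rule = "detected_below_cutoff", cutoff = 35)
  expect_equal(prof$global_mean_cq, mean(c(20, 34.9)))
  expect_equal(prof$n_assays_used, 2L)
})

test_that("undetected assays never contribute; empty samples are an error", {
  cq <- matrix(c(20, NA, 30,
                 NA, NA, NA), nrow = 3, ncol = 2,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cq[, 2] <- NA
  a <- agg_from_matrix(cq)
  expect_error(global_mean_profile(a), "s2")
  prof <- global_mean_profile(a[a$sample_id == "s1", ])
  expect_equal(prof$global_mean_cq, 25)
})

test_that("virtual assays average member Cqs and behave like assays", {
  cq <- matrix(c(20, 22,
                 30, 32), nrow = 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("s1", "s2")))
  a <- agg_from_matrix(cq)
  va <- make_virtual_assay(a, c("m1", "m2"), "virt")
  expect_equal(va$mean_cq[va$sample_id == "s1"], 25)
  # single member: Cq identical to that member
  v1 <- make_virtual_assay(a, "m1", "alias")
  expect_equal(v1$mean_cq, a$mean_cq[a$assay_id == "m1"])
  expect_error(make_virtual_assay(a, character(), "x"), "empty")
})

test_that("a virtual assay of two constant-ratio genes has geNorm M of 0 with either member", {
  cq <- matrix(c(20, 21, 23,
                 25, 26, 28), nrow = 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  a <- agg_from_matrix(cq)
  both <- rbind(a, make_virtual_assay(a, c("m1", "m2"), "virt"))
  rq <- cq_to_rq(both)
  V <- pairwise_variation_matrix(rq)
  expect_equal(V["virt", "m1"], 0, tolerance = 1e-12)
  expect_equal(V["virt", "m2"], 0, tolerance = 1e-12)
})

test_that("candidates tracking the global mean score zero and rank first", {
  # two samples, all genes move in parallel: every score is 0
  cq <- matrix(c(20, 21,
                 25, 26,
                 30, 31), nrow = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  a <- agg_from_matrix(cq)
  sc <- score_candidates(a, global_mean_profile(a))
  expect_equal(sc$resemblance_score, rep(0, 3))
  expect_equal(sc$assay_id, c("g1", "g2", "g3"))   # lexicographic ties
})

test_that("resemblance scores ignore sample-wide shifts and flag divergent genes", {
  set.seed(8)
  n <- 10
  base <- rnorm(n, 25, 0.3)
  cq <- rbind(tracker = base + 2,
              wobbler = base + rnorm(n, 0, 1.5),
              g3 = base - 1, g4 = base + 0.5)
  colnames(cq) <- paste0("s", 1:n)
  a <- agg_from_matrix(cq)
  sc <- score_candidates(a, global_mean_profile(a), top_k = 1)
  expect_equal(sc$assay_id[sc$rank == nrow(sc)], "wobbler")
  # sample-wide shift leaves every score unchanged
  shifted <- cq
  shifted[, 1] <- shifted[, 1] + 3
  sc2 <- score_candidates(agg_from_matrix(shifted),
                          global_mean_profile(agg_from_matrix(shifted)))
  expect_equal(sc2$resemblance_score[order(sc2$assay_id)],
               sc$resemblance_score[order(sc$assay_id)], tolerance = 1e-12)
})

test_that("a planted stable gene outranks noisy genes in nearly all runs", {
  wins <- 0
  for (seed in 1:100) {
    gp <- rbind(gene_plan("calm", 25, intra_sd = 0),
                gene_plan("n1", 24, intra_sd = 1),
                gene_plan("n2", 26, intra_sd = 1.2),
                gene_plan("n3", 27, intra_sd = 1.5),
                gene_plan("n4", 23, intra_sd = 1))
    cfg <- study_config(gp, n_tumour = 10, n_normal = 10,
                        sample_shift_sd = 0.5, replicate_sd = 0.1,
                        n_replicates = 2, seed = seed)
    agg <- aggregate_replicates(simulate_study(cfg)$dataset)
    sc <- score_candidates(agg, global_mean_profile(agg), top_k = 1)
    if (sc$assay_id[1] == "calm") wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("the global-mean virtual assay is among the most stable on large panels", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n_genes <- 50; n_samples <- 12
    base <- rnorm(n_samples, 0, 0.6)      # sample-wide shifts
    cq <- t(sapply(seq_len(n_genes), function(i)
      rnorm(1, 27, 2) + base + rnorm(n_samples, 0, runif(1, 0.2, 1.2))))
    dimnames(cq) <- list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples)))
    a <- agg_from_matrix(cq)
    withpanel <- rbind(a, make_virtual_assay(a, rownames(cq), "globalmean"))
    rq <- cq_to_rq(withpanel)
    V <- pairwise_variation_matrix(rq)
    m <- sapply(rownames(V), function(g) mean(V[g, setdiff(rownames(V), g)]))
    if (m["globalmean"] <= median(m[names(m) != "globalmean"]))
      hits <- hits + 1
  }
  expect_gte(hits, 48)
})
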