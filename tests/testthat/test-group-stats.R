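two_group_sheet <- function(n_case, n_ctrl) {
  data.frame(sample_id = paste0("s", seq_len(n_case + n_ctrl)),
             group = rep(c("tumour", "normal"), c(n_case, n_ctrl)),
             stringsAsFactors = FALSE)
}

test_that("identical groups give t = 0, p = 1 in the pre-check", {
  cq <- matrix(rep(c(24, 25, 26), 2), nrow = 1,
               dimnames = list("g", paste0("s", 1:6)))
  res <- differential_precheck(agg_from_matrix(cq), two_group_sheet(3, 3))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_true(res$pass)
})

test_that("the pre-check detects a planted shift with high power", {
  rejections <- sapply(1:100, function(seed) {
    gp <- gene_plan("probe", 25, group_shift_log2 = 1, intra_sd = 0.5)
    cfg <- study_config(gp, n_tumour = 35, n_normal = 39,
                        sample_shift_sd = 0, replicate_sd = 0.15,
                        n_replicates = 3, seed = 2000 + seed)
    sim <- simulate_study(cfg)
    res <- differential_precheck(aggregate_replicates(sim$dataset),
                                 sim$dataset$samples)
    res$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("Bartlett screening matches the textbook statistic", {
  # equal variances: statistic 0, p = 1
  cq <- rbind(g1 = c(20, 21, 22, 23),
              g2 = c(30, 31, 32, 33) + 5)
  colnames(cq) <- paste0("s", 1:4)
  res <- variance_homogeneity(agg_from_matrix(cq))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  # three-gene instance against the hand formula
  set.seed(31)
  cq3 <- rbind(a = rnorm(8, 25, 0.4), b = rnorm(8, 27, 1.2),
               c = rnorm(8, 23, 2.5))
  colnames(cq3) <- paste0("s", 1:8)
  res3 <- variance_homogeneity(agg_from_matrix(cq3))
  expect_equal(res3$statistic,
               oracle_bartlett(list(cq3["a", ], cq3["b", ], cq3["c", ])),
               tolerance = 1e-10)
  # zero-variance gene is a named error
  cq0 <- rbind(flat = rep(25, 4), ok = c(24, 25, 26, 27))
  colnames(cq0) <- paste0("s", 1:4)
  expect_error(variance_homogeneity(agg_from_matrix(cq0)), "flat")
})

test_that("Bartlett rejection rate under equal variances is near alpha", {
  rejections <- sapply(1:400, function(seed) {
    set.seed(9000 + seed)
    cq <- matrix(rnorm(4 * 20, 25, 1), 4, 20,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:20)))
    variance_homogeneity(agg_from_matrix(cq))$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("equivalence bounds follow the fold-change cutoff", {
  cq <- matrix(rnorm(8, 25, 0.1), nrow = 1,
               dimnames = list("g", paste0("s", 1:8)))
  a <- agg_from_matrix(cq)
  sheet <- two_group_sheet(4, 4)
  expect_equal(round(equivalence_test(a, sheet,
                                      fold_change_cutoff = 3)$bound, 2), 1.58)
  expect_equal(equivalence_test(a, sheet, fold_change_cutoff = 2)$bound, 1)
  expect_error(equivalence_test(a, sheet, fold_change_cutoff = 1),
               "fold_change_cutoff")
})

test_that("equivalence verdicts follow CI inclusion and are label-symmetric", {
  set.seed(12)
  n <- 20
  stable <- 25 + rnorm(2 * n, 0, 0.3)
  shifted <- c(22 + rnorm(n, 0, 0.3), 25 + rnorm(n, 0, 0.3))
  cq <- rbind(stable = stable, shifted = shifted)
  colnames(cq) <- paste0("s", 1:(2 * n))
  a <- agg_from_matrix(cq)
  sheet <- two_group_sheet(n, n)
  res <- equivalence_test(a, sheet)
  expect_true(res$equivalent[res$assay_id == "stable"])
  expect_false(res$equivalent[res$assay_id == "shifted"])
  expect_true(all(res$ci_low <= res$mean_log2_diff &
                    res$mean_log2_diff <= res$ci_high))
  # tumour is up in log2 expression for the gene with lowered tumour Cq
  expect_gt(res$mean_log2_diff[res$assay_id == "shifted"], 0)
  # swapping group labels flips the sign but not the verdict
  swapped <- sheet
  swapped$group <- ifelse(swapped$group == "tumour", "normal", "tumour")
  res2 <- equivalence_test(a, swapped)
  expect_equal(res2$equivalent, res$equivalent)
  expect_equal(res2$mean_log2_diff, -res$mean_log2_diff, tolerance = 1e-12)
})

test_that("tightening the cutoff or widening the CI never creates equivalence", {
  set.seed(77)
  cq <- matrix(25 + rnorm(30, 0, 1.2), nrow = 1,
               dimnames = list("g", paste0("s", 1:30)))
  a <- agg_from_matrix(cq)
  sheet <- two_group_sheet(15, 15)
  verdict <- function(fc, lvl)
    equivalence_test(a, sheet, fold_change_cutoff = fc,
                     ci_level = lvl)$equivalent
  for (lvl in c(0.8, 0.9, 0.95)) {
    v <- sapply(c(1.2, 1.5, 2, 3), function(fc) verdict(fc, lvl))
    expect_true(all(diff(v) >= 0))     # monotone in the cutoff
  }
  for (fc in c(1.5, 2, 3)) {
    v <- sapply(c(0.95, 0.9, 0.8), function(lvl) verdict(fc, lvl))
    expect_true(all(diff(v) >= 0))     # monotone in the CI level
  }
})

test_that("paired equivalence uses per-patient differences", {
  set.seed(3)
  n <- 10
  patient_effect <- rnorm(n, 0, 2)
  cq <- matrix(c(25 + patient_effect + rnorm(n, 0, 0.1),
                 25 + patient_effect + rnorm(n, 0, 0.1)), nrow = 1,
               dimnames = list("g", paste0("s", 1:(2 * n))))
  sheet <- two_group_sheet(n, n)
  sheet$patient_id <- rep(paste0("p", 1:n), 2)
  a <- agg_from_matrix(cq)
  unpaired <- equivalence_test(a, sheet)
  paired <- equivalence_test(a, sheet, paired = TRUE)
  # pairing removes the patient effect: far tighter interval
  expect_lt(paired$ci_high - paired$ci_low,
            (unpaired$ci_high - unpaired$ci_low) / 2)
})

test_that("normality screening flags heavy tails but not Normal data", {
  normal_ok <- sapply(1:100, function(seed) {
    set.seed(seed)
    cq <- matrix(rnorm(40, 25, 1), nrow = 1,
                 dimnames = list("g", paste0("s", 1:40)))
    normality_check(agg_from_matrix(cq))$flag == "ok"
  })
  expect_gte(mean(normal_ok), 0.90)
  heavy_flagged <- sapply(1:100, function(seed) {
    set.seed(seed)
    cq <- matrix(25 + rt(200, df = 1), nrow = 1,
                 dimnames = list("g", paste0("s", 1:200)))
    cq <- abs(cq) + 1    # keep Cq positive; preserves heavy tails
    normality_check(agg_from_matrix(cq))$flag == "non_normal"
  })
  expect_gte(mean(heavy_flagged), 0.95)
  # constant values: degenerate, not tested
  cq <- matrix(25, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  expect_equal(normality_check(agg_from_matrix(cq))$flag, "degenerate")
})
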