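make_tpm <- function(vals_ctrl, vals_trt, reps = 2) {
  n <- length(vals_ctrl)
  m <- cbind(matrix(rep(vals_ctrl, reps), ncol = reps),
             matrix(rep(vals_trt, reps), ncol = reps))
  rownames(m) <- paste0("g", seq_len(n))
  m
}

test_that("response is zero when treatment equals control", {
  m <- make_tpm(c(1, 10, 100), c(1, 10, 100))
  labels <- rep(c("control", "treatment"), each = 2)
  p <- response_vs_baseline(m, labels, "control", "treatment")
  expect_true(all(abs(p$response) < 1e-12))
})

test_that("a gene at the grand-mean control level has baseline zero", {
  vals <- c(2, 8, 5)   # grand mean (with pseudocount on both sides) ~ third
  m <- make_tpm(vals, vals)
  labels <- rep(c("control", "treatment"), each = 2)
  p <- response_vs_baseline(m, labels, "control", "treatment",
                            pseudocount = 0.5)
  grand <- mean(vals + 0.5)
  at_mean <- make_tpm(c(2, 8, grand - 0.5), c(2, 8, grand - 0.5))
  p2 <- response_vs_baseline(at_mean, labels, "control", "treatment",
                             pseudocount = 0.5)
  expect_equal(p2$baseline[3], 0, tolerance = 1e-12)
})

test_that("profiles are invariant to global rescaling up to pseudocount", {
  set.seed(3)
  m <- matrix(rlnorm(400, 3, 1), ncol = 4,
              dimnames = list(paste0("g", 1:100), NULL))
  labels <- rep(c("control", "treatment"), each = 2)
  p1 <- response_vs_baseline(m, labels, "control", "treatment",
                             pseudocount = 1e-6)
  p2 <- response_vs_baseline(m * 10, labels, "control", "treatment",
                             pseudocount = 1e-6)
  expect_equal(p1$baseline, p2$baseline, tolerance = 1e-4)
  expect_equal(p1$response, p2$response, tolerance = 1e-4)
})

test_that("trend statistic is tie-aware Spearman correlation", {
  p <- data.frame(baseline = c(3, 2, 1), response = c(1, 2, 3))
  expect_equal(trend_statistic(p)$rho, -1)
  # duplicated rows leave rho unchanged under midrank handling, and the
  # value matches a from-definition rank computation
  set.seed(8)
  b <- sample(rep(1:20, 2)); r <- 0.3 * b + rnorm(40)
  p2 <- data.frame(baseline = b, response = r)
  p2dup <- rbind(p2, p2)
  expect_equal(trend_statistic(p2)$rho, oracle_spearman(b, r))
  expect_equal(trend_statistic(p2dup)$rho,
               oracle_spearman(c(b, b), c(r, r)))
  # degenerate input
  expect_true(is.na(trend_statistic(
    data.frame(baseline = c(1, 1, 1), response = 1:3))$rho))
  expect_error(trend_statistic(data.frame(baseline = 1, response = 1)),
               "at least 3")
})

test_that("mean-reverting generator plants the negative trend", {
  p_rev <- response_vs_baseline(
    simulate_expression_matrix(synthetic_config(seed = 4, n_genes = 2000,
                                                kappa = 0.5)),
    rep(c("control", "treatment"), each = 3), "control", "treatment")
  expect_lt(trend_statistic(p_rev)$rho, -0.3)

  p_null <- response_vs_baseline(
    simulate_expression_matrix(synthetic_config(seed = 4, n_genes = 5000,
                                                kappa = 0)),
    rep(c("control", "treatment"), each = 3), "control", "treatment")
  expect_lt(abs(trend_statistic(p_null)$rho), 0.1)
})

test_that("log2 relative expression follows -(Ct_x - Ct_ref)", {
  ct <- data.frame(sample = rep("s1", 3),
                   gene = c("GAPDH", "X", "Y"),
                   ct = c(20, 25, 18), stringsAsFactors = FALSE)
  out <- log2_relative_expression(ct)
  expect_equal(out$log2re[out$gene == "X"], -5)
  expect_equal(out$log2re[out$gene == "Y"], 2)
  # equal Ct gives zero
  ct0 <- data.frame(sample = "s", gene = c("GAPDH", "Z"), ct = c(21, 21))
  expect_equal(log2_relative_expression(ct0)$log2re, 0)
})

test_that("log2RE is antitone in Ct and translation-invariant", {
  base <- data.frame(sample = "s", gene = c("GAPDH", "X"), ct = c(20, 24))
  shifted <- transform(base, ct = ct + 3)
  expect_equal(log2_relative_expression(base)$log2re,
               log2_relative_expression(shifted)$log2re)
  higher <- data.frame(sample = "s", gene = c("GAPDH", "X"), ct = c(20, 26))
  expect_lt(log2_relative_expression(higher)$log2re,
            log2_relative_expression(base)$log2re)
})

test_that("a missing reference sample is reported by name", {
  ct <- data.frame(sample = c("s1", "s2"), gene = c("GAPDH", "X"),
                   ct = c(20, 24), stringsAsFactors = FALSE)
  expect_error(log2_relative_expression(ct), "s2")
})

test_that("planted Ct effects are recovered as log2RE differences", {
  cfg <- synthetic_config(seed = 10, ct_effects = c(TG1 = -2, TG2 = 0))
  ct <- simulate_ct_table(cfg, n_reps = 4)
  l2 <- log2_relative_expression(ct)
  l2$condition <- ct$condition[match(paste(l2$sample, l2$gene),
                                     paste(ct$sample, ct$gene))]
  dmean <- function(g) {
    x <- l2[l2$gene == g, ]
    mean(x$log2re[x$condition == "treatment"]) -
      mean(x$log2re[x$condition == "control"])
  }
  expect_equal(dmean("TG1"), 2, tolerance = 0.3)
  expect_equal(dmean("TG2"), 0, tolerance = 0.3)
})
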