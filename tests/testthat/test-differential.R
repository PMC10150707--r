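test_that("paired_t matches the textbook formula and t.test", {
  d <- c(0.5, -0.2, 0.3, 0.1)
  m <- matrix(0, 1, 8, dimnames = list("chr1:1", paste0("S", 1:8)))
  m[1, 5:8] <- d
  res <- paired_t(m, toy_pairs())
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), 3)
  expect_equal(res$t_stat, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$df, 3L)
  tt <- t.test(d)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate zero-variance sites get p = 1 and a flag", {
  m <- matrix(0, 1, 8, dimnames = list("chr1:1", paste0("S", 1:8)))
  m[1, 5:8] <- 1   # constant differences
  res <- paired_t(m, toy_pairs())
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("paired_t validates its design", {
  m <- make_null_logcpm(5, 4)
  expect_equal(paired_t(m, data.frame(sample_A = c("S1", "S2"),
                                      sample_B = c("S3", "S4")))$df[1],
               1L)  # 2 pairs -> df 1
  expect_error(paired_t(m, data.frame(sample_A = "S1",
                                      sample_B = "S2")),
               "at least 2")
  expect_error(paired_t(m, data.frame(sample_A = c("S1", "S1"),
                                      sample_B = c("S2", "S3"))),
               "more than one pair")
})

test_that("negating all values negates t and preserves two-sided p", {
  m <- make_null_logcpm(200, seed = 5)
  res1 <- paired_t(m, toy_pairs())
  res2 <- paired_t(-m, toy_pairs())
  expect_equal(res2$t_stat, -res1$t_stat)
  expect_equal(res2$p_value, res1$p_value)
})

test_that("type-I error is calibrated on a Gaussian null", {
  m <- make_null_logcpm(10000, seed = 42)
  res <- paired_t(m, toy_pairs())
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.043)
  expect_lte(rate, 0.057)
})

test_that("log2_fold_change is the group-mean difference, antisymmetric", {
  m <- matrix(c(rep(2, 4), rep(2 - 1.89, 4)), 1,
              dimnames = list("chr1:1", paste0("S", 1:8)))
  fc <- log2_fold_change(m, paste0("S", 1:4), paste0("S", 5:8))
  expect_equal(as.numeric(fc), -1.89)
  expect_equal(as.numeric(log2_fold_change(m, paste0("S", 5:8),
                                           paste0("S", 1:4))), 1.89)
  expect_equal(attr(fc, "contrast"), "S5+S6+S7+S8_vs_S1+S2+S3+S4")
  expect_error(log2_fold_change(m, character(0), "S1"), "non-empty")
})

test_that("moderated t reduces to the classical statistic when variances agree", {
  set.seed(20)
  n <- 50
  effects <- rnorm(n)
  s_sq <- rep(0.25, n)
  mod <- moderated_t(effects, s_sq, df = 3, stderr_scale = 0.5)
  expect_equal(mod$s_post_sq, rep(0.25, n), tolerance = 1e-9)
  t_classical <- effects / (0.5 * 0.5)
  expect_equal(mod$t_mod, t_classical, tolerance = 1e-9)
  # forced infinite prior: every posterior variance is s0_sq
  mod2 <- moderated_t(effects, s_sq + rnorm(n, 0, 1e-3), df = 3,
                      stderr_scale = 0.5,
                      prior = list(d0 = Inf, s0_sq = 0.3))
  expect_equal(mod2$s_post_sq, rep(0.3, n))
})

test_that("EB prior recovery on a scaled inverse-chi-square simulation", {
  set.seed(9)
  d0 <- 4; s0_sq <- 0.04; df <- 3
  true_var <- s0_sq * d0 / rchisq(5000, d0)
  s_sq <- true_var * rchisq(5000, df) / df
  pr <- estimate_eb_prior(s_sq, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.30)
  expect_lt(abs(pr$s0_sq - s0_sq) / s0_sq, 0.10)
})

test_that("EB prior agrees with the reference shrinkage implementation", {
  skip_if_not_installed("limma")
  set.seed(23)
  s_sq <- 0.05 * 5 / rchisq(2000, 5) * rchisq(2000, 3) / 3
  pr <- estimate_eb_prior(s_sq, 3)
  ref <- limma::squeezeVar(s_sq, df = 3)
  expect_equal(pr$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, ref$var.prior, tolerance = 1e-6)
  mod <- moderated_t(rep(1, 2000), s_sq, 3, 1, prior = pr)
  expect_equal(mod$s_post_sq, ref$var.post, tolerance = 1e-6)
})

test_that("moderated and classical rankings agree under homogeneous variance", {
  # with homogeneous true variances the shrinkage target is the common
  # variance; once per-site estimates concentrate (here 50 pairs), the
  # two statistics order the sites the same way
  np <- 50
  m <- make_null_logcpm(2000, n_samples = 2 * np, seed = 77)
  pairs <- data.frame(sample_A = paste0("S", 1:np),
                      sample_B = paste0("S", np + 1:np))
  res <- paired_t(m, pairs)
  d <- m[, pairs$sample_B] - m[, pairs$sample_A]
  s_sq <- apply(d, 1, var)
  mod <- moderated_t(res$mean_diff, s_sq, np - 1, 1 / sqrt(np))
  expect_gt(cor(abs(res$t_stat), abs(mod$t_mod),
                method = "spearman"), 0.99)
})

test_that("moderated_t rejects unusable inputs", {
  expect_error(estimate_eb_prior(rep(0, 10), 3), "zero")
  expect_error(estimate_eb_prior(0.5, 3), "2 sites")
})

test_that("volcano classification follows the strict FC/p rule", {
  expect_equal(as.character(classify_volcano(-1.89, 8.8e-6)), "down")
  expect_equal(as.character(classify_volcano(0.5, 0.001)), "ns")
  expect_equal(as.character(classify_volcano(-1.0, 0.01)), "ns")
  expect_equal(as.character(classify_volcano(1.2, 0.04)), "up")
  expect_equal(as.character(classify_volcano(1.2, 0.05)), "ns")
})

test_that("BH adjustment matches the hand step-up and is stable", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # independent hand step-up oracle on random input
  set.seed(2)
  p <- runif(100)
  hand <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_fdr(p), hand(p), tolerance = 1e-14)
  # permutation equivariance
  perm <- sample(100)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("direction summary reports exact fractions", {
  diff <- data.frame(log2_fc = c(-1, -2, -0.5), p_value = c(0.01, 0.2, 0.03))
  s <- summarize_direction(diff)
  expect_equal(s$frac_negative_overall, 1.0)
  expect_equal(s$frac_negative_significant, 1.0)
  expect_error(summarize_direction(diff[0, ]), "empty")
})

test_that("null simulation gives a balanced sign fraction; a planted shift skews it", {
  des <- sim_design(seed = 301, n_sites = 10000)
  smp <- simulate_site_positions(10000, seed = 301)
  # planted null
  sim0 <- simulate_counts(smp, des,
                          sim_effects(global_shift = 0, frac_affected = 0))
  norm0 <- normalize_pipeline(sim0$counts, des$sample_sheet)
  diff0 <- differential_sites(norm0$logcpm, norm0$sample_sheet,
                              c("NSC", "iPSC"))
  s0 <- summarize_direction(diff0)
  expect_lt(abs(s0$frac_negative_overall - 0.5), 0.02)
  # global hypo shift: significant sites are more negative than overall
  sim1 <- simulate_counts(smp, sim_design(seed = 302, n_sites = 10000),
                          sim_effects(global_shift = -0.3,
                                      frac_affected = 0))
  norm1 <- normalize_pipeline(sim1$counts, des$sample_sheet)
  diff1 <- differential_sites(norm1$logcpm, norm1$sample_sheet,
                              c("NSC", "iPSC"))
  s1 <- summarize_direction(diff1)
  expect_gt(s1$frac_negative_significant, s1$frac_negative_overall)
})

test_that("unpaired Welch and pooled t are available for unknown designs", {
  set.seed(6)
  m <- make_null_logcpm(100, seed = 6)
  w <- unpaired_t(m, paste0("S", 1:4), paste0("S", 5:8))
  p <- unpaired_t(m, paste0("S", 1:4), paste0("S", 5:8), pooled = TRUE)
  i <- 7
  tt <- t.test(m[i, 5:8], m[i, 1:4])
  expect_equal(w$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$p_value[i], tt$p.value, tolerance = 1e-12)
  tt2 <- t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE)
  expect_equal(p$p_value[i], tt2$p.value, tolerance = 1e-12)
})
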