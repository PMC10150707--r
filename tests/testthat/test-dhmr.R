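test_that("one-sided p-values are complementary and match a tail oracle", {
  expect_equal(one_sided_p(0, 3, "less"), 0.5)
  expect_equal(one_sided_p(0, 3, "greater"), 0.5)
  set.seed(1)
  t <- rnorm(20, sd = 2)
  expect_equal(one_sided_p(t, 5, "less") + one_sided_p(t, 5, "greater"),
               rep(1, 20))
  # numerical-integration oracle for the upper tail at t = 2, df = 3
  dens <- function(x) dt(x, 3)
  oracle <- integrate(dens, 2, Inf, rel.tol = 1e-13)$value
  expect_equal(one_sided_p(2, 3, "greater"), oracle, tolerance = 1e-12)
  expect_equal(one_sided_p(c(1, 2), c(3, 3), "less",
                           degenerate = c(TRUE, FALSE))[1], 0.5)
  expect_error(one_sided_p(1, 0.5), "freedom")
})

test_that("fisher_windows computes the combined statistic per window", {
  sites <- data.frame(chrom = "chr1",
                      pos = seq(1, by = 100, length.out = 9))
  w1 <- fisher_windows(sites, p_less = rep(1, 9))$windows
  expect_equal(w1$x2, 0)
  expect_equal(w1$combined_p, 1)
  w2 <- fisher_windows(sites, p_less = rep(0.5, 9))$windows
  expect_equal(w2$x2, -2 * 9 * log(0.5), tolerance = 1e-12)
  expect_equal(w2$x2, 12.4766, tolerance = 1e-4)
  expect_equal(w2$combined_p, pchisq(12.476649, 18, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(w2$df, 18L)
})

test_that("windows spanning 50 kb or more are skipped with a tally", {
  sites <- data.frame(chrom = "chr1",
                      pos = c(seq(1, by = 100, length.out = 8), 60001))
  fw <- fisher_windows(sites, p_less = rep(0.5, 9))
  expect_equal(nrow(fw$windows), 0L)
  expect_equal(fw$n_skipped_wide, 1L)
  expect_error(fisher_windows(sites[c(2, 1, 3:9), ],
                              p_less = rep(0.5, 9)), "sorted")
  expect_error(fisher_windows(sites, p_less = rep(0.5, 5)), "length")
})

test_that("combined p equals an independent gamma survival oracle", {
  set.seed(101)
  k <- 9
  for (i in 1:1000) {
    p <- runif(k)
    sites <- data.frame(chrom = "chr1",
                        pos = seq(1, by = 10, length.out = k))
    cp <- fisher_windows(sites, p_less = p)$windows$combined_p
    # chi-square(2k) survival == gamma(shape k, scale 2) survival
    oracle <- pgamma(-2 * sum(log(p)), shape = k, scale = 2,
                     lower.tail = FALSE)
    expect_equal(cp, oracle, tolerance = 1e-10)
  }
})

test_that("decreasing a member p never increases the combined p", {
  set.seed(55)
  sites <- data.frame(chrom = "chr1",
                      pos = seq(1, by = 10, length.out = 9))
  for (i in 1:50) {
    p <- runif(9)
    base <- fisher_windows(sites, p_less = p)$windows$combined_p
    j <- sample(9, 1)
    p[j] <- p[j] * runif(1)
    lower <- fisher_windows(sites, p_less = p)$windows$combined_p
    expect_lte(lower, base)
  }
})

test_that("windows never cross chromosomes and counts add up", {
  set.seed(14)
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), c(30, 20)),
                      pos = c(sort(sample(1e6, 30)),
                              sort(sample(1e6, 20))))
  p <- runif(50)
  fw <- fisher_windows(sites, p_less = p,
                       params = dhmr_params(max_span = 10^9))
  expect_equal(nrow(fw$windows) + fw$n_skipped_wide, (30 - 8) + (20 - 8))
  expect_true(all(fw$windows$end > fw$windows$start))
  per_chr <- table(fw$windows$chrom)
  expect_equal(unname(per_chr["chr1"]) + unname(per_chr["chr2"]),
               nrow(fw$windows))
})

test_that("window-level null rejection over non-overlapping bins is calibrated", {
  set.seed(33)
  n <- 9000
  sites <- data.frame(chrom = "chr1", pos = seq(1, by = 10, length.out = n))
  p <- runif(n)
  fw <- fisher_windows(sites, p_less = p)
  nonov <- fw$windows[fw$windows$first_index %% 9 == 1, ]
  rate <- mean(nonov$combined_p < 0.05)
  expect_gte(rate, 0.036)
  expect_lte(rate, 0.064)
})

test_that("Bonferroni bin counts reproduce the non-overlapping rule", {
  expect_equal(bonferroni_bins(124603, 9)$n_bins, 13845L)
  expect_equal(bonferroni_bins(101673, 9)$n_bins, 11297L)
  b <- bonferroni_bins(9, 9)
  expect_equal(b$n_bins, 1L)
  expect_equal(b$threshold, 0.05)
  expect_error(bonferroni_bins(5, 9), "at least")
})

test_that("collapse_windows keeps the best window per overlapping chain", {
  w <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(100, 200, 100), end = c(900, 1000, 900),
                  span_bp = 801, first_index = c(1, 2, 50),
                  x2 = 1, df = 18,
                  combined_p = c(1e-3, 1e-4, 5e-3),
                  direction = "less", stringsAsFactors = FALSE)
  loci <- collapse_windows(w, k = 9)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$combined_p, c(1e-4, 5e-3))
  expect_equal(loci$size_bp, c(801L, 801L))
  # leftmost wins ties
  w2 <- w[1:2, ]; w2$combined_p <- 1e-3
  expect_equal(collapse_windows(w2, k = 9)$first_index, 1)
})

test_that("a planted 9-site run collapses to one locus containing it", {
  set.seed(71)
  n <- 400
  sites <- data.frame(chrom = "chr1",
                      pos = seq(1, by = 500, length.out = n))
  p <- runif(n)
  run <- 200:208
  p[run] <- runif(9, 0, 0.01)
  fw <- fisher_windows(sites, p_less = p)
  loci <- collapse_windows(fw)
  top <- loci[1, ]
  expect_lte(top$start, sites$pos[run[1]])
  expect_gte(top$end, sites$pos[run[9]])
  # loci are disjoint in member-site index space
  expect_true(all(diff(sort(loci$first_index)) >= 9))
})

test_that("dhmr_scan wires one-sided p-values through to collapsed loci", {
  des <- sim_design(seed = 401, n_sites = 3000)
  smp <- simulate_site_positions(3000, n_chrom = 2, seed = 401)
  pd <- data.frame(chrom = "chr1", start_index = 100L, k = 9L,
                   effect = -2)
  sim <- simulate_counts(smp, des, sim_effects(planted_dhmrs = pd))
  norm <- normalize_pipeline(sim$counts, des$sample_sheet)
  diff <- differential_sites(norm$logcpm, norm$sample_sheet,
                             c("NSC", "iPSC"))
  scan <- dhmr_scan(diff)
  planted_pos <- as.integer(sub(".*:", "",
                                sim$truth$site[!is.na(sim$truth$dhmr_id)]))
  top <- scan$loci[1, ]
  expect_equal(top$chrom, "chr1")
  expect_lte(top$start, max(planted_pos))
  expect_gte(top$end, min(planted_pos))
  expect_equal(scan$bonferroni$n_bins,
               as.integer(ceiling(nrow(diff) / 9)))
})

test_that("best_of_both reports the smaller combined p with its direction", {
  sites <- data.frame(chrom = "chr1",
                      pos = seq(1, by = 10, length.out = 9))
  pl <- rep(0.9, 9)
  w <- fisher_windows(sites, p_less = pl, p_greater = 1 - pl,
                      params = dhmr_params(direction = "best_of_both"))
  expect_equal(w$windows$direction, "greater")
  expect_equal(w$windows$x2, -2 * 9 * log(0.1), tolerance = 1e-12)
})
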