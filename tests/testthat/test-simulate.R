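test_that("genotypes are drawn under Hardy-Weinberg at the requested MAF", {
  g <- simulate_genotypes(10000, 0.1, seed = 11)
  expect_true(all(g %in% 0:2))
  expect_lt(abs(mean(g) / 2 - 0.1), 0.01)  # 3-sigma binomial bound
  het <- mean(g == 1)
  expect_lt(abs(het - 2 * 0.1 * 0.9), 0.015)
  expect_true(all(simulate_genotypes(4, 0.5, seed = 1) %in% 0:2))
})

test_that("genotype generation is deterministic and rejects bad MAFs", {
  expect_identical(simulate_genotypes(50, c(a = 0.5, b = 0.2), seed = 3),
                   simulate_genotypes(50, c(a = 0.5, b = 0.2), seed = 3))
  expect_error(simulate_genotypes(10, 0.6), "maf")
  expect_error(simulate_genotypes(10, 0), "maf")
})

test_that("simulated genotype frequencies pass a HWE goodness-of-fit sweep", {
  m <- 0.3
  expected_p <- c((1 - m)^2, 2 * m * (1 - m), m^2)
  pass <- vapply(1:200, function(i) {
    g <- simulate_genotypes(5000, m, seed = 1000 + i)
    obs <- tabulate(g + 1L, 3L)
    suppressWarnings(stats::chisq.test(obs, p = expected_p)$p.value) > 0.001
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("onset ages are log-normal around the genotype-group median", {
  g <- simulate_genotypes(5000, 0.3, seed = 5)
  ages <- simulate_onset_ages(g, 40, effect = 1, dispersion = 0.5, seed = 6)
  expect_true(all(ages > 0))
  expect_lt(abs(median(ages) / 40 - 1), 0.05)

  ages2 <- simulate_onset_ages(g, 40, effect = c(1, 0.4), dispersion = 0.5,
                               seed = 7)
  ratio <- median(ages2[g >= 1]) / median(ages2[g == 0])
  expect_lt(abs(ratio - 0.4), 0.05)

  # vanishing-noise limit: ages collapse onto baseline * effect
  ages3 <- simulate_onset_ages(c(0L, 1L, 2L), 10, effect = c(1, 0.5, 0.25),
                               dispersion = 1e-10, seed = 8)
  expect_equal(ages3, c(10, 5, 2.5), tolerance = 1e-6)

  expect_error(simulate_onset_ages(g, 40, effect = 0), "positive")
  expect_error(simulate_onset_ages(g, 40, dispersion = -1), "positive")
})

test_that("expression-survival generator plants hazards and hits the censoring rate", {
  sim <- simulate_expression_survival(10, 2000, censoring_rate = 0.3,
                                      seed = 9)
  expect_lt(abs(mean(sim$clinical$endpoint_event == 0) - 0.3), 0.05)

  sim0 <- simulate_expression_survival(5, 200, censoring_rate = 0, seed = 10)
  expect_true(all(sim0$clinical$endpoint_event == 1L))

  expect_error(simulate_expression_survival(5, 50, censoring_rate = 1),
               "censoring_rate")
  expect_error(simulate_expression_survival(
    5, 50, planted = data.frame(gene = 1, hazard_ratio = -2,
                                cutpoint_quantile = 0.5)), "positive")
  expect_error(simulate_expression_survival(
    5, 50, planted = data.frame(gene = "nope", hazard_ratio = 2,
                                cutpoint_quantile = 0.5)), "planted")
})

test_that("log-rank on the true dichotomy is calibrated under the null and powered under HR 4", {
  # type-I error of the log-rank test at hazard_ratio = 1
  rej <- vapply(1:200, function(i) {
    s <- simulate_expression_survival(
      1, 100, planted = data.frame(gene = 1, hazard_ratio = 1,
                                   cutpoint_quantile = 0.5),
      censoring_rate = 0.3, seed = 2000 + i)
    lr <- logrank_test(s$clinical$endpoint_time, s$clinical$endpoint_event,
                       ifelse(s$truth[1, ], "high", "low"))
    lr$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)  # 3-sigma band around 5% over 200 replicates
  expect_lt(mean(rej), 0.10)

  pow <- vapply(1:100, function(i) {
    s <- simulate_expression_survival(
      1, 120, planted = data.frame(gene = 1, hazard_ratio = 4,
                                   cutpoint_quantile = 0.5),
      censoring_rate = 0.3, seed = 3000 + i)
    lr <- logrank_test(s$clinical$endpoint_time, s$clinical$endpoint_event,
                       ifelse(s$truth[1, ], "high", "low"))
    lr$p < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.90)
})

test_that("haplotype panels realize the requested block LD structure", {
  pair_r2 <- function(hap, i, j) {
    a <- hap[, i] == 1; b <- hap[, j] == 1
    r_squared(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)))
  }
  # perfect LD: exact column copies
  hap1 <- simulate_haplotype_panel(
    data.frame(n_snps = 3, target_r2 = 1), 100, seed = 1)
  expect_identical(unname(hap1[, 1]), unname(hap1[, 2]))
  expect_equal(pair_r2(hap1, 1, 3), 1)
  # independence
  hap0 <- simulate_haplotype_panel(
    data.frame(n_snps = 2, target_r2 = 0), 5000, seed = 2)
  expect_lt(pair_r2(hap0, 1, 2), 0.01)
  # intermediate targets recovered within +-0.1; blocks independent
  hap <- simulate_haplotype_panel(
    data.frame(n_snps = c(2, 2), target_r2 = c(0.9, 0.5)), 2000, seed = 3)
  expect_lt(abs(pair_r2(hap, 1, 2) - 0.9), 0.1)
  expect_lt(abs(pair_r2(hap, 3, 4) - 0.5), 0.1)
  expect_lt(pair_r2(hap, 2, 3), 0.05)

  expect_identical(
    simulate_haplotype_panel(data.frame(n_snps = 2, target_r2 = .5), 50,
                             seed = 4),
    simulate_haplotype_panel(data.frame(n_snps = 2, target_r2 = .5), 50,
                             seed = 4))
  expect_error(simulate_haplotype_panel(
    data.frame(n_snps = 2, target_r2 = 1.2), 100), "target_r2")
  expect_error(simulate_haplotype_panel(
    data.frame(n_snps = 2, target_r2 = .5), 5), "even")
})

test_that("haplotype pairing into diploid genotypes preserves the panel", {
  hap <- simulate_haplotype_panel(
    data.frame(n_snps = 3, target_r2 = 0.8), 40, seed = 5)
  g <- haplotypes_to_genotypes(hap)
  expect_equal(dim(g), c(20, 3))
  expect_true(all(g %in% 0:2))
  expect_identical(attr(g, "panel"), attr(hap, "panel"))
})
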