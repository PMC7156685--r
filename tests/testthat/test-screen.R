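test_that("split plans partition the samples at the requested ratio", {
  ids10 <- paste0("S", 1:10)
  plan <- make_splits(ids10, n_splits = 10, seed = 1)
  expect_equal(unname(colSums(plan$assignments)), rep(5L, 10))
  # odd n: discovery gets the extra sample in every replicate
  plan11 <- make_splits(paste0("S", 1:11), n_splits = 10, seed = 2)
  expect_equal(unname(colSums(plan11$assignments)), rep(6L, 10))
  # each replicate is a partition: union is everything, halves disjoint
  for (s in 1:10) {
    disc <- rownames(plan$assignments)[plan$assignments[, s]]
    val <- rownames(plan$assignments)[!plan$assignments[, s]]
    expect_setequal(c(disc, val), ids10)
    expect_length(intersect(disc, val), 0)
  }
  expect_identical(make_splits(ids10, seed = 7)$assignments,
                   make_splits(ids10, seed = 7)$assignments)
  expect_error(make_splits(paste0("S", 1:3)), "at least 4")
})

test_that("the split screen calls a strongly planted gene and spares nulls", {
  for (r in 1:3) {
    sim <- simulate_expression_survival(
      16, 100, planted = data.frame(gene = 1, hazard_ratio = 10,
                                    cutpoint_quantile = 0.5),
      censoring_rate = 0.2, seed = 800 + r)
    res <- run_split_screen(sim$expression, sim$clinical, seed = 900 + r)
    expect_true(res$is_hit[res$gene == "gene_1"])
    expect_equal(res$hit_count[res$gene == "gene_1"], 10L)
    expect_lt(mean(res$hit_count[res$gene != "gene_1"]), 2)
  }
})

test_that("an unreachable hit threshold yields no hits", {
  sim <- simulate_expression_survival(
    8, 60, planted = data.frame(gene = 1, hazard_ratio = 10,
                                cutpoint_quantile = 0.5),
    censoring_rate = 0.2, seed = 21)
  res <- run_split_screen(sim$expression, sim$clinical,
                          hit_threshold = 11, seed = 22)
  expect_false(any(res$is_hit))
  expect_gt(max(res$hit_count), 0)  # counting still happens
})

test_that("hit counts are invariant to gene and sample ordering", {
  sim <- simulate_expression_survival(
    12, 60, planted = data.frame(gene = 1, hazard_ratio = 8,
                                 cutpoint_quantile = 0.5),
    censoring_rate = 0.2, seed = 23)
  res <- run_split_screen(sim$expression, sim$clinical, seed = 24)
  perm_g <- sample(nrow(sim$expression))
  perm_s <- sample(ncol(sim$expression))
  res2 <- run_split_screen(sim$expression[perm_g, perm_s],
                           sim$clinical, seed = 24)
  expect_equal(setNames(res2$hit_count, res2$gene)[res$gene],
               setNames(res$hit_count, res$gene))
})

test_that("tightening alpha never increases a hit count", {
  sim <- simulate_expression_survival(
    12, 80, planted = data.frame(gene = 1:2, hazard_ratio = 6,
                                 cutpoint_quantile = 0.5),
    censoring_rate = 0.3, seed = 25)
  loose <- run_split_screen(sim$expression, sim$clinical, alpha = 0.05,
                            seed = 26)
  tight <- run_split_screen(sim$expression, sim$clinical, alpha = 0.01,
                            seed = 26)
  expect_true(all(tight$hit_count <= loose$hit_count))
})

test_that("the two-cohort screen validates planted probes, not nulls", {
  planted <- data.frame(gene = 1:2, hazard_ratio = 6,
                        cutpoint_quantile = 0.5)
  planted_rate <- c(); null_rate <- c()
  for (r in 1:30) {
    d <- simulate_expression_survival(20, 19, planted = planted,
                                      censoring_rate = 0.3, seed = 40000 + r)
    v <- simulate_expression_survival(20, 34, planted = planted,
                                      censoring_rate = 0.3, seed = 41000 + r)
    res <- run_two_cohort_screen(d$expression, d$clinical,
                                 v$expression, v$clinical)
    is_planted <- res$probe %in% c("gene_1", "gene_2")
    planted_rate <- c(planted_rate, res$validated[is_planted])
    null_rate <- c(null_rate, res$validated[!is_planted])
  }
  expect_gte(mean(planted_rate), 1 / 3)
  expect_lte(mean(null_rate), 0.08)
  expect_gt(mean(planted_rate), mean(null_rate) + 0.2)
})

test_that("two-cohort screen enforces shared probes and direction consistency", {
  set.seed(27)
  n <- 40
  base_t <- rexp(n, 0.3)
  mk_clin <- function(tm) data.frame(sample_id = paste0("S", 1:n),
                                     endpoint_time = tm,
                                     endpoint_event = 1L)
  v <- seq_len(n) / n
  # discovery: high expression -> short survival; validation: reversed
  expr_d <- matrix(v, 1, n, dimnames = list("flip", paste0("S", 1:n)))
  t_d <- ifelse(v > 0.5, sort(base_t)[1:(n / 2)], sort(base_t)[(n / 2 + 1):n])
  t_v <- ifelse(v > 0.5, sort(base_t)[(n / 2 + 1):n], sort(base_t)[1:(n / 2)])
  res <- run_two_cohort_screen(expr_d, mk_clin(t_d), expr_d, mk_clin(t_v))
  expect_true(res$advanced)
  expect_lt(res$validation_p, 0.05)        # significant both times
  expect_false(res$validated)              # but direction flipped
  expect_false(identical(res$discovery_direction,
                         res$validation_direction))
  # probes absent from one platform are excluded from the shared set
  expr_2 <- rbind(expr_d, other = rnorm(n))
  rownames(expr_2) <- c("flip", "other")
  res2 <- run_two_cohort_screen(expr_2, mk_clin(t_d), expr_d, mk_clin(t_v))
  expect_equal(res2$probe, "flip")
  expect_error(run_two_cohort_screen(expr_2[2, , drop = FALSE],
                                     mk_clin(t_d), expr_d, mk_clin(t_v)),
               "empty")
})
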