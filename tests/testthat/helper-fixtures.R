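# Shared fixture builders. Everything is generated in code; seeds are fixed
# per test so the suite is deterministic.

# dosage vector from genotype-class counts (n0 = major hom, n1 = het, n2 = minor hom)
dosages_from_counts <- function(n0, n1, n2 = 0) {
  c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
}

# random right-censored survival data with guaranteed events
random_surv <- function(n, event_p = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    tm <- rexp(n)
    ev <- rbinom(n, 1, event_p)
    if (sum(ev) > 0) return(list(time = tm, event = ev))
  }
}

# six-SNP toy panel exercising one exclusion per QC rule plus one survivor
toy_qc_fixture <- function(n = 50, seed = 42) {
  set.seed(seed)
  panel <- data.frame(
    rsid = c("s_mt", "s_pos0", "s_dupA", "s_dupB", "s_rare", "s_clean"),
    chrom = c("MT", "1", "1", "1", "1", "1"),
    pos = c(100L, 0L, 500L, 500L, 600L, 700L),
    triallelic = FALSE, stringsAsFactors = FALSE)
  good <- function() sample(0:2, n, replace = TRUE, prob = c(.5, .4, .1))
  genotypes <- cbind(
    s_mt = good(), s_pos0 = good(), s_dupA = good(), s_dupB = good(),
    s_rare = c(rep(0L, n - 2), 1L, 1L),  # MAF = 2/(2n) = 0.02
    s_clean = good())
  rownames(genotypes) <- paste0("S", seq_len(n))
  list(panel = panel, genotypes = genotypes)
}

# paired small cohorts for cascade tests: one planted SNP among nulls
cascade_fixture <- function(n_disc = 40, n_val = 30, n_rep = 90,
                            n_null = 50, effect = 0.4, maf_planted = 0.2,
                            seed = 1) {
  set.seed(seed)
  maf <- c(maf_planted, runif(n_null, 0.05, 0.5))
  names(maf) <- c("planted", paste0("null_", seq_len(n_null)))
  mk <- function(n, k) {
    g <- simulate_genotypes(n, maf, seed = seed + k)
    ages <- simulate_onset_ages(g[, "planted"], 2, effect = c(1, effect),
                                dispersion = 0.5, seed = seed + k + 31)
    list(genotypes = g, ages = ages)
  }
  list(discovery = mk(n_disc, 1), validation = mk(n_val, 2),
       replication = mk(n_rep, 3), snp_set = names(maf))
}
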