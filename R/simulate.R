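#' Simulate a Hardy-Weinberg genotype matrix
#'
#' Draws minor-allele dosage calls for unrelated samples at independent SNPs.
#' Each SNP with minor-allele frequency \eqn{m} is sampled under
#' Hardy-Weinberg proportions: dosage 2 with probability \eqn{m^2}, dosage 1
#' with \eqn{2m(1-m)} and dosage 0 with \eqn{(1-m)^2}, independently across
#' samples and SNPs.
#'
#' @param n_samples number of samples (rows), at least 1.
#' @param maf numeric vector of per-SNP minor-allele frequencies, each in
#'   (0, 0.5]. Names, if present, become SNP ids; otherwise ids are
#'   `snp_1, snp_2, ...`.
#' @param seed integer seed; a fixed seed gives a bit-identical matrix.
#' @return integer matrix (samples x SNPs) of minor-allele dosages in
#'   \{0, 1, 2\}, with sample ids `S1, S2, ...` as rownames.
#' @examples
#' g <- simulate_genotypes(200, c(rs1 = 0.3, rs2 = 0.05), seed = 1)
#' colMeans(g) / 2  # close to the requested MAFs
#' @export
simulate_genotypes <- function(n_samples, maf, seed = NULL) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1)
  check_fraction(maf, "maf", min = 0, max = 0.5, open_min = TRUE)
  n_samples <- as.integer(n_samples)
  snp_ids <- if (!is.null(names(maf))) names(maf) else
    paste0("snp_", seq_along(maf))
  with_seed(seed, {
    g <- vapply(maf, function(m) {
      sample(0:2, n_samples, replace = TRUE,
             prob = c((1 - m)^2, 2 * m * (1 - m), m^2))
    }, integer(n_samples))
    g <- matrix(as.integer(g), nrow = n_samples,
                dimnames = list(paste0("S", seq_len(n_samples)), snp_ids))
    g
  })
}

#' Simulate age-of-onset with a planted genotype effect
#'
#' Ages are log-normal around a genotype-group-specific median: for sample
#' \eqn{i}, `age = baseline_median * effect[group(i)] * exp(dispersion * z)`
#' with `z` standard normal, so the population median of each group is
#' exactly `baseline_median * effect` (the log-normal median equals its
#' scale). A multiplicative effect below 1 plants an earlier onset for that
#' group — the signal the rank-test cascade is meant to recover.
#'
#' @param genotypes integer vector of minor-allele dosages (0/1/2; NA for a
#'   missing call, which still receives an age drawn under the baseline).
#' @param baseline_median median onset age (years) of the reference group.
#' @param effect positive multiplicative median shift. Length 1 (all
#'   samples), 2 (`c(noncarrier, carrier)` — dosage 0 vs dosage >= 1), or 3
#'   (per dosage 0/1/2).
#' @param dispersion positive log-scale standard deviation.
#' @param seed integer seed.
#' @return numeric vector of positive ages (years), one per sample.
#' @export
simulate_onset_ages <- function(genotypes, baseline_median, effect = 1,
                                dispersion = 0.5, seed = NULL) {
  stopifnot(is.numeric(baseline_median), baseline_median > 0)
  if (!is.numeric(effect) || any(effect <= 0))
    stop("`effect` must be positive", call. = FALSE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0)
    stop("`dispersion` must be a positive scalar", call. = FALSE)
  g <- as.integer(genotypes)
  eff <- switch(as.character(length(effect)),
    "1" = rep(effect, length(g)),
    "2" = effect[ifelse(!is.na(g) & g >= 1L, 2L, 1L)],
    "3" = effect[ifelse(is.na(g), 1L, g + 1L)],
    stop("`effect` must have length 1, 2 or 3", call. = FALSE))
  with_seed(seed, baseline_median * eff *
              exp(dispersion * rnorm(length(g))))
}

#' Simulate an expression matrix with planted survival effects
#'
#' Generates a genes x samples matrix of standard-normal (log2-like)
#' expression values and an exponential progression endpoint. For each
#' planted gene, samples whose expression exceeds that gene's latent
#' cut-point quantile have their event hazard multiplied by the gene's
#' hazard ratio; all other genes are independent of survival. Censoring is
#' independent uniform on `(0, t_max)` with `t_max` solved so the expected
#' censored fraction matches `censoring_rate` given the simulated hazard
#' mix; `censoring_rate = 0` yields no censoring at all.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param planted `NULL`, or a data.frame with columns `gene` (id or index
#'   into the gene set), `hazard_ratio` (> 0) and `cutpoint_quantile`
#'   (fraction in (0,1); the latent high/low boundary).
#' @param censoring_rate target fraction censored, in \[0, 1).
#' @param baseline_hazard events per year for the low group (default 0.2).
#' @param seed integer seed.
#' @return list with `expression` (genes x samples matrix), `clinical`
#'   (data.frame: `sample_id`, `endpoint_time`, `endpoint_event`,
#'   `endpoint_kind = "PFI"`), and `truth` (per-sample latent high/low
#'   indicator matrix for the planted genes).
#' @export
simulate_expression_survival <- function(n_genes, n_samples, planted = NULL,
                                         censoring_rate = 0.3,
                                         baseline_hazard = 0.2,
                                         seed = NULL) {
  stopifnot(n_genes >= 1, n_samples >= 1, baseline_hazard > 0)
  check_fraction(censoring_rate, "censoring_rate", max = 1, open_max = TRUE)
  gene_ids <- paste0("gene_", seq_len(n_genes))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("gene", "hazard_ratio", "cutpoint_quantile") %in%
                    names(planted)))
    if (is.numeric(planted$gene)) planted$gene <- gene_ids[planted$gene]
    if (!all(planted$gene %in% gene_ids))
      stop("planted gene ids must be among the simulated genes",
           call. = FALSE)
    if (any(planted$hazard_ratio <= 0))
      stop("hazard ratios must be positive", call. = FALSE)
    check_fraction(planted$cutpoint_quantile, "cutpoint_quantile",
                   open_min = TRUE, open_max = TRUE)
  }
  with_seed(seed, {
    expr <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
                   dimnames = list(gene_ids,
                                   paste0("S", seq_len(n_samples))))
    hazard <- rep(baseline_hazard, n_samples)
    truth <- NULL
    if (!is.null(planted) && nrow(planted)) {
      truth <- matrix(FALSE, nrow(planted), n_samples,
                      dimnames = list(planted$gene, colnames(expr)))
      for (k in seq_len(nrow(planted))) {
        x <- expr[planted$gene[k], ]
        hi <- x > quantile(x, planted$cutpoint_quantile[k])
        truth[k, ] <- hi
        hazard <- hazard * ifelse(hi, planted$hazard_ratio[k], 1)
      }
    }
    time_event <- rexp(n_samples, rate = hazard)
    if (censoring_rate > 0) {
      t_max <- censoring_horizon(hazard, censoring_rate)
      time_cens <- runif(n_samples, 0, t_max)
      event <- as.integer(time_event <= time_cens)
      obs_time <- pmin(time_event, time_cens)
    } else {
      event <- rep(1L, n_samples)
      obs_time <- time_event
    }
    list(expression = expr,
         clinical = data.frame(sample_id = colnames(expr),
                               endpoint_time = obs_time,
                               endpoint_event = event,
                               endpoint_kind = "PFI",
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}

# For C ~ U(0, T) independent of X ~ Exp(h), P(censored) = (1 - exp(-hT))/(hT).
# Averaged over the sample hazards, solve for the T that hits the target rate.
censoring_horizon <- function(hazards, rate) {
  p_cens <- function(t) mean((1 - exp(-hazards * t)) / (hazards * t))
  lo <- 1e-8; hi <- 1
  while (p_cens(hi) > rate && hi < 1e12) hi <- hi * 10
  uniroot(function(t) p_cens(t) - rate, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' Builds a haplotype x SNP 0/1 matrix in which SNPs are organised in
#' blocks. Within a block, each SNP after the first copies its left
#' neighbour's allele with probability `sqrt(target_r2)` and is otherwise
#' redrawn as an independent Bernoulli(maf) — so adjacent SNPs have
#' allelic correlation `sqrt(target_r2)` (hence r-squared equal to the
#' target in expectation) and the allele frequency is preserved along the
#' block. `target_r2 = 1` yields exactly duplicated columns. Blocks are
#' mutually independent. Positions are laid out 1 kb apart within a block
#' and 1 Mb between blocks, all on chromosome 1.
#'
#' @param ld_blocks data.frame with columns `n_snps` and `target_r2` (each
#'   in \[0,1\]); optional column `maf` (default 0.5).
#' @param n_haplotypes even number of haplotypes, at least 4.
#' @param seed integer seed.
#' @return 0/1 integer matrix (haplotypes x SNPs) with attributes `panel`
#'   (data.frame `rsid`, `chrom`, `pos`, `block`).
#' @export
simulate_haplotype_panel <- function(ld_blocks, n_haplotypes, seed = NULL) {
  ld_blocks <- as.data.frame(ld_blocks)
  stopifnot(all(c("n_snps", "target_r2") %in% names(ld_blocks)))
  check_fraction(ld_blocks$target_r2, "target_r2")
  if (n_haplotypes < 4 || n_haplotypes %% 2 != 0)
    stop("`n_haplotypes` must be even and at least 4", call. = FALSE)
  if (is.null(ld_blocks$maf)) ld_blocks$maf <- 0.5
  check_fraction(ld_blocks$maf, "maf", open_min = TRUE, max = 0.5)
  with_seed(seed, {
    cols <- list(); panel <- list()
    for (b in seq_len(nrow(ld_blocks))) {
      k <- ld_blocks$n_snps[b]
      theta <- sqrt(ld_blocks$target_r2[b])
      m <- ld_blocks$maf[b]
      block <- matrix(0L, n_haplotypes, k)
      block[, 1] <- rbinom(n_haplotypes, 1, m)
      if (k > 1) for (j in 2:k) {
        copy <- runif(n_haplotypes) < theta
        block[, j] <- ifelse(copy, block[, j - 1],
                             rbinom(n_haplotypes, 1, m))
      }
      cols[[b]] <- block
      panel[[b]] <- data.frame(
        rsid = sprintf("blk%d_snp%d", b, seq_len(k)),
        chrom = "1",
        pos = (b - 1L) * 1000000L + 1000L * seq_len(k),
        block = b, stringsAsFactors = FALSE)
    }
    hap <- do.call(cbind, cols)
    panel <- do.call(rbind, panel)
    dimnames(hap) <- list(paste0("H", seq_len(n_haplotypes)), panel$rsid)
    attr(hap, "panel") <- panel
    hap
  })
}

#' Collapse a phased haplotype panel into diploid genotypes
#'
#' Pairs consecutive haplotypes (1+2, 3+4, ...) into individuals and sums
#' alleles into dosages, preserving the SNP panel attribute.
#'
#' @param haplotypes matrix from [simulate_haplotype_panel()].
#' @return integer dosage matrix (individuals x SNPs).
#' @export
haplotypes_to_genotypes <- function(haplotypes) {
  n <- nrow(haplotypes)
  stopifnot(n %% 2 == 0)
  idx <- seq(1, n, by = 2)
  g <- haplotypes[idx, , drop = FALSE] + haplotypes[idx + 1, , drop = FALSE]
  rownames(g) <- paste0("S", seq_along(idx))
  attr(g, "panel") <- attr(haplotypes, "panel")
  g
}
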