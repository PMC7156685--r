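#' Minor-allele frequency from dosage calls
#'
#' Computes the cohort minor-allele frequency of one SNP from its
#' alternate-allele dosage vector: `f = sum(dosage) / (2 * n_called)` with
#' missing calls excluded from numerator and denominator, returned as
#' `min(f, 1 - f)` so the value is always the frequency of the *less*
#' common allele in this cohort (which allele is minor can differ between
#' cohorts).
#'
#' @param dosages integer vector of alternate-allele dosages (0/1/2), NA
#'   for missing calls.
#' @return minor-allele frequency in \[0, 0.5\].
#' @examples
#' compute_maf(c(rep(0, 21), rep(1, 5)))  # 5/52 = 0.0962
#' @export
compute_maf <- function(dosages) {
  called <- dosages[!is.na(dosages)]
  if (!length(called))
    stop_modscreen("all genotype calls missing; MAF undefined",
                   "modscreen_all_missing")
  if (!all(called %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  f <- sum(called) / (2 * length(called))
  min(f, 1 - f)
}

#' Per-SNP call rate
#'
#' Fraction of samples with a non-missing genotype call.
#' @param dosages dosage vector with NA for missing.
#' @return fraction in \[0, 1\].
#' @export
call_rate <- function(dosages) mean(!is.na(dosages))

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on a genotype-count triple. Conditional on the
#' total sample size and the minor-allele count, the number of
#' heterozygotes has a known distribution under HWE; the p-value is the
#' sum of the probabilities of all heterozygote counts no more probable
#' than the observed one.
#'
#' @param n_hom_major,n_het,n_hom_minor non-negative genotype counts
#'   (may also be passed as a single length-3 vector in `n_hom_major`).
#' @return exact two-sided p-value in (0, 1\].
#' @examples
#' hwe_exact_test(25, 50, 25)  # observed count is modal: p = 1
#' hwe_exact_test(50, 0, 50)   # gross heterozygote deficit: p << 1e-6
#' @export
hwe_exact_test <- function(n_hom_major, n_het = NULL, n_hom_minor = NULL) {
  if (is.null(n_het) && length(n_hom_major) == 3L) {
    n_het <- n_hom_major[2]; n_hom_minor <- n_hom_major[3]
    n_hom_major <- n_hom_major[1]
  }
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotype call required", call. = FALSE)
  # orient to the rarer allele; the test is symmetric in allele labels
  n_rare <- min(2 * n_hom_major + n_het, 2 * n_hom_minor + n_het)
  if (n_rare == 0) return(1)  # monomorphic: single attainable configuration
  hets <- seq(n_rare %% 2, n_rare, by = 2)  # feasible heterozygote counts
  logp <- vapply(hets, function(h) {
    a <- (n_rare - h) / 2          # rare homozygotes
    b <- n - a - h                 # common homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' QC criteria for a SNP panel
#'
#' Bundles the filtering thresholds used by [apply_qc()]. The defaults are
#' the standard candidate-panel settings: drop SNPs on unplaced (0),
#' pseudoautosomal (XY), Y or mitochondrial contigs and SNPs at position 0;
#' remove triallelic, all-missing, duplicated-position and monomorphic
#' SNPs; restrict X-chromosome SNPs to female samples; and require a 95%
#' call rate and a cohort MAF of at least 0.05.
#'
#' @param maf_min minimum cohort minor-allele frequency.
#' @param call_rate_min minimum per-SNP genotyping rate.
#' @param drop_chroms chromosome labels removed outright.
#' @param drop_pos_zero drop SNPs with position 0 (unmapped).
#' @param x_females_only compute X-chromosome statistics on females only.
#' @param drop_triallelic,drop_duplicates,drop_monomorphic rule switches.
#' @return object of class `qc_criteria`.
#' @export
qc_criteria <- function(maf_min = 0.05, call_rate_min = 0.95,
                        drop_chroms = c("0", "XY", "Y", "MT"),
                        drop_pos_zero = TRUE, x_females_only = TRUE,
                        drop_triallelic = TRUE, drop_duplicates = TRUE,
                        drop_monomorphic = TRUE) {
  check_fraction(maf_min, "maf_min")
  check_fraction(call_rate_min, "call_rate_min")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 drop_chroms = as.character(drop_chroms),
                 drop_pos_zero = drop_pos_zero,
                 x_females_only = x_females_only,
                 drop_triallelic = drop_triallelic,
                 drop_duplicates = drop_duplicates,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_criteria")
}

#' Filter a SNP panel by quality-control rules
#'
#' Applies the QC rules in a fixed, documented order — chromosome /
#' position filters, triallelic, all-missing, duplicate position,
#' monomorphic, X-chromosome female restriction, call rate, MAF — and
#' attributes each excluded SNP to the *first* rule that removed it. The
#' surviving set does not depend on the order; only the ledger attribution
#' does. The duplicate rule removes every SNP in a duplicated
#' chromosome/position group. For X-chromosome SNPs (when
#' `x_females_only`), call rate, monomorphism and MAF are computed on
#' female samples only.
#'
#' @param panel data.frame with columns `rsid`, `chrom`, `pos`; optional
#'   logical column `triallelic`.
#' @param genotypes dosage matrix (samples x SNPs), columns matching
#'   `panel$rsid`.
#' @param clinical optional data.frame with `sample_id` and `sex`
#'   (required if the panel has X SNPs and `x_females_only` is set).
#' @param criteria a [qc_criteria()] object.
#' @return list with `panel` (surviving rows, plus `maf` and `call_rate`
#'   columns), `genotypes` (surviving columns), and `ledger` (data.frame
#'   `rule`, `n_excluded`, one row per rule in application order).
#' @export
apply_qc <- function(panel, genotypes, clinical = NULL,
                     criteria = qc_criteria()) {
  stopifnot(inherits(criteria, "qc_criteria"),
            all(c("rsid", "chrom", "pos") %in% names(panel)))
  panel <- as.data.frame(panel)
  if (!all(panel$rsid %in% colnames(genotypes)))
    stop("panel and genotype columns are not aligned", call. = FALSE)
  genotypes <- genotypes[, panel$rsid, drop = FALSE]
  n <- nrow(panel)
  chrom <- as.character(panel$chrom)

  female <- NULL
  has_x <- any(chrom == "X")
  if (criteria$x_females_only && has_x) {
    if (is.null(clinical) || is.null(clinical$sex))
      stop("clinical table with a `sex` column is required to restrict ",
           "X-chromosome SNPs to females", call. = FALSE)
    sex <- clinical$sex[match(rownames(genotypes), clinical$sample_id)]
    female <- !is.na(sex) & sex == "female"
  }

  # per-SNP working dosages: X SNPs restricted to females where requested
  col_dosages <- function(j) {
    d <- genotypes[, j]
    if (!is.null(female) && chrom[j] == "X") d <- d[female]
    d
  }

  rules <- c("chromosome", "position_zero", "triallelic", "all_missing",
             "duplicate_position", "monomorphic", "call_rate", "maf")
  excluded_by <- rep(NA_character_, n)
  flag <- function(idx, rule) {
    idx[is.na(idx)] <- FALSE
    idx <- idx & is.na(excluded_by)
    excluded_by[idx] <<- rule
  }

  flag(chrom %in% criteria$drop_chroms, "chromosome")
  if (criteria$drop_pos_zero) flag(panel$pos == 0, "position_zero")
  if (criteria$drop_triallelic && !is.null(panel$triallelic))
    flag(panel$triallelic %in% TRUE, "triallelic")

  ncalled <- vapply(seq_len(n), function(j) sum(!is.na(col_dosages(j))),
                    integer(1))
  flag(ncalled == 0, "all_missing")

  if (criteria$drop_duplicates) {
    # grouped on the full panel (not the not-yet-excluded subset) so the
    # surviving set is independent of rule order; SNPs at invalid positions
    # are not meaningful duplicates of each other
    valid_pos <- !is.na(panel$pos) & panel$pos > 0
    key <- ifelse(valid_pos, paste(chrom, panel$pos, sep = ":"),
                  paste0("invalid_", seq_len(n)))
    dup_keys <- unique(key[duplicated(key)])
    flag(key %in% dup_keys, "duplicate_position")
  }

  stat_maf <- rep(NA_real_, n); stat_cr <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    d <- col_dosages(j)
    stat_cr[j] <- if (length(d)) mean(!is.na(d)) else 0
    if (any(!is.na(d))) stat_maf[j] <- compute_maf(d)
  }
  if (criteria$drop_monomorphic)
    flag(!is.na(stat_maf) & stat_maf == 0, "monomorphic")
  flag(!is.na(stat_cr) & stat_cr < criteria$call_rate_min, "call_rate")
  flag(!is.na(stat_maf) & stat_maf < criteria$maf_min, "maf")

  keep <- is.na(excluded_by)
  ledger <- data.frame(
    rule = rules,
    n_excluded = vapply(rules, function(r)
      sum(excluded_by == r, na.rm = TRUE), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out_panel <- panel[keep, , drop = FALSE]
  out_panel$maf <- stat_maf[keep]
  out_panel$call_rate <- stat_cr[keep]
  rownames(out_panel) <- NULL
  list(panel = out_panel,
       genotypes = genotypes[, keep, drop = FALSE],
       ledger = ledger)
}
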