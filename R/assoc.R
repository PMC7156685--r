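#' Genotype-grouped age-of-onset test for one SNP
#'
#' Resolves the cohort minor allele from the alternate-allele dosages,
#' groups samples by minor-allele count, and tests onset ages across
#' groups. When the minor-homozygote count is at most `combine_threshold`
#' (default 4) — or when `force_combined` is set, as in small carrier
#' cohorts — heterozygous and homozygous minor calls are pooled into one
#' carrier group and a two-sided Mann-Whitney U test is used; otherwise
#' the three genotype groups are compared by Kruskal-Wallis. The effect
#' direction compares group median ages: `minor_earlier` when minor-allele
#' carriers have the lower median onset.
#'
#' @param dosages alternate-allele dosage vector (0/1/2, NA missing).
#' @param ages onset ages (years), same length; pairs with a missing
#'   dosage or age are dropped.
#' @param combine_threshold pool het + minor-hom when the minor-homozygote
#'   count is at most this (default 4).
#' @param force_combined always use the two-group pooling.
#' @param mwu_mode passed to [mann_whitney_u()].
#' @param rsid optional id carried into the result.
#' @return one-row data.frame with `rsid`, `mode`, per-group `n`, median
#'   and mean ages, `statistic`, `p` and `direction`
#'   (`minor_earlier` / `minor_later` / `mixed`).
#' @export
group_and_test <- function(dosages, ages, combine_threshold = 4,
                           force_combined = FALSE, mwu_mode = "auto",
                           rsid = NA_character_) {
  keep <- !is.na(dosages) & !is.na(ages)
  d <- as.integer(dosages[keep]); y <- ages[keep]
  if (!length(d)) stop("no called samples", call. = FALSE)
  f_alt <- sum(d) / (2 * length(d))
  minor_count <- if (f_alt > 0.5) 2L - d else d  # per-sample minor dosage
  tab <- tabulate(minor_count + 1L, nbins = 3L)
  if (sum(tab > 0) < 2)
    stop_modscreen(sprintf("SNP %s untestable: fewer than two genotype groups",
                           rsid), "modscreen_untestable")
  two_group <- force_combined || tab[3] <= combine_threshold
  med <- function(x) if (length(x)) median(x) else NA_real_
  mn <- function(x) if (length(x)) mean(x) else NA_real_
  major <- y[minor_count == 0]
  het <- y[minor_count == 1]; hom <- y[minor_count == 2]
  if (two_group) {
    carrier <- y[minor_count >= 1]
    if (!length(major) || !length(carrier))
      stop_modscreen(sprintf("SNP %s untestable: empty genotype group", rsid),
                     "modscreen_untestable")
    tst <- mann_whitney_u(major, carrier, mode = mwu_mode)
    statistic <- tst$U; p <- tst$p
    direction <- if (med(carrier) < med(major)) "minor_earlier"
      else if (med(carrier) > med(major)) "minor_later" else "mixed"
    mode <- "two_group_combined"
    n_het_out <- length(carrier); n_hom_out <- NA_integer_
    med_het <- med(carrier); med_hom <- NA_real_
    mean_het <- mn(carrier); mean_hom <- NA_real_
  } else {
    gl <- list(major, het, hom)
    gl <- gl[lengths(gl) > 0]
    tst <- kruskal_wallis(gl)
    statistic <- tst$H; p <- tst$p
    below <- c(med(het) < med(major), med(hom) < med(major))
    below <- below[!is.na(below)]
    direction <- if (all(below)) "minor_earlier"
      else if (!any(below)) "minor_later" else "mixed"
    mode <- "three_group"
    n_het_out <- length(het); n_hom_out <- length(hom)
    med_het <- med(het); med_hom <- med(hom)
    mean_het <- mn(het); mean_hom <- mn(hom)
  }
  data.frame(rsid = rsid, mode = mode, maf = min(f_alt, 1 - f_alt),
             n_major = length(major), n_het = n_het_out, n_hom = n_hom_out,
             median_major = med(major), median_het = med_het,
             median_hom = med_hom,
             mean_major = mn(major), mean_het = mean_het,
             mean_hom = mean_hom,
             statistic = statistic, p = p, direction = direction,
             stringsAsFactors = FALSE)
}

# test every column of a genotype matrix; untestable SNPs return NULL rows
test_panel <- function(genotypes, ages, force_combined = FALSE,
                       combine_threshold = 4, mwu_mode = "auto") {
  res <- lapply(colnames(genotypes), function(s) {
    tryCatch(group_and_test(genotypes[, s], ages,
                            combine_threshold = combine_threshold,
                            force_combined = force_combined,
                            mwu_mode = mwu_mode, rsid = s),
             modscreen_untestable = function(e) NULL)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(rsid = character(), p = numeric(),
                      direction = character()))
  do.call(rbind, res)
}

#' Discovery / validation / replication association cascade
#'
#' Runs the three-stage candidate-SNP screen for age-of-onset modifiers:
#'
#' 1. **Discovery** — every SNP in `snp_set` is tested in the discovery
#'    cohort (carriers pooled: two-group Mann-Whitney); SNPs with raw
#'    `p < alpha` advance.
#' 2. **Validation** — among advancing SNPs with validation-cohort
#'    MAF >= `maf_min_validation`, keep those with raw `p < alpha` *and*
#'    the same effect direction (the same allele class shows the earlier
#'    median onset in both cohorts).
#' 3. **Replication** — survivors are mapped onto the replication
#'    platform via [best_proxy()] (the SNP itself when directly
#'    genotyped), tested with [group_and_test()] (three genotype groups
#'    unless minor homozygotes are at most `combine_threshold`), and
#'    Bonferroni-adjusted over the number of SNPs actually tested at this
#'    stage.
#'
#' Cohorts are lists with elements `genotypes` (samples x SNPs dosage
#' matrix) and `ages`. A stage with zero testable SNPs yields an empty
#' report rather than an error.
#'
#' @param discovery,validation,replication cohort lists (see above).
#' @param snp_set rsids to screen (already QC'd / catalog-intersected).
#' @param alpha per-stage raw significance level (default 0.05).
#' @param maf_min_validation minimum validation-cohort MAF for a SNP to be
#'   tested at stage 2 (default 0.05).
#' @param ld_table LD table used to resolve replication proxies; `NULL`
#'   means only directly genotyped SNPs can replicate.
#' @param combine_threshold replication-stage pooling rule (default 4).
#' @param mwu_mode passed through to the rank tests.
#' @return object of class `cascade_report`: list with per-stage result
#'   data.frames (`discovery`, `validation`, `replication`), the final
#'   `survivors` rsids, and `counts` mirroring the flow chart (panel size,
#'   tested and significant per stage).
#' @export
run_cascade <- function(discovery, validation, replication, snp_set,
                        alpha = 0.05, maf_min_validation = 0.05,
                        ld_table = NULL, combine_threshold = 4,
                        mwu_mode = "auto") {
  check_fraction(alpha, "alpha", open_min = TRUE)
  snp_set <- intersect(snp_set, colnames(discovery$genotypes))
  empty <- data.frame(rsid = character(), p = numeric(),
                      direction = character())

  disc <- test_panel(discovery$genotypes[, snp_set, drop = FALSE],
                     discovery$ages, force_combined = TRUE,
                     mwu_mode = mwu_mode)
  disc$stage <- rep("discovery", nrow(disc))
  disc_sig <- disc[disc$p < alpha, , drop = FALSE]

  val_testable <- character(0); val <- empty; val_sig <- empty
  if (nrow(disc_sig)) {
    in_val <- intersect(disc_sig$rsid, colnames(validation$genotypes))
    maf_val <- vapply(in_val, function(s)
      tryCatch(compute_maf(validation$genotypes[, s]),
               modscreen_all_missing = function(e) 0), numeric(1))
    val_testable <- in_val[maf_val >= maf_min_validation]
    if (length(val_testable)) {
      val <- test_panel(validation$genotypes[, val_testable, drop = FALSE],
                        validation$ages, force_combined = TRUE,
                        mwu_mode = mwu_mode)
      if (nrow(val)) {
        val$stage <- "validation"
        dir_disc <- disc_sig$direction[match(val$rsid, disc_sig$rsid)]
        val$consistent <- val$direction == dir_disc &
          val$direction %in% c("minor_earlier", "minor_later")
        val_sig <- val[val$p < alpha & val$consistent, , drop = FALSE]
      }
    }
  }

  rep_res <- empty; survivors <- character(0); n_rep_tested <- 0L
  if (nrow(val_sig)) {
    genotyped <- colnames(replication$genotypes)
    mapped <- vapply(val_sig$rsid, best_proxy, character(1),
                     genotyped = genotyped, ld_table = ld_table)
    ok <- !is.na(mapped)
    if (any(ok)) {
      rows <- lapply(which(ok), function(i) {
        r <- tryCatch(
          group_and_test(replication$genotypes[, mapped[i]],
                         replication$ages,
                         combine_threshold = combine_threshold,
                         mwu_mode = mwu_mode, rsid = val_sig$rsid[i]),
          modscreen_untestable = function(e) NULL)
        if (!is.null(r)) r$tested_as <- mapped[i]
        r
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) {
        rep_res <- do.call(rbind, rows)
        rep_res$stage <- "replication"
        n_rep_tested <- nrow(rep_res)
        rep_res$p_adjusted <- bonferroni(rep_res$p, n_rep_tested)
        survivors <- rep_res$rsid[rep_res$p_adjusted < alpha]
      }
    }
  }

  structure(list(
    discovery = disc, validation = val, replication = rep_res,
    survivors = survivors,
    counts = data.frame(
      stage = c("panel", "discovery_tested", "discovery_significant",
                "validation_tested", "validation_significant",
                "replication_tested", "replication_significant"),
      n = c(length(snp_set), nrow(disc), nrow(disc_sig),
            length(val_testable), nrow(val_sig), n_rep_tested,
            length(survivors)))),
    class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Age-of-onset association cascade\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-24s %d\n", x$counts$stage[i], x$counts$n[i]))
  if (length(x$survivors))
    cat("  survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}
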