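#' Squared allelic correlation between two loci
#'
#' Computes r-squared from phased two-locus haplotype counts
#' `(n_AB, n_Ab, n_aB, n_ab)`:
#' \deqn{r^2 = D^2 / (p_A p_a p_B p_b), \quad D = f_{AB} - p_A p_B}
#' with all frequencies taken from the counts. Symmetric in the two loci
#' and invariant to relabelling alleles at either locus.
#'
#' @param counts numeric vector of the four haplotype counts, in the order
#'   AB, Ab, aB, ab; sum must be at least 1.
#' @return r-squared in \[0, 1\].
#' @examples
#' r_squared(c(40, 10, 10, 40))  # D = 0.15, r2 = 0.36
#' @export
r_squared <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("at least one haplotype required", call. = FALSE)
  f <- counts / n
  p_A <- f[1] + f[2]; p_B <- f[1] + f[3]
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
    stop_modscreen("r-squared undefined: a locus is monomorphic",
                   "modscreen_monomorphic")
  D <- f[1] - p_A * p_B
  unname(D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B)))
}

#' Pairwise LD table from a phased haplotype panel
#'
#' Computes r-squared for every pair of polymorphic SNPs within
#' `max_distance` of each other (monomorphic columns are skipped) and
#' returns the upper-triangle rows of the symmetric relation.
#'
#' @param haplotypes 0/1 matrix (haplotypes x SNPs), e.g. from
#'   [simulate_haplotype_panel()]; SNP positions are taken from its
#'   `panel` attribute or from a `panel` argument.
#' @param panel data.frame with `rsid` and `pos` (and optionally `chrom`);
#'   defaults to `attr(haplotypes, "panel")`.
#' @param max_distance only pairs at most this many base pairs apart (on
#'   the same chromosome) are reported.
#' @return data.frame with columns `rsid_a`, `rsid_b`, `r2`, `distance`.
#' @export
ld_from_haplotypes <- function(haplotypes, panel = attr(haplotypes, "panel"),
                               max_distance = 500000) {
  stopifnot(!is.null(panel), all(colnames(haplotypes) %in% panel$rsid))
  panel <- panel[match(colnames(haplotypes), panel$rsid), ]
  chrom <- if (is.null(panel$chrom)) rep("1", nrow(panel)) else
    as.character(panel$chrom)
  poly <- apply(haplotypes, 2, function(x) length(unique(x)) > 1)
  idx <- which(poly)
  rows <- list(); k <- 0L
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    for (j in idx[-seq_len(ii)]) {
      if (chrom[i] != chrom[j]) next
      d <- abs(panel$pos[i] - panel$pos[j])
      if (d > max_distance) next
      a <- haplotypes[, i]; b <- haplotypes[, j]
      cnt <- c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
      k <- k + 1L
      rows[[k]] <- data.frame(rsid_a = panel$rsid[i], rsid_b = panel$rsid[j],
                              r2 = r_squared(cnt), distance = d,
                              stringsAsFactors = FALSE)
    }
  }
  if (!k) return(data.frame(rsid_a = character(), rsid_b = character(),
                            r2 = numeric(), distance = numeric()))
  do.call(rbind, rows)
}

#' Proxy-eligibility criteria
#'
#' Thresholds for [expand_proxies()]: a proxy must be in strong LD with
#' its lead (`r2_min`, default 0.8), within `max_distance` (500 kb), and
#' itself pass MAF (0.01), Hardy-Weinberg (exact p >= 1e-6) and call-rate
#' (95%) checks where those statistics are available on the panel.
#'
#' @param r2_min,maf_min,max_distance,hwe_p_min,call_rate_min thresholds.
#' @return object of class `ld_criteria`.
#' @export
ld_criteria <- function(r2_min = 0.8, maf_min = 0.01, max_distance = 500000,
                        hwe_p_min = 1e-6, call_rate_min = 0.95) {
  check_fraction(r2_min, "r2_min")
  check_fraction(maf_min, "maf_min")
  check_fraction(call_rate_min, "call_rate_min")
  stopifnot(max_distance > 0, hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(r2_min = r2_min, maf_min = maf_min,
                 max_distance = max_distance, hwe_p_min = hwe_p_min,
                 call_rate_min = call_rate_min), class = "ld_criteria")
}

# symmetric closure of an LD table, one row per ordered (a, b) pair
ld_closure <- function(ld_table) {
  rbind(ld_table[, c("rsid_a", "rsid_b", "r2", "distance")],
        setNames(ld_table[, c("rsid_b", "rsid_a", "r2", "distance")],
                 c("rsid_a", "rsid_b", "r2", "distance")))
}

#' Expand lead SNPs to their LD proxies
#'
#' For each lead SNP, returns the lead itself plus every SNP linked to it
#' in the LD table with `r2 >= r2_min` and `distance <= max_distance`,
#' where the proxy also passes the per-SNP MAF, HWE and call-rate criteria
#' (checked against the matching `maf`, `hwe_p`, `call_rate` columns of
#' `panel` when present; a missing column means the check is not applied).
#' The union over leads is deduplicated, keeping for each proxy the lead
#' with maximal r-squared as provenance; the number of leads a proxy
#' served is kept as `n_leads`.
#'
#' @param leads character vector of lead rsids.
#' @param ld_table data.frame `rsid_a`, `rsid_b`, `r2`, `distance`
#'   (unordered pairs; symmetry is applied internally).
#' @param panel optional data.frame with `rsid` and any of `maf`, `hwe_p`,
#'   `call_rate` used for proxy-eligibility checks.
#' @param criteria an [ld_criteria()] object.
#' @return data.frame `rsid`, `lead`, `r2`, `distance`, `n_leads`; leads
#'   themselves appear with `r2 = 1`, `distance = 0`.
#' @export
expand_proxies <- function(leads, ld_table, panel = NULL,
                           criteria = ld_criteria()) {
  stopifnot(inherits(criteria, "ld_criteria"))
  leads <- unique(as.character(leads))
  sym <- if (nrow(ld_table)) ld_closure(ld_table) else ld_table
  eligible <- function(rsids) {
    ok <- rep(TRUE, length(rsids))
    if (is.null(panel)) return(ok)
    i <- match(rsids, panel$rsid)
    chk <- function(col, thr) {
      v <- panel[[col]][i]
      ifelse(is.na(i) | is.null(v) | is.na(v), TRUE, v >= thr)
    }
    if (!is.null(panel$maf)) ok <- ok & chk("maf", criteria$maf_min)
    if (!is.null(panel$hwe_p)) ok <- ok & chk("hwe_p", criteria$hwe_p_min)
    if (!is.null(panel$call_rate))
      ok <- ok & chk("call_rate", criteria$call_rate_min)
    ok
  }
  out <- data.frame(rsid = leads, lead = leads, r2 = 1, distance = 0,
                    stringsAsFactors = FALSE)
  if (nrow(ld_table)) {
    hits <- sym[sym$rsid_a %in% leads &
                  sym$r2 >= criteria$r2_min &
                  sym$distance <= criteria$max_distance, , drop = FALSE]
    if (nrow(hits)) {
      hits <- hits[eligible(hits$rsid_b), , drop = FALSE]
      out <- rbind(out, data.frame(rsid = hits$rsid_b, lead = hits$rsid_a,
                                   r2 = hits$r2, distance = hits$distance,
                                   stringsAsFactors = FALSE))
    }
  }
  mult <- tapply(out$lead, out$rsid, function(x) length(unique(x)))
  out <- out[order(out$rsid, -out$r2, out$distance, out$lead), ]
  out <- out[!duplicated(out$rsid), , drop = FALSE]
  out$n_leads <- as.integer(mult[out$rsid])
  rownames(out) <- NULL
  out
}

#' Best genotyped proxy for a target SNP
#'
#' Resolves a SNP selected on one genotyping platform to the replication
#' platform: the target itself if directly genotyped, otherwise the
#' genotyped SNP most closely linked to it (maximal r-squared, ties broken
#' by smaller distance, then lexicographic rsid), or `NA` if no genotyped
#' SNP reaches `r2_min`.
#'
#' @param target rsid to resolve.
#' @param genotyped character vector of rsids available on the
#'   replication platform.
#' @param ld_table data.frame `rsid_a`, `rsid_b`, `r2`, `distance`.
#' @param r2_min minimum linkage for an acceptable proxy (default 0.8).
#' @return single rsid, or `NA_character_` when no proxy qualifies.
#' @export
best_proxy <- function(target, genotyped, ld_table, r2_min = 0.8) {
  if (target %in% genotyped) return(target)
  if (is.null(ld_table) || !nrow(ld_table)) return(NA_character_)
  sym <- ld_closure(ld_table)
  cand <- sym[sym$rsid_a == target & sym$rsid_b %in% genotyped &
                sym$r2 >= r2_min, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  cand <- cand[order(-cand$r2, cand$distance, cand$rsid_b), , drop = FALSE]
  cand$rsid_b[1]
}
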