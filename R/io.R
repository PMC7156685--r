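#' Read a genotype matrix with its SNP panel
#'
#' Reads either a VCF (4.x, the GT field is sufficient) or the package's
#' matrix-TSV dialect (samples as rows, SNPs as columns, header row of
#' rsids, missing calls as `NA`). Dosages are coded as
#' alternate-allele counts: `0/0` maps to 0, `0/1` and `1/0` to 1, `1/1`
#' to 2 and `./.` to missing (phased `|` separators are accepted).
#' Records with more than one ALT allele are kept but flagged
#' `triallelic` in the panel, with all their calls set missing, so the QC
#' layer excludes them. Whether the alternate allele is the *minor*
#' allele is resolved per cohort at analysis time, since it can flip
#' between cohorts.
#'
#' @param path input file.
#' @param format `"vcf"`, `"matrix"`, or `"auto"` (by file extension).
#' @return list with `genotypes` (samples x SNPs integer matrix) and
#'   `panel` (data.frame `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `triallelic`; chromosome and position are `NA` for matrix input).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_matrix(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  triallelic <- grepl(",", fix$ALT)
  rsid <- fix$ID
  rsid[is.na(rsid) | rsid == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(rsid) | rsid == "."]
  panel <- data.frame(rsid = rsid, chrom = as.character(fix$CHROM),
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, triallelic = triallelic,
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt[triallelic, ] <- NA  # dosage undefined; QC drops these via the flag
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  known <- is.na(gt) | gt %in% c(names(code), "./.", ".|.", ".")
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown GT token \"%s\" at record %d (%s)",
                 gt[!known][1], bad[1], rownames(gt)[bad[1]]),
         call. = FALSE)
  }
  d <- matrix(code[gt], nrow = nrow(gt))
  d[triallelic, ] <- NA_integer_
  genotypes <- t(d)
  dimnames(genotypes) <- list(colnames(gt), rsid)
  list(genotypes = genotypes, panel = panel)
}

read_genotypes_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, row.names = 1)
  genotypes <- as.matrix(tab)
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("matrix-TSV dosages must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(genotypes) <- "integer"
  panel <- data.frame(rsid = colnames(genotypes), chrom = NA_character_,
                      pos = NA_integer_, ref = NA_character_,
                      alt = NA_character_, triallelic = FALSE,
                      stringsAsFactors = FALSE)
  list(genotypes = genotypes, panel = panel)
}

#' Write a genotype matrix in the matrix-TSV dialect
#'
#' Samples as rows, SNPs as columns, header row of rsids, missing = `NA`.
#' [read_genotypes()] on the result reproduces the matrix exactly.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  write.table(cbind(sample_id = rownames(genotypes),
                    as.data.frame(genotypes, check.names = FALSE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes and a SNP panel as a minimal VCF
#'
#' Emits a VCF 4.2 file carrying only the GT field (unphased), with the
#' alternate-allele dosage mapped back to `0/0`, `0/1`, `1/1` and missing
#' to `./.`. Used so synthetic cohorts exercise the same VCF parser that
#' real data would pass through.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @param panel data.frame with `rsid`, `chrom`, `pos` and optionally
#'   `ref`, `alt` (defaults A/G).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(genotypes, panel, path) {
  stopifnot(all(colnames(genotypes) == panel$rsid))
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  ref <- if (is.null(panel$ref)) rep("A", nrow(panel)) else panel$ref
  alt <- if (is.null(panel$alt)) rep("G", nrow(panel)) else panel$alt
  for (j in seq_len(ncol(genotypes))) {
    calls <- genotypes[, j]
    gt <- ifelse(is.na(calls), "./.", gt_code[calls + 1L])
    writeLines(paste(c(panel$chrom[j], panel$pos[j], panel$rsid[j],
                       ref[j], alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GWAS-catalog-style lead-SNP list
#'
#' Expects a TSV with columns `rsid`, `trait`, `trait_class` (e.g.
#' `cancer` / `non-cancer`) and `ancestry`. Rows are filtered to the
#' requested ancestry label and reduced to unique `(rsid, trait_class)`
#' pairs. The column dialect is fixed here; catalog downloads must be
#' mapped onto it beforehand.
#'
#' @param path TSV file.
#' @param ancestry ancestry label to retain (default `"EUR"`); `NULL`
#'   keeps all rows.
#' @return data.frame with unique `rsid`, `trait_class` pairs.
#' @export
read_catalog <- function(path, ancestry = "EUR") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid", "trait", "trait_class", "ancestry")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("catalog file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(ancestry)) tab <- tab[tab$ancestry == ancestry, , drop = FALSE]
  out <- unique(tab[, c("rsid", "trait_class")])
  rownames(out) <- NULL
  if (!nrow(out)) warning("catalog is empty after filtering", call. = FALSE)
  out
}

#' Read a per-sample clinical table
#'
#' TSV with required column `sample_id` (unique) and any of
#' `age_at_diagnosis` (years), `sex` (`female`/`male`/`unknown`),
#' `carrier_status`, `endpoint_time`, `endpoint_event` (0/1),
#' `endpoint_kind` (`PFI`/`PFS`/`none`).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(tab$sample_id))
    stop("clinical file lacks required column(s): sample_id", call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  if (!is.null(tab$endpoint_time) && any(tab$endpoint_time < 0, na.rm = TRUE))
    stop("endpoint_time must be non-negative", call. = FALSE)
  if (!is.null(tab$endpoint_event) &&
      !all(tab$endpoint_event %in% c(0, 1, NA)))
    stop("endpoint_event must be 0 or 1", call. = FALSE)
  if (!is.null(tab$age_at_diagnosis) &&
      any(tab$age_at_diagnosis <= 0, na.rm = TRUE))
    stop("age_at_diagnosis must be positive", call. = FALSE)
  tab
}

#' Read an expression matrix
#'
#' TSV with gene/probe ids in the first column and one column per sample.
#'
#' @param path TSV file.
#' @return numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, check.names = FALSE, row.names = 1)
  if (anyDuplicated(rownames(tab)))
    stop("duplicated gene/probe ids", call. = FALSE)
  as.matrix(tab)
}

#' Write an expression matrix as TSV
#' @param expression genes x samples matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  write.table(cbind(gene = rownames(expression),
                    as.data.frame(expression, check.names = FALSE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' TSV with columns `rsid_a`, `rsid_b`, `r2` and `distance` (base pairs);
#' the symmetric closure is implied and applied by consumers.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_ld_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid_a", "rsid_b", "r2", "distance")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("LD file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  check_fraction(tab$r2, "r2")
  tab
}

#' Write a result table as TSV
#' @param x data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
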