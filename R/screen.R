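#' Random discovery/validation split plan
#'
#' Draws `n_splits` independent uniform-random partitions of the samples
#' into a discovery and a validation half at the requested ratio. For an
#' odd sample count the discovery half receives the extra sample. With a
#' fixed seed the plan (and everything downstream of it) is reproducible
#' bit-for-bit.
#'
#' @param sample_ids character vector of at least 4 sample ids.
#' @param n_splits number of replicate splits (default 10).
#' @param ratio discovery fraction (default 0.5).
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `assignments` (logical
#'   samples x splits matrix, TRUE = discovery), `sample_ids`, `n_splits`,
#'   `ratio`, `seed`.
#' @export
make_splits <- function(sample_ids, n_splits = 10, ratio = 0.5,
                        seed = NULL) {
  n <- length(sample_ids)
  if (n < 4) stop("at least 4 samples are required", call. = FALSE)
  check_fraction(ratio, "ratio", open_min = TRUE, open_max = TRUE)
  stopifnot(n_splits >= 1)
  n_disc <- ceiling(n * ratio)
  assignments <- with_seed(seed, {
    vapply(seq_len(n_splits), function(i) {
      disc <- sample.int(n, n_disc)
      seq_len(n) %in% disc
    }, logical(n))
  })
  assignments <- matrix(assignments, nrow = n,
                        dimnames = list(sample_ids,
                                        paste0("split_", seq_len(n_splits))))
  structure(list(assignments = assignments, sample_ids = sample_ids,
                 n_splits = as.integer(n_splits), ratio = ratio,
                 seed = seed),
            class = "split_plan")
}

# dichotomized log-rank for every gene (rows) of an expression matrix on a
# sample subset; returns NA rows for genes that are constant or have no
# events in the subset (callers log/skip them)
screen_half <- function(expression, time, event, minprop) {
  genes <- rownames(expression)
  out <- data.frame(gene = genes, p = NA_real_, cutpoint = NA_real_,
                    direction = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    r <- tryCatch(
      dichotomized_logrank(expression[i, ], time, event, minprop = minprop),
      modscreen_error = function(e) NULL)
    if (!is.null(r)) {
      out$p[i] <- r$p; out$cutpoint[i] <- r$cutpoint
      out$direction[i] <- r$direction
    }
  }
  out
}

#' Repeated-split expression survival screen
#'
#' The resampled hit-calling procedure for expression modifiers of a
#' progression endpoint. Samples (after dropping those without an
#' endpoint) are split 50:50 into discovery and validation halves
#' `n_splits` times. In each split, every gene is dichotomized at its
#' maximally selected cut-point and tested by log-rank in the discovery
#' half; genes with raw `p < alpha` advance to the validation half, where
#' the cut-point and test are recomputed independently and the p-value is
#' Bonferroni-adjusted over the number of genes that advanced in that
#' split. A gene scores the split when its adjusted p is below `alpha`
#' and (when `require_direction`) the same side of the cut-point has the
#' worse survival in both halves. Genes scoring at least `hit_threshold`
#' of the splits are called hits.
#'
#' @param expression genes x samples matrix.
#' @param clinical data.frame with `sample_id`, `endpoint_time`,
#'   `endpoint_event` covering the expression columns.
#' @param n_splits,ratio,seed passed to [make_splits()].
#' @param alpha significance level (default 0.05).
#' @param hit_threshold minimum validated splits for a hit (default 6).
#' @param minprop cut-point support bound (default 0.1).
#' @param require_direction require the discovery and validation halves
#'   to agree on which expression side has worse survival (default TRUE).
#' @param bonferroni_scope `"per_split"` (default: adjust over the genes
#'   advanced in that split) or `"global"` (adjust over all genes).
#' @return object of class `screen_result`: data.frame with one row per
#'   gene (`gene`, `hit_count`, `is_hit`, `n_advanced_mean`), with the
#'   per-split detail table in `attr(, "detail")` and the split plan in
#'   `attr(, "plan")`.
#' @export
run_split_screen <- function(expression, clinical, n_splits = 10,
                             ratio = 0.5, alpha = 0.05, hit_threshold = 6,
                             minprop = 0.1, require_direction = TRUE,
                             bonferroni_scope = c("per_split", "global"),
                             seed = NULL) {
  bonferroni_scope <- match.arg(bonferroni_scope)
  check_fraction(alpha, "alpha", open_min = TRUE)
  cl <- clinical[match(colnames(expression), clinical$sample_id), ]
  usable <- complete.cases(cl[, c("endpoint_time", "endpoint_event")])
  cl <- cl[usable, ]; expression <- expression[, usable, drop = FALSE]
  # canonical sample order so results do not depend on input column order
  ord <- order(cl$sample_id)
  cl <- cl[ord, ]; expression <- expression[, ord, drop = FALSE]
  plan <- make_splits(cl$sample_id, n_splits = n_splits, ratio = ratio,
                      seed = seed)
  genes <- rownames(expression)
  validated <- matrix(FALSE, length(genes), plan$n_splits,
                      dimnames = list(genes, colnames(plan$assignments)))
  detail <- list()
  n_advanced <- integer(plan$n_splits)
  for (s in seq_len(plan$n_splits)) {
    disc <- plan$assignments[, s]
    d <- screen_half(expression[, disc, drop = FALSE],
                     cl$endpoint_time[disc], cl$endpoint_event[disc],
                     minprop)
    adv <- d$gene[!is.na(d$p) & d$p < alpha]
    n_advanced[s] <- length(adv)
    if (length(adv)) {
      v <- screen_half(expression[adv, !disc, drop = FALSE],
                       cl$endpoint_time[!disc], cl$endpoint_event[!disc],
                       minprop)
      m <- if (bonferroni_scope == "per_split") length(adv) else
        length(genes)
      v$p_adjusted <- ifelse(is.na(v$p), NA, bonferroni(pmax(v$p, 1e-300), m))
      dir_d <- d$direction[match(v$gene, d$gene)]
      ok <- !is.na(v$p_adjusted) & v$p_adjusted < alpha &
        (!require_direction | (v$direction == dir_d))
      validated[v$gene[ok], s] <- TRUE
      detail[[s]] <- data.frame(split = s, gene = v$gene,
                                discovery_p = d$p[match(v$gene, d$gene)],
                                validation_p = v$p,
                                validation_p_adjusted = v$p_adjusted,
                                discovery_direction = dir_d,
                                validation_direction = v$direction,
                                validated = ok, stringsAsFactors = FALSE)
    }
  }
  hit_count <- rowSums(validated)
  res <- data.frame(gene = genes, hit_count = as.integer(hit_count),
                    is_hit = hit_count >= hit_threshold,
                    stringsAsFactors = FALSE)
  attr(res, "detail") <- if (length(detail)) do.call(rbind, detail) else NULL
  attr(res, "plan") <- plan
  attr(res, "n_advanced") <- n_advanced
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Two-cohort shared-probe survival screen
#'
#' The fixed discovery/validation variant used when two cohorts were
#' profiled on different array platforms: only probes shared between the
#' platforms are analysed. Each shared probe is dichotomized and tested
#' in the discovery cohort; probes with raw `p < alpha` are retested in
#' the validation cohort (own cut-point), Bonferroni-adjusted over the
#' number advanced, and kept when the adjusted p is below `alpha` with a
#' consistent direction.
#'
#' @param expr_discovery,expr_validation probes x samples matrices.
#' @param clin_discovery,clin_validation clinical tables (`sample_id`,
#'   `endpoint_time`, `endpoint_event`).
#' @param shared_probes probe ids present on both platforms; defaults to
#'   the rowname intersection. An empty set is an error.
#' @param alpha,minprop as in [run_split_screen()].
#' @return data.frame with one row per shared probe: discovery and
#'   validation p-values, adjusted p, directions, and `validated`.
#' @export
run_two_cohort_screen <- function(expr_discovery, clin_discovery,
                                  expr_validation, clin_validation,
                                  shared_probes = NULL, alpha = 0.05,
                                  minprop = 0.1) {
  if (is.null(shared_probes))
    shared_probes <- intersect(rownames(expr_discovery),
                               rownames(expr_validation))
  shared_probes <- intersect(
    intersect(shared_probes, rownames(expr_discovery)),
    rownames(expr_validation))
  if (!length(shared_probes))
    stop("the shared-probe set is empty", call. = FALSE)
  prep <- function(expr, clin) {
    cl <- clin[match(colnames(expr), clin$sample_id), ]
    usable <- complete.cases(cl[, c("endpoint_time", "endpoint_event")])
    list(expr = expr[shared_probes, usable, drop = FALSE], cl = cl[usable, ])
  }
  dd <- prep(expr_discovery, clin_discovery)
  vv <- prep(expr_validation, clin_validation)
  d <- screen_half(dd$expr, dd$cl$endpoint_time, dd$cl$endpoint_event,
                   minprop)
  adv <- d$gene[!is.na(d$p) & d$p < alpha]
  out <- data.frame(probe = shared_probes,
                    discovery_p = d$p, discovery_direction = d$direction,
                    advanced = d$gene %in% adv,
                    validation_p = NA_real_,
                    validation_p_adjusted = NA_real_,
                    validation_direction = NA_character_,
                    validated = FALSE, stringsAsFactors = FALSE)
  if (length(adv)) {
    v <- screen_half(vv$expr[adv, , drop = FALSE],
                     vv$cl$endpoint_time, vv$cl$endpoint_event, minprop)
    i <- match(v$gene, out$probe)
    out$validation_p[i] <- v$p
    out$validation_p_adjusted[i] <-
      ifelse(is.na(v$p), NA, bonferroni(pmax(v$p, 1e-300), length(adv)))
    out$validation_direction[i] <- v$direction
    out$validated[i] <- !is.na(out$validation_p_adjusted[i]) &
      out$validation_p_adjusted[i] < alpha &
      out$validation_direction[i] == out$discovery_direction[i]
  }
  out
}
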