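#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function (censored observations
#' at an event time count as at risk for that time; the step function is
#' right-continuous). A thin wrapper around [survival::survfit()] that
#' returns the curve as a plain table suitable for TSV export and
#' plotting.
#'
#' @param time non-negative event/censoring times.
#' @param event event indicator, 1 = event, 0 = censored.
#' @param unit time unit label carried through (e.g. `"days"`, `"years"`).
#' @return object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(time, event, unit = "days") {
  if (any(time < 0)) stop("negative times are not allowed", call. = FALSE)
  stopifnot(length(time) == length(event), all(event %in% 0:1))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "unit") <- unit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
plot.km_curve <- function(x, xlab = NULL, ylab = "Survival probability",
                          ...) {
  if (is.null(xlab))
    xlab <- paste0("Time (", attr(x, "unit") %||% "time", ")")
  plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
       ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Kaplan-Meier curve as TSV
#'
#' @param km a [kaplan_meier()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_km_tsv <- function(km, path) {
  write.table(as.data.frame(km), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Signed log-rank z for each column of a logical membership matrix G
# (TRUE = "group 1"). At each distinct event time t with d events among n
# at risk, group 1 contributes observed d1 and expected d * n1/n with
# hypergeometric variance d * (n-d)/(n-1) * n1/n * (1 - n1/n). Returns
# z = (O - E)/sqrt(V) per column (0 where V = 0), plus O, E, V. Positive z
# means group 1 has more events than expected (worse survival).
logrank_core <- function(time, event, G) {
  G <- as.matrix(G)
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  G_s <- G[ord, , drop = FALSE]
  # suffix sums: number of group-1 samples with time >= t_s[i]
  n1_suffix <- apply(G_s, 2, function(col) rev(cumsum(rev(col))))
  n1_suffix <- matrix(n1_suffix, nrow = n)
  n_suffix <- n - seq_len(n) + 1L
  ev_rows <- which(e_s == 1)
  if (!length(ev_rows))
    stop_modscreen("no events in the data", "modscreen_no_events")
  first_at <- match(t_s, t_s)            # first row index of each time
  d_tab <- tapply(e_s, first_at, sum)    # events per distinct time
  et <- as.integer(names(d_tab))[d_tab > 0]
  d <- as.numeric(d_tab[d_tab > 0])
  n_at <- n_suffix[et]
  n1_at <- n1_suffix[et, , drop = FALSE]
  # observed group-1 events per distinct event time
  ev_first <- first_at[ev_rows]
  O1 <- rowsum(G_s[ev_rows, , drop = FALSE] * 1, group = ev_first)
  O1 <- O1[match(et, as.integer(rownames(O1))), , drop = FALSE]
  O1[is.na(O1)] <- 0
  p1 <- n1_at / n_at
  E1 <- d * p1
  vfac <- ifelse(n_at > 1, d * (n_at - d) / (n_at - 1), 0)
  V1 <- vfac * p1 * (1 - p1)
  O <- colSums(O1); E <- colSums(E1); V <- colSums(V1)
  z <- ifelse(V > 0, (O - E) / sqrt(V), 0)
  list(z = z, O = O, E = E, V = V)
}

#' Mantel-Haenszel log-rank test
#'
#' Compares survival between two groups by pooling, over the distinct
#' event times, the hypergeometric observed-minus-expected event counts:
#' the statistic is \eqn{(\sum O - E)^2 / \sum V}, referred to chi-square
#' with 1 degree of freedom.
#'
#' @param time,event survival data (event 1 / censored 0).
#' @param group two-level grouping (factor, character or logical).
#' @return list with `chisq`, `df`, `p`, per-group `observed` and
#'   `expected`, and `z`, the signed standardized statistic for the first
#'   group level (positive = first level has worse survival).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2)
    stop("exactly two non-empty groups required", call. = FALSE)
  g <- droplevels(g)
  if (sum(event) == 0)
    stop_modscreen("no events in the data", "modscreen_no_events")
  core <- logrank_core(time, event, matrix(g == levels(g)[1], ncol = 1))
  chisq <- core$z^2
  obs <- c(core$O, sum(event) - core$O)
  expd <- c(core$E, sum(event) - core$E)
  names(obs) <- names(expd) <- levels(g)
  list(chisq = unname(chisq), df = 1L,
       p = unname(pchisq(chisq, 1, lower.tail = FALSE)),
       observed = obs, expected = expd, z = unname(core$z))
}

#' Maximally selected rank-statistic cut-point
#'
#' Finds the dichotomizing threshold for a continuous marker (e.g. a
#' gene's expression) that maximizes the absolute standardized log-rank
#' statistic between the induced low/high groups. Candidate cut-points
#' are the midpoints between consecutive distinct sorted marker values
#' such that both sides retain at least `ceil(minprop * n)` samples; ties
#' in the maximal statistic are broken toward the smaller cut-point.
#'
#' @param values numeric marker vector, one per sample; must not be
#'   constant.
#' @param time,event survival data.
#' @param minprop minimum fraction of samples on each side of the
#'   cut-point, in (0, 0.5) (default 0.1).
#' @return object of class `cutpoint_result`: list with `cutpoint`,
#'   `statistic` (signed z of the low group at the optimum),
#'   `abs_statistic`, `n_low`, `n_high`, `candidate_range` and
#'   `n_candidates`.
#' @export
maxstat_cutpoint <- function(values, time, event, minprop = 0.1) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  check_fraction(minprop, "minprop", open_min = TRUE, max = 0.5,
                 open_max = TRUE)
  n <- length(values)
  if (n < ceiling(1 / minprop))
    stop("too few samples for the requested `minprop`", call. = FALSE)
  sv <- sort(unique(values))
  if (length(sv) < 2)
    stop_modscreen("no valid cutpoint: marker values are constant",
                   "modscreen_constant_marker")
  mids <- (sv[-length(sv)] + sv[-1]) / 2
  k_min <- ceiling(minprop * n)
  n_low <- vapply(mids, function(ct) sum(values <= ct), integer(1))
  ok <- n_low >= k_min & (n - n_low) >= k_min
  if (!any(ok))
    stop_modscreen("no valid cutpoint under the `minprop` constraint",
                   "modscreen_constant_marker")
  mids <- mids[ok]; n_low <- n_low[ok]
  G <- outer(values, mids, `<=`)     # low-group membership per candidate
  core <- logrank_core(time, event, G)
  best <- which.max(abs(core$z))     # first max = smaller cut-point
  structure(list(cutpoint = mids[best], statistic = core$z[best],
                 abs_statistic = abs(core$z[best]),
                 n_low = n_low[best], n_high = n - n_low[best],
                 candidate_range = range(mids),
                 n_candidates = length(mids)),
            class = "cutpoint_result")
}

#' Log-rank test at the maximally selected cut-point
#'
#' Dichotomizes a marker at its [maxstat_cutpoint()] (values above the
#' cut-point are "high", below are "low") and reports the log-rank
#' comparison of the two groups. The reported p-value is the naive
#' log-rank p of the selected split — no adjustment is made for having
#' selected the cut-point on the same data, so under the null it is
#' anti-conservative; downstream screens rely on independent validation
#' splits, not on this p-value's calibration.
#'
#' @inheritParams maxstat_cutpoint
#' @return list with `cutpoint`, `chisq`, `p`, `n_low`, `n_high` and
#'   `direction` (`"low_worse"` or `"high_worse"`: which side has more
#'   events than expected).
#' @export
dichotomized_logrank <- function(values, time, event, minprop = 0.1) {
  cp <- maxstat_cutpoint(values, time, event, minprop = minprop)
  z_low <- cp$statistic
  chisq <- z_low^2
  list(cutpoint = cp$cutpoint, chisq = unname(chisq),
       p = unname(pchisq(chisq, 1, lower.tail = FALSE)),
       n_low = cp$n_low, n_high = cp$n_high,
       direction = if (z_low >= 0) "low_worse" else "high_worse")
}
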