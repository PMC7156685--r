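#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. The statistic is
#' `U = #\{(a, b) : a > b\} + ties/2` (the base-R Wilcoxon `W`
#' convention for the first sample). The exact two-sided p-value sums the
#' permutation null over all rank splits (via the Wilcoxon null
#' distribution, valid only without ties); the normal approximation uses
#' the tie-corrected variance with a continuity correction. `"auto"`
#' chooses the exact test when both samples have at most 12 observations
#' and no ties are present — with two cohorts of a few dozen patients the
#' approximation is the common path, and which of the two was used is
#' recorded in the result.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `U`, `p` (two-sided, capped at 1) and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p        # 2/6
#' mann_whitney_u(1:6, 7:12)$p               # 2/choose(12, 6)
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs a > b, + ties/2
  ties <- any(duplicated(c(a, b)))
  if (mode == "exact" && ties)
    stop("exact mode requires untied data; use \"normal_approx\"",
         call. = FALSE)
  exact <- switch(mode,
                  exact = TRUE,
                  normal_approx = FALSE,
                  auto = !ties && n1 <= 12 && n2 <= 12)
  if (exact) {
    p <- if (U > n1 * n2 / 2) {
      pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      pwilcox(U, n1, n2)
    }
    p <- min(1, 2 * p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal_approx"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (U == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = unname(U), p = unname(p), method = method)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic over k groups,
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \bar R)^2 \Big/
#'   \Big(1 - \sum_t (t^3 - t)/(N^3 - N)\Big),}
#' with the p-value from a chi-square distribution on k - 1 degrees of
#' freedom. When all observations are equal the tie correction degenerates
#' and the result is H = 0, p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `H`, `df` and `p`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$H  # 4.571
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("at least two groups required", call. = FALSE)
  if (any(lengths(groups) == 0))
    stop("all groups must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (N + 1)
  tab <- table(r)
  corr <- 1 - sum(tab^3 - tab) / (N^3 - N)
  df <- length(groups) - 1L
  if (corr <= 0) return(list(H = 0, df = df, p = 1))  # all values equal
  H <- H / corr
  list(H = unname(H), df = df, p = unname(pchisq(H, df, lower.tail = FALSE)))
}

#' Bonferroni adjustment of a p-value
#'
#' `min(1, m * p)` for `m` hypotheses.
#'
#' @param p raw p-value(s) in (0, 1\].
#' @param m number of tests, at least 1.
#' @return adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni(0.00019, 6)   # 0.00114
#' bonferroni(0.00019, 23)  # 0.00437
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop("`m` must be at least 1", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("`p` must be in (0, 1]", call. = FALSE)
  pmin(1, m * p)
}
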