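# Group statistics: two-group t-tests with a Levene-gated pooled/Welch
# choice, ANOVA / Kruskal-Wallis for more than two groups. Alpha is fixed at
# 0.05 two-sided throughout.

.alpha <- 0.05

.comparison <- function(endpoint, test, statistic, df, p, levene_p = NA_real_,
                        note = NA_character_) {
  data.frame(endpoint = endpoint, test = test, statistic = statistic,
             df = df, p = p, levene_p = levene_p,
             significant = is.finite(p) && p < .alpha, note = note,
             stringsAsFactors = FALSE)
}

#' Levene's test for homogeneity of variances
#'
#' Mean-centered by default; `center = "median"` gives the Brown-Forsythe
#' variant. Thin wrapper over `car::leveneTest`.
#'
#' @param values numeric vector.
#' @param group grouping vector of the same length.
#' @param center `"mean"` (default) or `"median"`.
#' @return the p-value.
#' @export
levene_p <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") base::mean else stats::median
  lt <- car::leveneTest(values, factor(group), center = fun)
  lt[["Pr(>F)"]][1L]
}

#' Independent two-group comparison of means
#'
#' In `"auto"` mode (default) Levene's test (mean-centered) gates the
#' variance assumption: pooled-variance t-test when Levene p >= 0.05, Welch
#' otherwise. The variant actually used is always recorded in the returned
#' row -- the mode never switches silently. Two degenerate zero-variance
#' groups with equal means return p = 1 with a note.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param mode `"auto"`, `"pooled"` or `"welch"`.
#' @param endpoint label carried into the output.
#' @return a one-row comparison data.frame: `endpoint`, `test`, `statistic`,
#'   `df`, `p`, `levene_p`, `significant`, `note`.
#' @export
two_group_test <- function(a, b, mode = c("auto", "pooled", "welch"),
                           endpoint = "endpoint") {
  mode <- match.arg(mode)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(.comparison(endpoint, "t-pooled", 0, length(a) + length(b) - 2L,
                         1, note = "degenerate: zero variance, equal means"))
    stop("zero variance in both groups with unequal means: t undefined",
         call. = FALSE)
  }
  lp <- if (mode == "auto")
    levene_p(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
  else NA_real_
  pooled <- switch(mode, auto = lp >= .alpha, pooled = TRUE, welch = FALSE)
  tt <- stats::t.test(a, b, var.equal = pooled)
  .comparison(endpoint, if (pooled) "t-pooled" else "t-welch",
              unname(tt$statistic), unname(tt$parameter), tt$p.value,
              levene_p = lp)
}

#' Two-group t-test from summary statistics
#'
#' Entry point for printed mean / SD / n summaries when raw values are not
#' available.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param mode `"pooled"` (default) or `"welch"`.
#' @param endpoint label carried into the output.
#' @return a one-row comparison data.frame.
#' @examples
#' two_group_test_summary(13.9, 2.1, 5, 10.9, 1.2, 5)
#' @export
two_group_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                   mode = c("pooled", "welch"),
                                   endpoint = "endpoint") {
  mode <- match.arg(mode)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (mode == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  .comparison(endpoint, if (mode == "pooled") "t-pooled" else "t-welch",
              tstat, df, p)
}

#' Compare means across three or more groups
#'
#' One-way ANOVA for means; Kruskal-Wallis (mid-rank ties correction, as in
#' `stats::kruskal.test`) for ordinal endpoints such as toxicity grades.
#' All-identical observations return H = 0, p = 1.
#'
#' @param groups named list of numeric vectors.
#' @param mode `"anova"` or `"kruskal"`.
#' @param endpoint label carried into the output.
#' @return a one-row comparison data.frame.
#' @export
multi_group_test <- function(groups, mode = c("anova", "kruskal"),
                             endpoint = "endpoint") {
  mode <- match.arg(mode)
  k <- length(groups)
  if (k < 2L) stop("at least two groups are required", call. = FALSE)
  nmin <- min(lengths(groups))
  if (mode == "anova" && nmin < 2L)
    stop("ANOVA needs n >= 2 per group", call. = FALSE)
  if (nmin < 1L) stop("empty group", call. = FALSE)
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), lengths(groups)))
  if (mode == "anova") {
    an <- stats::anova(stats::lm(v ~ g))
    lp <- levene_p(v, g)
    .comparison(endpoint, "anova", an[1, "F value"], an[1, "Df"],
                an[1, "Pr(>F)"], levene_p = lp)
  } else {
    if (stats::var(v) == 0)
      return(.comparison(endpoint, "kruskal-wallis", 0, k - 1L, 1,
                         note = "degenerate: all observations identical"))
    kw <- stats::kruskal.test(v, g)
    .comparison(endpoint, "kruskal-wallis", unname(kw$statistic),
                unname(kw$parameter), kw$p.value)
  }
}
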