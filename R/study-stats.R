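#' @include AllGenerics.R
NULL

#' Kolmogorov-Smirnov normality screening
#'
#' One-sample K-S test against a normal with mean and SD estimated from the
#' sample, i.e. the Lilliefors-corrected test (testing against a fully
#' specified normal is almost never what a mean/SD screening step does). The
#' p-value uses the published Lilliefors approximation for n >= 4; for n = 3
#' it is obtained by Monte-Carlo calibration of the statistic (the test has
#' essentially no power there in any case).
#'
#' @param x numeric sample, n >= 3, not constant.
#' @return list with \code{statistic} (D, in [0, 1]), \code{p} and \code{n}.
#' @export
ksNormality <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant sample: normality test degenerate")
  if (n >= 4L) {
    t <- nortest::lillie.test(x)
    return(list(statistic = unname(t$statistic), p = unname(t$p.value), n = n))
  }
  ## n = 3: Lilliefors statistic with Monte-Carlo p, RNG state preserved
  lillieD <- function(z) {
    z <- sort((z - mean(z)) / stats::sd(z))
    pz <- stats::pnorm(z)
    m <- length(z)
    max(seq_len(m) / m - pz, pz - (seq_len(m) - 1) / m)
  }
  D <- lillieD(x)
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state,
                                      envir = globalenv()))
  set.seed(20260924L)
  null <- replicate(2000L, lillieD(stats::rnorm(n)))
  list(statistic = D, p = mean(null >= D), n = n)
}

.anovaResult <- function(msb, msw, dfb, dfw) {
  if (msw == 0) {
    if (msb == 0)
      return(new("AnovaResult", F = 0, df_between = as.integer(dfb),
                 df_within = as.integer(dfw), p = 1, ms_between = 0,
                 ms_within = 0, infinite_F = FALSE))
    return(new("AnovaResult", F = Inf, df_between = as.integer(dfb),
               df_within = as.integer(dfw), p = 0, ms_between = msb,
               ms_within = 0, infinite_F = TRUE))
  }
  F <- msb / msw
  new("AnovaResult", F = max(F, 0), df_between = as.integer(dfb),
      df_within = as.integer(dfw),
      p = stats::pf(F, dfb, dfw, lower.tail = FALSE),
      ms_between = msb, ms_within = msw, infinite_F = FALSE)
}

#' One-way ANOVA on raw samples
#'
#' Classical fixed-effects one-way analysis of variance via the standard
#' linear-model decomposition (stats::aov). Zero within-group variance with
#' unequal means yields a flagged infinite F rather than an error.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2);
#'   alternatively a single numeric vector together with \code{labels}.
#' @param labels optional grouping factor when \code{groups} is a vector.
#' @return an [AnovaResult-class]
#' @examples
#' anovaOneway(list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2)))
#' @export
anovaOneway <- function(groups, labels = NULL) {
  if (!is.null(labels)) groups <- split(as.numeric(groups), labels)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ## suppress stats' "essentially perfect fit" warning: the degenerate case
  ## is detected and flagged explicitly below
  tab <- withCallingHandlers(
    stats::anova(stats::aov(y ~ g)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  msw <- tab[["Mean Sq"]][2L]
  msb <- tab[["Mean Sq"]][1L]
  ## exactly-constant groups: the QR decomposition leaves numerical dust in
  ## the residual mean square; detect the degenerate case directly
  if (all(vapply(groups, stats::var, 1) == 0)) msw <- 0
  .anovaResult(msb, if (is.finite(msw)) msw else 0,
               tab[["Df"]][1L], tab[["Df"]][2L])
}

#' One-way ANOVA from summary cells
#'
#' Recovers the exact classical one-way ANOVA from per-group mean, SD and n
#' alone: SS_between = sum n_i (m_i - m_bar)^2 with m_bar the n-weighted
#' grand mean, and MS_within = sum (n_i - 1) s_i^2 / sum (n_i - 1). This is
#' algebraically identical to [anovaOneway()] on the raw samples, and lets
#' the printed mean/SD cells of published tables be re-analysed directly.
#'
#' @param cells data.frame with columns mean, sd, n (one row per group), or a
#'   list of such rows.
#' @return an [AnovaResult-class]
#' @examples
#' anovaFromSummary(data.frame(mean = c(217.5, 436.3, 702.5, 1039.8),
#'                             sd = c(60.1, 59.6, 42.9, 93.9), n = 8))
#' @export
anovaFromSummary <- function(cells) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("mean", "sd", "n") %in% names(cells)))
  k <- nrow(cells)
  if (k < 2L) stop("need at least 2 cells")
  if (any(cells$n < 2L)) stop("every cell needs n >= 2")
  if (any(cells$sd < 0)) stop("sd: must be >= 0")
  n <- cells$n; m <- cells$mean; s <- cells$sd
  N <- sum(n)
  gm <- sum(n * m) / N
  msb <- sum(n * (m - gm)^2) / (k - 1)
  msw <- sum((n - 1) * s^2) / sum(n - 1)
  .anovaResult(msb, msw, k - 1L, N - k)
}

#' Student-Newman-Keuls post hoc test
#'
#' Stepwise studentized-range comparisons after a one-way ANOVA: group means
#' are sorted, each pair is tested with the critical value of the studentized
#' range for the span r of the pair (qtukey at the ANOVA's error df), and the
#' standard SNK protection applies — a non-rejected pair blocks every pair it
#' encloses. Ties in means are handled in stable sort order. Unequal group
#' sizes use the harmonic-mean standard error.
#'
#' @param groups named list of numeric samples.
#' @param alpha per-step significance level (default 0.05).
#' @return a [PosthocResult-class]
#' @examples
#' snkPosthoc(list(a = rnorm(8), b = rnorm(8, 10), c = rnorm(8, 20)))
#' @export
snkPosthoc <- function(groups, alpha = 0.05) {
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  fit <- anovaOneway(groups)
  msw <- fit@ms_within; dfw <- fit@df_within
  means <- vapply(groups, mean, 1)
  ns <- vapply(groups, length, 1L)
  ord <- order(means)   # stable: ties keep input order
  k <- length(groups)
  rows <- list()
  not_rejected <- list()   # sorted-position intervals of accepted pairs
  for (span in seq(k, 2L)) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      gi <- ord[i]; gj <- ord[j]
      se <- sqrt(msw / 2 * (1 / ns[gi] + 1 / ns[gj]))
      q <- if (se > 0) (means[gj] - means[gi]) / se else
        if (means[gj] > means[gi]) Inf else 0
      qc <- stats::qtukey(1 - alpha, span, dfw)
      blocked <- any(vapply(not_rejected, function(iv)
        iv[1L] <= i && j <= iv[2L], logical(1)))
      reject <- !blocked && q > qc
      if (!reject) not_rejected[[length(not_rejected) + 1L]] <- c(i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = names(groups)[gi], group2 = names(groups)[gj],
        r = span, q = q, q_crit = qc, reject = reject, blocked = blocked,
        stringsAsFactors = FALSE)
    }
  }
  new("PosthocResult", comparisons = do.call(rbind, rows),
      alpha = alpha, df_within = as.integer(dfw))
}

#' Pearson correlation with strength label
#'
#' Product-moment correlation with two-sided p from the t transform on
#' n - 2 df, labelled by the convention of the reference study: |r| > 0.8
#' high, 0.5 <= |r| <= 0.8 moderate, otherwise weak.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return a [CorrelationResult-class]
#' @examples
#' pearsonCorrelation(1:4, c(1, 3, 2, 4))   # r = 0.8, moderate
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson r undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  strength <- if (abs(r) > 0.8) "high" else if (abs(r) >= 0.5) "moderate"
              else "weak"
  new("CorrelationResult", r = r, p = unname(ct$p.value), n = as.integer(n),
      strength = strength)
}
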