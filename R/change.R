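# Two-period change statistics: the P1 (1984-1999) vs P2 (2000-2018,
# 2012 absent) comparison framework — period means, Wilcoxon rank-sum
# tests, OLS trends, integer percent differences and lake change vectors.

#' The two comparison periods
#'
#' P1 = 1984-1999 (n = 16) and P2 = 2000-2018 excluding the 2012 satellite
#' gap (n = 18).
#'
#' @param p1,p2 integer year vectors
#' @return a `period_definition`
#' @export
period_definition <- function(p1 = 1984:1999,
                              p2 = setdiff(2000:2018, 2012)) {
  stopifnot(length(intersect(p1, p2)) == 0, max(p1) < min(p2))
  structure(list(P1 = as.integer(p1), P2 = as.integer(p2)),
            class = "period_definition")
}

#' Integer percent change between two means
#'
#' `round(100 * (m2 - m1) / m1)` with half-away-from-zero rounding (so the
#' printed-style integers -27, -47, +7 are reproduced deterministically;
#' base `round()` rounds half to even).
#'
#' @param m1 first-period mean (non-zero)
#' @param m2 second-period mean
#' @return integer percent
#' @export
percent_change <- function(m1, m2) {
  if (any(m1 == 0)) stop("percent change undefined for zero baseline mean")
  x <- 100 * (m2 - m1) / m1
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Wilcoxon / Mann-Whitney rank-sum test
#'
#' U is the Mann-Whitney statistic for `x` (number of (x, y) pairs with
#' x > y, counting ties as 1/2, i.e. midranks). The two-sided p-value is
#' exact (null distribution of U by the standard counting recurrence) when
#' `max(n1, n2) <= exact_max` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty)
#' @param exact_max largest sample size for the exact path (default 10)
#' @return list with `U`, `p`, `method`
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && max(n1, n2) <= exact_max) {
    # exact: P(U <= u) from the distribution of the Mann-Whitney count
    u <- round(U)
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    list(U = U, p = min(p, 1), method = "exact")
  } else {
    n <- n1 + n2
    tt <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    mu <- n1 * n2 / 2
    z <- U - mu
    cc <- sign(z) * 0.5  # continuity correction toward the mean
    z <- if (sigma2 > 0) (z - cc) / sqrt(sigma2) else 0
    p <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1
    list(U = U, p = min(p, 1), method = "normal")
  }
}

#' Ordinary least-squares linear trend
#'
#' Regresses values on year; returns the slope, its standard error and the
#' two-sided t-test p-value. A zero-variance residual with non-zero spread
#' in year and constant values yields slope 0 with `p = NaN` and
#' `degenerate = TRUE` (the t statistic is undefined).
#'
#' @param years,values numeric sequences (NA values dropped pairwise)
#' @return list with `slope`, `se`, `p`, `degenerate`
#' @export
linear_trend <- function(years, values) {
  ok <- !is.na(years) & !is.na(values)
  years <- years[ok]; values <- values[ok]
  n <- length(years)
  if (n < 3) stop("need at least 3 points for a trend")
  if (var(years) == 0) stop("all years identical; trend undefined")
  xc <- years - mean(years)
  slope <- sum(xc * values) / sum(xc^2)
  intercept <- mean(values) - slope * mean(years)
  resid <- values - intercept - slope * years
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sum(xc^2))
  if (se == 0) {
    degen <- var(values) == 0
    return(list(slope = slope, se = 0,
                p = if (degen) NaN else 0, degenerate = degen))
  }
  tval <- slope / se
  list(slope = slope, se = se, p = 2 * pt(-abs(tval), n - 2),
       degenerate = FALSE)
}

#' Two-period summary of an annual series
#'
#' Period means and SDs, absolute change (P2 - P1), rounded integer
#' percent difference, Wilcoxon rank-sum U and p, and the OLS trend over
#' the full record. Missing years (e.g. 2012) are skipped.
#'
#' @param years,values the annual record
#' @param periods a [period_definition()]
#' @param watershed,region,variable optional tags carried in the result
#' @return a `period_summary`
#' @export
period_summary <- function(years, values, periods = period_definition(),
                           watershed = NA, region = NA, variable = NA) {
  ok <- !is.na(values)
  v1 <- values[ok & years %in% periods$P1]
  v2 <- values[ok & years %in% periods$P2]
  if (length(v1) < 2 || length(v2) < 2)
    stop("each period needs at least 2 observations")
  m1 <- mean(v1); m2 <- mean(v2)
  w <- wilcoxon_rank_sum(v1, v2)
  tr <- linear_trend(years[ok], values[ok])
  structure(list(watershed = watershed, region = region,
                 variable = variable,
                 n1 = length(v1), n2 = length(v2),
                 mean1 = m1, sd1 = sd(v1), mean2 = m2, sd2 = sd(v2),
                 change = m2 - m1,
                 pct = if (m1 != 0) percent_change(m1, m2) else NA_integer_,
                 wilcox_U = w$U, wilcox_p = w$p,
                 slope = tr$slope, slope_se = tr$se, slope_p = tr$p),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf(
    "<period_summary>%s P1 %.4g (sd %.3g, n=%d) -> P2 %.4g (sd %.3g, n=%d)\n",
    if (is.na(x$variable)) "" else paste0(" ", x$variable),
    x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  cat(sprintf("  change %.4g (%d%%), Wilcoxon p=%.3g, slope %.4g (p=%.3g)\n",
              x$change, x$pct, x$wilcox_p, x$slope, x$slope_p))
  invisible(x)
}

#' Lake change vector between periods
#'
#' Areas are scaled by the record maximum (1984-2018) to a proportion of
#' maximum inundation; the vector runs from (P1 mean proportion, P1
#' proportion variance) to the P2 pair, tracing lake transitions along
#' wet/dry and stable/variable gradients.
#'
#' @param years,areas annual lake areas
#' @param periods a [period_definition()]
#' @return a `change_vector`: per-period mean and variance of the
#'   proportion-of-maximum series, the delta vector, its magnitude and
#'   direction (radians, atan2(dvar, dmean))
#' @export
change_vector <- function(years, areas, periods = period_definition()) {
  ok <- !is.na(areas)
  mx <- max(areas[ok])
  if (!is.finite(mx) || mx <= 0) stop("record maximum area must be > 0")
  prop <- areas / mx
  p1 <- prop[ok & years %in% periods$P1]
  p2 <- prop[ok & years %in% periods$P2]
  if (length(p1) < 2 || length(p2) < 2)
    stop("each period needs at least 2 observations")
  dmean <- mean(p2) - mean(p1)
  dvar <- var(p2) - var(p1)
  structure(list(mean1 = mean(p1), var1 = var(p1),
                 mean2 = mean(p2), var2 = var(p2),
                 dmean = dmean, dvar = dvar,
                 magnitude = sqrt(dmean^2 + dvar^2),
                 direction = atan2(dvar, dmean)),
            class = "change_vector")
}

#' Regional rollup of period summaries
#'
#' Pools watershed summaries of one variable within regions: P1/P2 means
#' of the summed series (sums of the watershed period means), absolute and
#' integer percent change, and counts of watersheds significant at p < .05
#' by Wilcoxon and by OLS trend.
#'
#' @param summaries list of `period_summary` (tagged with region/variable)
#' @param alpha significance cut (default 0.05)
#' @return data.frame, one row per region x variable plus "all" rows when
#'   several regions are present
#' @export
regional_rollup <- function(summaries, alpha = 0.05) {
  stopifnot(length(summaries) >= 1)
  vars <- vapply(summaries, function(s) as.character(s$variable),
                 character(1))
  if (length(unique(vars)) > 1)
    stop("mixed variables/units in rollup: ",
         paste(unique(vars), collapse = ", "))
  regs <- vapply(summaries, function(s) as.character(s$region), character(1))
  one <- function(sel, tag) {
    m1 <- sum(vapply(summaries[sel], `[[`, numeric(1), "mean1"))
    m2 <- sum(vapply(summaries[sel], `[[`, numeric(1), "mean2"))
    data.frame(region = tag, variable = vars[1], n_watersheds = sum(sel),
               mean1 = m1, mean2 = m2, change = m2 - m1,
               pct = percent_change(m1, m2),
               n_wilcox_sig = sum(vapply(summaries[sel], `[[`, numeric(1),
                                         "wilcox_p") < alpha),
               n_trend_sig = sum(vapply(summaries[sel], `[[`, numeric(1),
                                        "slope_p") < alpha, na.rm = TRUE))
  }
  out <- do.call(rbind, lapply(unique(regs), function(r)
    one(regs == r, r)))
  if (length(unique(regs)) > 1)
    out <- rbind(out, one(rep(TRUE, length(regs)), "all"))
  rownames(out) <- NULL
  out
}

#' Write a rollup table as CSV
#' @param rollup data.frame from [regional_rollup()]
#' @param path CSV path
#' @export
write_rollup <- function(rollup, path) {
  write.csv(rollup, path, row.names = FALSE)
  invisible(path)
}
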