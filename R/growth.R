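#' Exponential growth rate from an OD600 time series
#'
#' The growth rate is the slope of ln(OD600) versus time over the exponential
#' phase. Because real curves carry lag and stationary phases, the exponential
#' window is selected automatically: all windows of at least `min_points`
#' consecutive points are fit by least squares on the log scale; windows with
#' a non-positive slope or R-squared below `r2_min` are discarded, and among
#' the rest the window whose slope has the largest t-statistic wins (ties go
#' to the longer window, then the earlier start). The t-statistic rewards
#' windows that are simultaneously steep, long and clean, so the selection
#' neither chases short noise-aligned stretches (as a raw max-slope rule
#' would) nor swallows lag or stationary boundary points (as a longest-window
#' rule would); on noiseless data every pure log-linear window fits exactly
#' and the tie-break returns the full exponential phase.
#'
#' @param series A data.frame with columns `time_h` (strictly increasing) and
#'   `od600` (dilution-corrected optical density).
#' @param min_points Minimum window length; default 4.
#' @param r2_min Minimum R-squared for a window to qualify; default 0.98.
#' @return A `growth_fit`: list with `alpha` (h^-1), `intercept` (ln OD at
#'   t = 0 extrapolated), `r_squared`, `window` (start and end index into the
#'   usable points), `n_points`, and `n_excluded` (non-positive OD points
#'   dropped).
#' @examples
#' tt <- 0:6
#' fit_growth_rate(data.frame(time_h = tt, od600 = 0.1 * exp(0.5 * tt)))
#' @export
fit_growth_rate <- function(series, min_points = 4, r2_min = 0.98) {
  if (!is.data.frame(series) || !all(c("time_h", "od600") %in% names(series))) {
    stop("'series' must be a data.frame with columns time_h and od600",
         call. = FALSE)
  }
  if (min_points < 2) stop("'min_points' must be at least 2", call. = FALSE)
  t <- as.numeric(series$time_h)
  od <- as.numeric(series$od600)
  keep <- is.finite(od) & od > 0 & is.finite(t)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warning(sprintf("%d point(s) with non-positive or missing OD excluded",
                    n_excluded), call. = FALSE)
  }
  t <- t[keep]
  od <- od[keep]
  if (is.unsorted(t, strictly = TRUE)) {
    stop("'time_h' must be strictly increasing", call. = FALSE)
  }
  n <- length(t)
  if (n < min_points) {
    stop(sprintf("insufficient data: %d usable point(s), need >= %d", n,
                 min_points), call. = FALSE)
  }
  y <- log(od)

  best <- NULL
  for (w in seq(min_points, n)) {
    for (s in seq_len(n - w + 1)) {
      e <- s + w - 1
      ti <- t[s:e]
      yi <- y[s:e]
      tc <- ti - mean(ti)
      sxx <- sum(tc^2)
      slope <- sum(tc * yi) / sxx
      if (slope <= 0) next  # not a growth stretch
      fit <- mean(yi) + slope * tc
      sst <- sum((yi - mean(yi))^2)
      ssr <- sum((yi - fit)^2)
      r2 <- 1 - ssr / sst
      if (r2 < r2_min) next
      sigma <- sqrt(ssr / max(w - 2, 1))
      tstat <- if (sigma < 1e-12) Inf else slope * sqrt(sxx) / sigma
      cand <- list(slope = slope, intercept = mean(yi) - slope * mean(ti),
                   r2 = max(0, min(1, r2)), window = c(s, e), w = w,
                   tstat = tstat)
      if (is.null(best) ||
          cand$tstat > best$tstat ||
          (cand$tstat == best$tstat &&
             (cand$w > best$w || (cand$w == best$w && s < best$window[1])))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf("no exponential phase found: no window of >= %d points has R^2 >= %g",
                 min_points, r2_min), call. = FALSE)
  }
  structure(
    list(alpha = best$slope, intercept = best$intercept,
         r_squared = best$r2, window = best$window,
         n_points = best$w, n_excluded = n_excluded),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: alpha = %.4g h^-1 (R^2 = %.4f, %d points, window %d-%d)\n",
              x$alpha, x$r_squared, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Ratio of two growth rates
#'
#' Fold difference in growth rate between two strains or conditions, with the
#' value rounded to two significant figures alongside (the conventional
#' reporting style, e.g. "1.7 times faster").
#'
#' @param alpha_a,alpha_b Growth rates, h^-1; `alpha_b` is the reference and
#'   must be positive.
#' @return List with `ratio` (exact) and `reported` (two significant figures).
#' @examples
#' growth_rate_ratio(0.7938, 0.4759)  # reported 1.7
#' @export
growth_rate_ratio <- function(alpha_a, alpha_b) {
  if (any(alpha_b <= 0)) stop("'alpha_b' must be positive", call. = FALSE)
  r <- alpha_a / alpha_b
  list(ratio = r, reported = signif(r, 2))
}
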