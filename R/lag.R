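#' Cross-correlation between regulator and target at a given lag
#'
#' For series `a` (regulator) and `b` (target) of common length N on the
#' same time grid, the statistic at integer lag `h` is
#'
#' \deqn{r_{a,b}(h) = \frac{\sum_i (a_{i+h} - \bar a)(b_i - \bar b)}
#'   {\sqrt{\sum_i (a_i-\bar a)^2 \; \sum_i (b_i-\bar b)^2}}}
#'
#' where the numerator runs over the overlap \eqn{0 \le i + h < N} and
#' \eqn{\bar a}, \eqn{\bar b} are the full-series means (used in the
#' denominator over the full series as well, whatever the overlap). The
#' regulator series carries the shift, so a negative `h` lines up earlier
#' regulator values with later target values: a target that responds k
#' sampling intervals after its regulator peaks at `h = -k`.
#'
#' Lags are counted in sampling-index units, not hours: the default grid
#' (3, 4, 5, 6, 8 h) is unevenly spaced and the method works with
#' positions.
#'
#' With full-series means and a partial overlap the ratio can exceed 1 in
#' magnitude by a small amount; this is inherent to the definition and is
#' not clipped.
#'
#' @param a numeric vector, regulator profile (log expression).
#' @param b numeric vector, target profile on the same grid.
#' @param h integer lag, `-(N-1) <= h <= N-1`.
#' @param shift which series carries the index shift. The default
#'   `"regulator"` makes the retained band `h <= 0` mean "target responds
#'   after regulator"; `"target"` flips the sign convention.
#' @param means `"full"` (default) uses full-series means; `"overlap"`
#'   recomputes means on the overlapping windows.
#' @return the correlation value; `NaN` when both series are constant.
#' @export
cross_correlation <- function(a, b, h,
                              shift = c("regulator", "target"),
                              means = c("full", "overlap")) {
  shift <- match.arg(shift)
  means <- match.arg(means)
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("profiles must share the same time grid")
  if (n < 2L) stop("need at least 2 timepoints")
  h <- as.integer(h)
  if (abs(h) > n - 1L) stop("lag out of range: ", h)
  if (shift == "target") return(cross_correlation(b, a, h, means = means))
  i <- seq.int(0L, n - 1L)
  i <- i[i + h >= 0L & i + h <= n - 1L]
  if (means == "full") {
    abar <- mean(a); bbar <- mean(b)
    den <- sqrt(sum((a - abar)^2) * sum((b - bbar)^2))
  } else {
    abar <- mean(a[i + h + 1L]); bbar <- mean(b[i + 1L])
    den <- sqrt(sum((a[i + h + 1L] - abar)^2) * sum((b[i + 1L] - bbar)^2))
  }
  num <- sum((a[i + h + 1L] - abar) * (b[i + 1L] - bbar))
  if (den == 0) return(NaN)
  num / den
}

# fast path: r(h) over several lags with full-series means, no argument
# checking; used by the lag search and the simulator's rejection loop
xcorr_vec <- function(a, b, hs) {
  n <- length(a)
  abar <- mean(a); bbar <- mean(b)
  ac <- a - abar; bc <- b - bbar
  den <- sqrt(sum(ac^2) * sum(bc^2))
  vapply(hs, function(h) {
    i <- seq.int(max(0L, -h), min(n - 1L, n - 1L - h))
    if (den == 0) NaN else sum(ac[i + h + 1L] * bc[i + 1L]) / den
  }, numeric(1))
}

#' Choose the lag maximizing the absolute cross-correlation
#'
#' Evaluates [cross_correlation()] at every candidate lag and selects the
#' lag with the largest `|r|`. Ties on `|r|` go to the smallest `|h|`; a
#' remaining tie between `+h` and `-h` goes to the negative lag (the
#' retained, causally-sensible band). The retention rule of
#' [filter_by_lag()] is applied to the chosen lag.
#'
#' @inheritParams cross_correlation
#' @param candidates integer vector of candidate lags (default `-3:3`;
#'   `|h| = 4` is never considered on the 5-point grid).
#' @return a list of class `lag_result`: `h`, `r`, `retained`, `r_by_lag`
#'   (named vector over the candidates), and `defined` (`FALSE` when the
#'   correlation is undefined because both series are constant).
#' @export
best_lag <- function(a, b, candidates = -3:3,
                     shift = c("regulator", "target"),
                     means = c("full", "overlap")) {
  shift <- match.arg(shift); means <- match.arg(means)
  candidates <- sort(as.integer(candidates))
  if (means == "full") {
    if (shift == "target") { tmp <- a; a <- b; b <- tmp }
    r <- xcorr_vec(as.numeric(a), as.numeric(b), candidates)
  } else {
    r <- vapply(candidates, function(h)
      cross_correlation(a, b, h, shift = shift, means = means), numeric(1))
  }
  names(r) <- candidates
  if (all(is.nan(r))) {
    res <- structure(list(h = NA_integer_, r = NA_real_, retained = FALSE,
                          r_by_lag = r, defined = FALSE),
                     class = "lag_result")
    return(res)
  }
  ok <- which(!is.nan(r))
  # order: |r| desc, then |h| asc, then h asc (negative before positive)
  ord <- ok[order(-abs(r[ok]), abs(candidates[ok]), candidates[ok])]
  best <- ord[1L]
  res <- structure(list(h = candidates[best], r = unname(r[best]),
                        retained = NA, r_by_lag = r, defined = TRUE),
                   class = "lag_result")
  filter_by_lag(res)
}

#' Apply the lag retention rule
#'
#' Pairs whose selected lag lies in `0 < h <= 3` — target apparently
#' preceding its regulator — are discarded; the retained band is
#' `-3 <= h <= 0`, i.e. the target responds zero to three sampling
#' intervals after the regulator.
#'
#' @param result a `lag_result` from [best_lag()], or an integer lag.
#' @return the `lag_result` with `retained` set (or, for an integer input,
#'   a logical).
#' @export
filter_by_lag <- function(result) {
  if (is.numeric(result)) return(result >= -3 & result <= 0)
  result$retained <- isTRUE(result$defined) &&
    !is.na(result$h) && result$h >= -3L && result$h <= 0L
  result
}

#' @export
print.lag_result <- function(x, ...) {
  if (!x$defined) {
    cat("lag_result: undefined (constant profiles)\n")
    return(invisible(x))
  }
  cat(sprintf("lag_result: h = %d, r = %.4f, %s\n", x$h, x$r,
              if (x$retained) "retained" else "discarded"))
  print(round(x$r_by_lag, 4))
  invisible(x)
}

#' Per-pair lag table for a set of regulatory pairs
#'
#' Runs [best_lag()] for every pair against a log-expression matrix.
#' Pairs whose genes are missing from the matrix, or whose correlation is
#' undefined (both profiles constant), are flagged and not retained.
#'
#' @param expr a `log_expr` matrix from [normalize_log()] (rows = genes).
#' @param pairs a `regulatory_pairs` data.frame.
#' @inheritParams best_lag
#' @return data.frame of class `lag_table`: `regulator`, `target`,
#'   `effect`, `h`, `r`, `retained`, `defined`, plus one `r_lag_<h>`
#'   column per candidate lag.
#' @export
lag_table <- function(expr, pairs, candidates = -3:3,
                      shift = c("regulator", "target"),
                      means = c("full", "overlap")) {
  shift <- match.arg(shift); means <- match.arg(means)
  ids <- tolower(rownames(expr))
  candidates <- sort(as.integer(candidates))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ra <- match(pairs$regulator[k], ids)
    rb <- match(pairs$target[k], ids)
    if (is.na(ra) || is.na(rb)) {
      rby <- rep(NA_real_, length(candidates))
      return(c(list(h = NA_integer_, r = NA_real_, retained = FALSE,
                    defined = FALSE), as.list(rby)))
    }
    res <- best_lag(expr[ra, ], expr[rb, ], candidates = candidates,
                    shift = shift, means = means)
    c(res[c("h", "r", "retained", "defined")], as.list(unname(res$r_by_lag)))
  })
  out <- data.frame(regulator = pairs$regulator, target = pairs$target,
                    effect = pairs$effect,
                    h = vapply(rows, function(x) as.integer(x$h), 1L),
                    r = vapply(rows, function(x) as.numeric(x$r), 1.0),
                    retained = vapply(rows, function(x) isTRUE(x$retained),
                                      TRUE),
                    defined = vapply(rows, function(x) isTRUE(x$defined),
                                     TRUE),
                    stringsAsFactors = FALSE)
  rmat <- t(vapply(rows, function(x)
    unlist(x[-(1:4)], use.names = FALSE), numeric(length(candidates))))
  colnames(rmat) <- paste0("r_lag_", candidates)
  out <- cbind(out, rmat)
  class(out) <- c("lag_table", "data.frame")
  out
}

#' Compare plain correlation with best-lag cross-correlation
#'
#' For a set of pairs, summarizes the zero-lag Pearson correlation and the
#' best-lag cross-correlation: overall mean, mean of the negative values
#' and mean of the positive values. Intended to show, on a given data set,
#' how much allowing a lag strengthens the regulator-target association.
#'
#' @param expr a `log_expr` matrix.
#' @param pairs a `regulatory_pairs` data.frame.
#' @inheritParams best_lag
#' @return data.frame with rows `pearson` (h = 0) and `cross_correlation`
#'   (best lag) and columns `overall_mean`, `negative_mean`,
#'   `positive_mean`, `n` (pairs with a defined value). Means over an
#'   empty sign class are `NA`.
#' @export
correlation_summary <- function(expr, pairs, candidates = -3:3,
                                shift = c("regulator", "target"),
                                means = c("full", "overlap")) {
  shift <- match.arg(shift); means <- match.arg(means)
  lt <- lag_table(expr, pairs, candidates = candidates,
                  shift = shift, means = means)
  zero <- lt[[paste0("r_lag_", 0L)]]
  summarize <- function(v) {
    v <- v[!is.na(v) & !is.nan(v)]
    c(overall_mean = if (length(v)) mean(v) else NA_real_,
      negative_mean = if (any(v < 0)) mean(v[v < 0]) else NA_real_,
      positive_mean = if (any(v > 0)) mean(v[v > 0]) else NA_real_,
      n = length(v))
  }
  out <- as.data.frame(rbind(pearson = summarize(zero),
                             cross_correlation = summarize(lt$r)))
  out
}
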