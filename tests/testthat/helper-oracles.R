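# Independent oracle implementations, written as literal direct sums and
# exhaustive scans so they share no code path with the package internals.

# cross-correlation at lag h: explicit loop over the overlap, full-series
# means and denominators
xcorr_oracle <- function(a, b, h) {
  N <- length(a)
  abar <- sum(a) / N
  bbar <- sum(b) / N
  num <- 0
  for (i in 0:(N - 1)) {
    if (i + h >= 0 && i + h <= N - 1)
      num <- num + (a[i + h + 1] - abar) * (b[i + 1] - bbar)
  }
  da <- 0; db <- 0
  for (i in 1:N) {
    da <- da + (a[i] - abar)^2
    db <- db + (b[i] - bbar)^2
  }
  if (da * db == 0) return(NaN)
  num / sqrt(da * db)
}

# brute-force best lag: evaluate the oracle everywhere, order by
# (|r| desc, |h| asc, h asc)
best_lag_oracle <- function(a, b, candidates = -3:3) {
  r <- sapply(candidates, function(h) xcorr_oracle(a, b, h))
  ord <- order(-abs(r), abs(candidates), candidates)
  list(h = candidates[ord[1]], r = r[ord[1]])
}

# brute-force median-of-ratios size factors
size_factor_oracle <- function(m) {
  n <- ncol(m)
  geo <- apply(m, 1, function(x) prod(x)^(1 / n))
  keep <- apply(m, 1, function(x) all(x > 0))
  sapply(seq_len(n), function(j) median(m[keep, j] / geo[keep]))
}

# exhaustive scan of the eligible difference-matrix entries with the
# (smallest |value|, earliest t_a, earliest t_b) preference
select_times_oracle <- function(M) {
  rh <- as.numeric(rownames(M)); ch <- as.numeric(colnames(M))
  cells <- expand.grid(p = seq_along(rh), q = seq_along(ch))
  cells <- cells[ch[cells$q] >= rh[cells$p], ]
  ord <- order(abs(M[as.matrix(cells)]), rh[cells$p], ch[cells$q])
  top <- cells[ord[1], ]
  list(t_a = rh[top$p], t_b = ch[top$q], m_value = M[top$p, top$q])
}

# unit step profile: 0 before the jump after index p, 1 afterwards
step_profile <- function(p, N = 5) as.numeric(seq_len(N) > p)

# shift a profile k positions later in index, extending the first value
shift_profile <- function(a, k) a[pmax(seq_along(a) - k, 1)]
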