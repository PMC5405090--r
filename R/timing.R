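#' Differences of expression between adjacent timepoints
#'
#' For a profile v on the grid (3, 4, 5, 6, 8) the entries are
#' `d_v(i, j) = v(j) - v(i)` over the adjacent pairs (3,4), (4,5), (5,6),
#' (6,8). The difference is the raw change, not a per-hour rate, so the
#' (6,8) entry spans two hours; set `per_hour = TRUE` for a rate variant.
#'
#' @param v numeric profile (one gene's log expression), or a `log_expr`
#'   row.
#' @param hours the time grid; defaults to the `timepoints` attribute of
#'   `v`, else (3,4,5,6,8).
#' @param per_hour divide each difference by the interval length
#'   (default `FALSE`).
#' @return data.frame of class `diff_vector` with columns `from`, `to`,
#'   `d`; one row per adjacent interval, labelled by its start hour.
#' @examples
#' adjacent_differences(c(1, 3, 6, 10, 15))
#' @export
adjacent_differences <- function(v, hours = NULL, per_hour = FALSE) {
  if (is.null(hours)) hours <- attr(v, "timepoints")
  v <- as.numeric(v)
  if (is.null(hours)) hours <- if (length(v) == 5L) c(3, 4, 5, 6, 8)
                               else seq_along(v)
  if (length(hours) != length(v)) stop("hours and profile lengths differ")
  if (length(v) < 2L) stop("need at least 2 timepoints")
  d <- diff(v)
  if (per_hour) d <- d / diff(hours)
  out <- data.frame(from = hours[-length(hours)], to = hours[-1L], d = d)
  class(out) <- c("diff_vector", "data.frame")
  out
}

#' Pairwise-difference matrix between two difference vectors
#'
#' `M[p, q] = da$d[p] - db$d[q]`: the regulator's adjacent-interval
#' differences along the rows, the target's along the columns. On the
#' default grid M is 4 x 4, with rows and columns named by the interval
#' start hours (3, 4, 5, 6).
#'
#' @param da `diff_vector` of the regulator.
#' @param db `diff_vector` of the target, on the same grid.
#' @return numeric matrix.
#' @export
difference_matrix <- function(da, db) {
  if (!identical(da$from, db$from) || !identical(da$to, db$to))
    stop("difference vectors are on different grids")
  M <- outer(da$d, db$d, "-")
  dimnames(M) <- list(regulator = format(da$from, trim = TRUE),
                      target = format(db$from, trim = TRUE))
  M
}

#' Assign activation times from a difference matrix
#'
#' Searches the eligible entries of M — those whose target (column) start
#' hour is at least the regulator (row) start hour, so that the target
#' responds no earlier than its regulator — and picks the entry with the
#' smallest absolute value. The activation times are the start hours of
#' the chosen row (`t_a`, regulator) and column (`t_b`, target). Ties go
#' to the earliest `t_a`, then the earliest `t_b`. On the default grid 10
#' of the 16 entries are eligible and times lie in {3, 4, 5, 6}: a time is
#' the start of the interval in which the change happens, so the last grid
#' hour never appears.
#'
#' With `eligibility = "lag"` the search is further restricted to entries
#' whose column/row index offset equals the magnitude of the pair's chosen
#' lag — a stricter coupling of the two stages, off by default.
#'
#' @param M matrix from [difference_matrix()].
#' @param lag optional `lag_result` (or integer lag) for the pair; required
#'   for `eligibility = "lag"`. When a `lag_result` is supplied it must be
#'   retained.
#' @param eligibility `"time"` (default): column hour >= row hour;
#'   `"lag"`: additionally column index - row index == |h|.
#' @return list of class `activation_assignment`: `t_a`, `t_b`, `m_value`
#'   (signed value of the chosen entry), `eligible_count`.
#' @export
select_activation_times <- function(M, lag = NULL,
                                    eligibility = c("time", "lag")) {
  eligibility <- match.arg(eligibility)
  row_h <- as.numeric(rownames(M))
  col_h <- as.numeric(colnames(M))
  h <- NULL
  if (!is.null(lag)) {
    if (inherits(lag, "lag_result")) {
      if (!isTRUE(lag$retained))
        stop("activation times are only assigned for retained pairs")
      h <- lag$h
    } else h <- as.integer(lag)
  }
  elig <- outer(row_h, col_h, function(r, c) c >= r)
  if (eligibility == "lag") {
    if (is.null(h)) stop("eligibility = \"lag\" needs the pair's lag")
    off <- outer(seq_along(row_h), seq_along(col_h), function(r, c) c - r)
    elig <- elig & off == abs(h)
  }
  if (!any(elig)) stop("no eligible entries in M")
  idx <- which(elig, arr.ind = TRUE)
  vals <- abs(M[idx])
  ord <- order(vals, row_h[idx[, 1L]], col_h[idx[, 2L]])
  pick <- idx[ord[1L], ]
  structure(list(t_a = row_h[pick[1L]], t_b = col_h[pick[2L]],
                 m_value = M[pick[1L], pick[2L]],
                 eligible_count = sum(elig)),
            class = "activation_assignment")
}

#' @export
print.activation_assignment <- function(x, ...) {
  cat(sprintf(
    "activation_assignment: t_a = %g h, t_b = %g h (|M| = %.4g over %d eligible entries)\n",
    x$t_a, x$t_b, abs(x$m_value), x$eligible_count))
  invisible(x)
}

#' Activation-time assignments for all retained pairs
#'
#' For each retained row of a [lag_table()], computes the two
#' adjacent-difference vectors, the difference matrix, and the activation
#' times.
#'
#' @param expr a `log_expr` matrix.
#' @param lags a `lag_table`.
#' @param eligibility passed to [select_activation_times()].
#' @param per_hour passed to [adjacent_differences()].
#' @return data.frame of class `assignment_table`: `regulator`, `target`,
#'   `h`, `r`, `t_a`, `t_b`, `m_value` — one row per retained pair.
#' @export
assign_times <- function(expr, lags, eligibility = c("time", "lag"),
                         per_hour = FALSE) {
  eligibility <- match.arg(eligibility)
  ids <- tolower(rownames(expr))
  hours <- timepoints(expr)
  keep <- which(lags$retained)
  rows <- lapply(keep, function(k) {
    ra <- match(lags$regulator[k], ids)
    rb <- match(lags$target[k], ids)
    da <- adjacent_differences(expr[ra, ], hours, per_hour = per_hour)
    db <- adjacent_differences(expr[rb, ], hours, per_hour = per_hour)
    M <- difference_matrix(da, db)
    sel <- select_activation_times(M, lag = lags$h[k],
                                   eligibility = eligibility)
    data.frame(regulator = lags$regulator[k], target = lags$target[k],
               h = lags$h[k], r = lags$r[k],
               t_a = sel$t_a, t_b = sel$t_b, m_value = sel$m_value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(regulator = character(), target = character(),
                         h = integer(), r = numeric(), t_a = numeric(),
                         t_b = numeric(), m_value = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Frequency table of activation-time combinations
#'
#' Tallies the assignments into a table of counts with the target
#' activation time `t_b` down the rows and the regulator activation time
#' `t_a` across the columns, over the interval start hours of the grid.
#' Cells below the diagonal (`t_b < t_a`) are structurally zero because
#' eligibility enforces `t_b >= t_a`. Row sums, column sums and the grand
#' total are attached.
#'
#' @param assignments an `assignment_table` from [assign_times()].
#' @param hours the interval start hours (default `c(3, 4, 5, 6)`).
#' @return integer matrix of class `activation_table` (rows `t_b`, columns
#'   `t_a`) with a `Sum` row and column.
#' @export
activation_table <- function(assignments, hours = c(3, 4, 5, 6)) {
  lab <- format(hours, trim = TRUE)
  tab <- matrix(0L, length(hours), length(hours),
                dimnames = list(t_b = lab, t_a = lab))
  if (nrow(assignments)) {
    cnt <- table(factor(assignments$t_b, levels = hours),
                 factor(assignments$t_a, levels = hours))
    tab[] <- as.integer(cnt)
  }
  out <- rbind(cbind(tab, Sum = rowSums(tab)),
               Sum = c(colSums(tab), sum(tab)))
  class(out) <- c("activation_table", class(out))
  out
}

#' @export
print.activation_table <- function(x, ...) {
  cat("Frequency of activation times (rows: target t_b, columns: regulator t_a)\n")
  print(unclass(x))
  invisible(x)
}
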