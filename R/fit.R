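#' Fit the sequential-activity model to one biological sample
#'
#' The main entry point: runs the full per-sample analysis on a raw counts
#' table and a regulator-target pair table —
#'
#' 1. restrict the counts to the analysis time grid and drop genes that
#'    are never expressed;
#' 2. estimate median-of-ratios size factors and form
#'    `log2(count / factor + pseudocount)` profiles;
#' 3. filter the pair table (expressed genes, optional single-transcript
#'    annotation, lone self-loops);
#' 4. for each pair, choose the lag maximizing the absolute
#'    cross-correlation and discard pairs whose target would precede its
#'    regulator (`0 < h <= 3`);
#' 5. assign activation times `(t_a, t_b)` through the
#'    pairwise-difference matrix of adjacent-timepoint changes;
#' 6. tabulate the `(t_a, t_b)` frequencies and assemble the timed
#'    directed network.
#'
#' Biological samples are analysed separately; use [run_pipeline()] to
#' drive several samples at once.
#'
#' @param counts a [count_matrix()] (or a path readable by
#'   [read_counts()]).
#' @param pairs a `regulatory_pairs` data.frame (or a path readable by
#'   [read_pairs()]).
#' @param grid analysis hours (default `c(3, 4, 5, 6, 8)`); must be
#'   columns of `counts`.
#' @param annotation optional annotation data.frame (see
#'   [read_annotation()]): only genes with one transcript configuration
#'   are analysed.
#' @param pseudocount offset for the log transform (default 1).
#' @param candidates candidate lags (default `-3:3`).
#' @param shift,means conventions for [cross_correlation()].
#' @param eligibility,per_hour options for [assign_times()].
#' @return an object of class `seqreg`: list with `counts`, `expr`,
#'   `size_factors`, `pairs`, `lags` ([lag_table()]), `assignments`
#'   ([assign_times()]), `freq_table` ([activation_table()]), `network`
#'   ([build_network()]), `stages` (named pair counts through the filter
#'   chain) and `call`.
#' @examples
#' sim <- simulate_dataset(simulation_spec(n_regulators = 4, seed = 42))
#' fit <- seqreg(sim$counts, sim$pairs)
#' fit
#' summary(fit)
#' @export
seqreg <- function(counts, pairs, grid = c(3, 4, 5, 6, 8),
                   annotation = NULL, pseudocount = 1, candidates = -3:3,
                   shift = c("regulator", "target"),
                   means = c("full", "overlap"),
                   eligibility = c("time", "lag"), per_hour = FALSE) {
  shift <- match.arg(shift); means <- match.arg(means)
  eligibility <- match.arg(eligibility)
  cl <- match.call()
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  stages <- c(input_pairs = nrow(pairs))
  counts <- select_timepoints(counts, grid)
  counts <- filter_unexpressed(counts)
  sf <- estimate_size_factors(counts)
  expr <- normalize_log(counts, sf, pseudocount = pseudocount)
  pairs <- filter_pairs(pairs, expressed = rownames(counts),
                        annotation = annotation)
  stages <- c(stages, filtered_pairs = nrow(pairs))
  lags <- lag_table(expr, pairs, candidates = candidates,
                    shift = shift, means = means)
  stages <- c(stages, retained_pairs = sum(lags$retained))
  assignments <- assign_times(expr, lags, eligibility = eligibility,
                              per_hour = per_hour)
  stages <- c(stages, assigned_pairs = nrow(assignments))
  hours <- grid[-length(grid)]
  freq <- activation_table(assignments, hours = hours)
  network <- build_network(assignments, sample_id = sample_id(counts))
  structure(list(counts = counts, expr = expr, size_factors = sf,
                 pairs = pairs, lags = lags, assignments = assignments,
                 freq_table = freq, network = network, stages = stages,
                 grid = grid, call = cl),
            class = "seqreg")
}

#' @export
print.seqreg <- function(x, ...) {
  cat("Sequential transcriptional activity fit\n")
  cat(sprintf("  sample: '%s', %d genes on grid %s h\n",
              sample_id(x$counts), nrow(x$counts),
              paste(x$grid, collapse = ", ")))
  cat(sprintf("  pairs: %d in, %d analysable, %d retained (lag band -3..0), %d time-assigned\n",
              x$stages["input_pairs"], x$stages["filtered_pairs"],
              x$stages["retained_pairs"], x$stages["assigned_pairs"]))
  cat(sprintf("  network: %d vertices, %d edges\n",
              nrow(x$network$vertices), nrow(x$network$edges)))
  invisible(x)
}

#' @export
summary.seqreg <- function(object, ...) {
  lt <- object$lags
  out <- list(sample_id = sample_id(object$counts),
              stages = object$stages,
              lag_distribution = table(factor(lt$h[lt$retained],
                                              levels = -3:0)),
              freq_table = object$freq_table,
              correlation = correlation_summary(object$expr, object$pairs),
              network_size = c(vertices = nrow(object$network$vertices),
                               edges = nrow(object$network$edges)))
  class(out) <- "summary.seqreg"
  out
}

#' @export
print.summary.seqreg <- function(x, ...) {
  cat(sprintf("Sequential activity summary, sample '%s'\n", x$sample_id))
  cat("Pairs through the filter chain:\n")
  print(x$stages)
  cat("Retained lag distribution (h):\n")
  print(x$lag_distribution)
  print(x$freq_table)
  cat("Association strength (mean r):\n")
  print(round(x$correlation, 4))
  cat(sprintf("Network: %d vertices, %d edges\n",
              x$network_size["vertices"], x$network_size["edges"]))
  invisible(x)
}

#' @describeIn seqreg plot the fitted timed network as per-hour snapshots.
#' @param x a `seqreg` fit.
#' @param ... passed on to [plot.timed_network()].
#' @export
plot.seqreg <- function(x, ...) plot(x$network, hours = x$grid, ...)
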