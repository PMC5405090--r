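#' Pipeline configuration
#'
#' Collects the tunables of [run_pipeline()] and validates them: the
#' retained lag band must lie within the candidate lags and the grid must
#' have at least three points.
#'
#' @param samples named list: per biological sample, either a path to a
#'   counts file or a [count_matrix()].
#' @param pairs path to a pair table or a `regulatory_pairs` data.frame.
#' @param out_dir output directory (created if absent); `NULL` disables
#'   file output.
#' @param grid analysis hours.
#' @param candidates candidate lags.
#' @param annotation optional annotation table or path.
#' @param pseudocount,shift,means,eligibility,per_hour passed to
#'   [seqreg()].
#' @param seed integer seed set once before the run (the analysis itself
#'   is deterministic; the seed pins any randomized consumer code).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, pairs, out_dir = NULL,
                            grid = c(3, 4, 5, 6, 8), candidates = -3:3,
                            annotation = NULL, pseudocount = 1,
                            shift = "regulator", means = "full",
                            eligibility = "time", per_hour = FALSE,
                            seed = 1L) {
  if (!is.list(samples) || is.null(names(samples)) ||
      any(!nzchar(names(samples))))
    stop("`samples` must be a named list")
  grid <- sort(as.numeric(grid))
  if (length(grid) < 3L) stop("grid must have at least 3 points")
  candidates <- sort(as.integer(candidates))
  band <- candidates[candidates >= -3L & candidates <= 0L]
  if (!all(-(min(3L, length(grid) - 2L)):0L %in% candidates) &&
      length(band) == 0L)
    stop("retained lag band must lie within the candidate lags")
  if (!all(band %in% candidates))
    stop("retained lag band must lie within the candidate lags")
  structure(list(samples = samples, pairs = pairs, out_dir = out_dir,
                 grid = grid, candidates = candidates,
                 annotation = annotation, pseudocount = pseudocount,
                 shift = shift, means = means, eligibility = eligibility,
                 per_hour = per_hour, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline over several biological samples
#'
#' Each sample is analysed independently with [seqreg()] (samples are
#' never pooled). Per sample the run writes, under
#' `out_dir/<sample>/`: the normalized matrix, the per-pair lag table,
#' the assignments table, the activation-time frequency table, and the
#' timed network in GraphML and JSON. A machine-readable run log
#' (`run_log.json`) records the pair counts at every filter stage. An
#' error in one sample is logged and halts that sample only.
#'
#' As a labelled extra beyond the per-sample method, the log also reports
#' the edge sets shared by all successfully analysed samples
#' (`consensus_edges`), for convenience when comparing samples.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress console progress messages.
#' @return invisibly, a list with `fits` (named list of `seqreg` objects
#'   or `NULL` for failed samples) and `log` (the run log as a list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  pairs <- config$pairs
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  annotation <- config$annotation
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (nrow(pairs) == 0L)
    warning("empty pair table: all outputs will be empty")
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fits <- stats::setNames(vector("list", length(config$samples)),
                          names(config$samples))
  log <- list(seed = config$seed, grid = config$grid,
              candidates = config$candidates, samples = list())
  for (sname in names(config$samples)) {
    say("sample %s: analysing", sname)
    entry <- list(sample = sname, status = "ok")
    fit <- tryCatch({
      cm <- config$samples[[sname]]
      if (is.character(cm)) cm <- read_counts(cm, sample_id = sname)
      seqreg(cm, pairs, grid = config$grid, annotation = annotation,
             pseudocount = config$pseudocount,
             candidates = config$candidates, shift = config$shift,
             means = config$means, eligibility = config$eligibility,
             per_hour = config$per_hour)
    }, error = function(e) {
      say("sample %s: FAILED at analysis stage: %s", sname,
          conditionMessage(e))
      entry$status <<- "error"
      entry$message <<- conditionMessage(e)
      NULL
    })
    if (!is.null(fit)) {
      entry$stages <- as.list(fit$stages)
      entry$network <- list(vertices = nrow(fit$network$vertices),
                            edges = nrow(fit$network$edges))
      if (nrow(fit$pairs) == 0L) entry$warning <- "no analysable pairs"
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, sname)
        if (!dir.exists(sdir)) dir.create(sdir)
        write_normalized(fit$expr, file.path(sdir, "normalized.tsv"))
        utils::write.table(fit$lags, file.path(sdir, "lag_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(fit$assignments,
                           file.path(sdir, "assignments.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(unclass(fit$freq_table),
                           file.path(sdir, "activation_table.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA)
        export_network(fit$network, file.path(sdir, "network.graphml"),
                       "graphml")
        export_network(fit$network, file.path(sdir, "network.json"),
                       "json")
      }
    }
    fits[[sname]] <- fit
    log$samples[[sname]] <- entry
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (sum(ok) >= 2L) {
    keys <- lapply(fits[ok], function(f)
      paste(f$network$edges$source, f$network$edges$destination, sep = "->"))
    log$consensus_edges <- Reduce(intersect, keys)
  }
  if (!is.null(out_dir))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fits = fits, log = log))
}
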