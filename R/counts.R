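#' Construct a count matrix for one biological sample
#'
#' A `count_matrix` is the container for raw RNA-seq counts of one
#' biological sample: an integer matrix with genes in rows and sampling
#' times (hours) in columns.
#'
#' @param counts numeric matrix of non-negative integers, genes x timepoints.
#'   Row names are gene identifiers and must be unique.
#' @param timepoints numeric vector of sampling times in hours, strictly
#'   increasing, one per column. Defaults to the column names of `counts`.
#' @param sample_id label for the biological sample.
#' @return an object of class `count_matrix`: the integer matrix with
#'   attributes `timepoints` and `sample_id`.
#' @examples
#' m <- matrix(rpois(15, 50), nrow = 3,
#'             dimnames = list(c("gA", "gB", "gC"), c(3, 4, 5, 6, 8)))
#' cm <- count_matrix(m, sample_id = "s1")
#' timepoints(cm)
#' @export
count_matrix <- function(counts, timepoints = NULL, sample_id = "sample") {
  counts <- as.matrix(counts)
  if (is.null(timepoints)) {
    if (is.null(colnames(counts)))
      stop("`timepoints` must be given when `counts` has no column names")
    timepoints <- suppressWarnings(as.numeric(colnames(counts)))
    if (anyNA(timepoints))
      stop("column names of `counts` are not parseable as hours: ",
           paste(colnames(counts)[is.na(timepoints)], collapse = ", "))
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(counts))
    stop("length(timepoints) != ncol(counts)")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (is.null(rownames(counts)))
    stop("`counts` must have gene identifiers as row names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  colnames(counts) <- format(timepoints, trim = TRUE)
  structure(counts,
            timepoints = timepoints,
            sample_id = as.character(sample_id)[1],
            class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d timepoints (hours %s), sample '%s'\n",
              nrow(x), ncol(x),
              paste(timepoints(x), collapse = ", "), sample_id(x)))
  n <- min(nrow(x), 6L)
  print(unclass(x)[seq_len(n), , drop = FALSE])
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more genes)\n", sep = "")
  invisible(x)
}

#' Sampling times of a count or expression matrix
#' @param x a `count_matrix` or `log_expr` object.
#' @return numeric vector of hours.
#' @export
timepoints <- function(x) attr(x, "timepoints")

#' Sample label of a count or expression matrix
#' @param x a `count_matrix` or `log_expr` object.
#' @return character scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Read a counts table from a delimited file
#'
#' The expected layout is one header line (first field `gene_id`, remaining
#' fields sampling times in hours) followed by one row per gene. The field
#' separator (tab or comma) is sniffed from the header unless given.
#' Columns are reordered so hours increase left to right. Lines starting
#' with `#` are skipped.
#'
#' @param path path to the file.
#' @param sample_id label for the biological sample.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, sample_id = "sample", sep = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 1L) stop("empty counts file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header (need gene_id plus >= 1 time column): ", lines[1])
  hours <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(hours))
    stop("malformed header: columns not parseable as hours: ",
         paste(header[-1][is.na(hours)], collapse = ", "))
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1] + 1L,
         " has ", nf[nf != length(header)][1], " fields, expected ",
         length(header))
  ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(hours))))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(hours))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric count for gene '", ids[bad[1]],
         "', hour ", hours[bad[2]])
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(vals) <- ids
  ord <- order(hours)
  count_matrix(vals[, ord, drop = FALSE], hours[ord], sample_id)
}

#' Write a counts table to a delimited file
#'
#' Writes the layout [read_counts()] expects, so the two functions
#' round-trip.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  colnames(df)[-1] <- format(timepoints(x), trim = TRUE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes that are never expressed
#'
#' Removes exactly the genes whose count is zero at every retained
#' timepoint; every other gene is kept. Idempotent.
#'
#' @param x a [count_matrix()].
#' @return a [count_matrix()] restricted to expressed genes (possibly with
#'   zero rows).
#' @export
filter_unexpressed <- function(x) {
  keep <- rowSums(unclass(x)) > 0L
  count_matrix(unclass(x)[keep, , drop = FALSE], timepoints(x), sample_id(x))
}

#' Restrict a count matrix to an analysis time grid
#'
#' @param x a [count_matrix()].
#' @param grid numeric vector of hours to keep; each must be a column of
#'   `x`. The default is the five-point grid the method was developed on.
#' @return a [count_matrix()] whose columns are `grid`, ascending.
#' @export
select_timepoints <- function(x, grid = c(3, 4, 5, 6, 8)) {
  grid <- sort(as.numeric(grid))
  idx <- match(grid, timepoints(x))
  if (anyNA(idx))
    stop("requested hours missing from counts; missing: ",
         paste(grid[is.na(idx)], collapse = ", "))
  count_matrix(unclass(x)[, idx, drop = FALSE], grid, sample_id(x))
}

#' Median-of-ratios size factors
#'
#' Per-column normalization constants for sequencing depth: for column j,
#' the median over genes of `count[g, j] / geomean_g`, where `geomean_g` is
#' the geometric mean of gene g across the columns. Genes with a zero count
#' in any column (geometric mean zero) are excluded from the median but are
#' not removed from the data. Each biological sample's time course is
#' normalized on its own; a "column" here is one timepoint of one sample.
#'
#' @param x a [count_matrix()] (or plain non-negative matrix).
#' @return numeric vector of positive factors, one per column, named by
#'   column.
#' @export
estimate_size_factors <- function(x) {
  m <- unclass(as.matrix(x))
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) stop("no reference genes for size factors")
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(exp(logm - loggeo), 2L, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("non-positive size factor estimated")
  sf
}

#' Normalize counts and log transform
#'
#' Divides each column by its size factor and applies
#' `log2(count / factor + pseudocount)`. The log2 base with a pseudocount
#' of 1 is the transcriptomics convention; both are configurable.
#'
#' @param x a [count_matrix()].
#' @param factors per-column size factors, typically from
#'   [estimate_size_factors()]; all must be positive.
#' @param pseudocount non-negative offset added before the log (default 1).
#' @return a `log_expr` object: numeric matrix of log2 expression with the
#'   same dimnames as `x` and attributes `timepoints`, `sample_id`,
#'   `size_factors` and `pseudocount`. Each row is one gene's time-series
#'   profile.
#' @export
normalize_log <- function(x, factors = estimate_size_factors(x),
                          pseudocount = 1) {
  if (length(factors) != ncol(x))
    stop("need one size factor per column")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  vals <- log2(sweep(unclass(x), 2L, factors, "/") + pseudocount)
  structure(vals,
            timepoints = timepoints(x),
            sample_id = sample_id(x),
            size_factors = factors,
            pseudocount = pseudocount,
            class = c("log_expr", "matrix", "array"))
}

#' @export
print.log_expr <- function(x, ...) {
  cat(sprintf(
    "log_expr: %d genes x %d timepoints (hours %s), sample '%s', log2(count/sf + %g)\n",
    nrow(x), ncol(x), paste(timepoints(x), collapse = ", "),
    sample_id(x), attr(x, "pseudocount")))
  n <- min(nrow(x), 6L)
  print(round(unclass(x)[seq_len(n), , drop = FALSE], 3))
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more genes)\n", sep = "")
  invisible(x)
}

#' Write a normalized log-expression matrix
#'
#' Same delimited layout as [write_counts()], preceded by a
#' `#normalized log2` comment line.
#'
#' @param x a `log_expr` matrix from [normalize_log()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_normalized <- function(x, path, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#normalized log2", con)
  header <- paste(c("gene_id", format(timepoints(x), trim = TRUE)),
                  collapse = sep)
  writeLines(header, con)
  body <- apply(unclass(x), 1L, function(v)
    paste(format(v, trim = TRUE, digits = 15), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}
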