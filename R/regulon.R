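#' Read a regulator-target pair table
#'
#' Parses a network file in the style distributed by curated regulation
#' databases for E. coli: tab-delimited, `#` comment lines, regulator name
#' in the first column, target gene in the second, and optionally an effect
#' sign (`+`, `-`, `+-` or `?`) in the third. Duplicated
#' (regulator, target) rows are collapsed, keeping the first effect seen.
#' Matching elsewhere in the package is case-folded, so names are
#' lower-cased here.
#'
#' @param path path to the file.
#' @param sep field separator (default tab).
#' @return a data.frame of class `regulatory_pairs` with columns
#'   `regulator`, `target`, `effect` (one of `"+"`, `"-"`, `"+-"`,
#'   `"unknown"`).
#' @export
read_pairs <- function(path, sep = "\t") {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(regulatory_pairs(character(), character()))
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("line ", lineno[nf < 2L][1], ": fewer than 2 fields")
  reg <- trimws(vapply(fields, `[[`, "", 1L))
  tgt <- trimws(vapply(fields, `[[`, "", 2L))
  eff <- vapply(fields, function(f)
    if (length(f) >= 3L) trimws(f[[3L]]) else "", "")
  regulatory_pairs(reg, tgt, eff)
}

#' Construct a regulatory pair table
#'
#' @param regulator,target character vectors of gene names (non-empty,
#'   case-folded to lower case).
#' @param effect optional effect signs; anything other than `+`, `-`,
#'   `+-`/`-+`/`±` becomes `"unknown"`.
#' @return a `regulatory_pairs` data.frame, de-duplicated on
#'   (regulator, target).
#' @export
regulatory_pairs <- function(regulator, target,
                             effect = rep("", length(regulator))) {
  regulator <- tolower(as.character(regulator))
  target <- tolower(as.character(target))
  if (any(!nzchar(regulator)) || any(!nzchar(target)))
    stop("regulator and target names must be non-empty")
  effect <- as.character(effect)
  effect[is.na(effect)] <- ""
  effect <- ifelse(effect %in% c("+", "-"), effect,
                   ifelse(effect %in% c("+-", "-+", "±"), "+-",
                          "unknown"))
  df <- data.frame(regulator = regulator, target = target, effect = effect,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("regulator", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("regulatory_pairs", "data.frame")
  df
}

#' Write a regulatory pair table
#' @param pairs a `regulatory_pairs` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# regulator\ttarget\teffect", con)
  writeLines(paste(pairs$regulator, pairs$target, pairs$effect, sep = "\t"),
             con)
  invisible(path)
}

#' Read a gene annotation table (transcript configurations)
#'
#' Two-column delimited file: `gene_id` and the number of transcript
#' configurations of that gene (a positive integer). Used to restrict the
#' analysis to genes with a single transcript configuration.
#'
#' @param path path to the file.
#' @param sep field separator (default tab).
#' @return data.frame with columns `gene_id` (lower-cased) and
#'   `transcript_configurations`.
#' @export
read_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation needs gene_id and a count column")
  out <- data.frame(gene_id = tolower(as.character(df[[1]])),
                    transcript_configurations = as.integer(df[[2]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$transcript_configurations)) ||
      any(out$transcript_configurations < 1L))
    stop("transcript_configurations must be positive integers")
  out
}

#' Filter regulatory pairs for analysis
#'
#' Keeps the pairs the timing analysis can and should use:
#' * both regulator and target must be among the expressed genes
#'   (profiles are needed for both);
#' * when an annotation is supplied, both genes must have exactly one
#'   transcript configuration (applied to regulator and target alike);
#' * a self-loop `g -> g` is dropped when `g` has no other regulator in
#'   the table; a self-regulating gene that is also regulated by someone
#'   else keeps its loop.
#'
#' The operation is idempotent and never adds pairs.
#'
#' @param pairs a `regulatory_pairs` data.frame.
#' @param expressed character vector of expressed gene ids (case-folded
#'   internally).
#' @param annotation optional annotation data.frame from
#'   [read_annotation()]; genes absent from it are treated as
#'   single-configuration.
#' @return the filtered `regulatory_pairs` data.frame.
#' @export
filter_pairs <- function(pairs, expressed, annotation = NULL) {
  expressed <- tolower(as.character(expressed))
  keep <- pairs$regulator %in% expressed & pairs$target %in% expressed
  if (!is.null(annotation)) {
    multi <- annotation$gene_id[annotation$transcript_configurations > 1L]
    keep <- keep & !(pairs$regulator %in% multi) & !(pairs$target %in% multi)
  }
  out <- pairs[keep, , drop = FALSE]
  is_loop <- out$regulator == out$target
  if (any(is_loop)) {
    other_reg <- vapply(which(is_loop), function(i) {
      g <- out$target[i]
      any(out$target == g & out$regulator != g)
    }, logical(1))
    drop <- which(is_loop)[!other_reg]
    if (length(drop)) out <- out[-drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
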