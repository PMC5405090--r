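#' Build a timed regulatory network from activation assignments
#'
#' Each assignment becomes one directed edge from regulator to target,
#' carrying its activation window `[t_a, t_b]`; self-loops are allowed.
#' Each gene becomes one vertex carrying its role (`regulator`, `target`
#' or `both`) and the set of hours at which it activates — `t_a` over the
#' edges where it acts as regulator, `t_b` where it is the target. Every
#' vertex arrives with an edge, so the network has no isolated vertices
#' by construction: a timing statement needs both ends of a pair.
#'
#' @param assignments an `assignment_table` from [assign_times()].
#' @param sample_id label carried on the network.
#' @return object of class `timed_network`: list with `vertices`
#'   (data.frame `gene_id`, `role`, `activation_times` list-column),
#'   `edges` (data.frame `source`, `destination`, `t_a`, `t_b`) and
#'   `sample_id`.
#' @export
build_network <- function(assignments, sample_id = "sample") {
  edges <- data.frame(source = as.character(assignments$regulator),
                      destination = as.character(assignments$target),
                      t_a = as.numeric(assignments$t_a),
                      t_b = as.numeric(assignments$t_b),
                      stringsAsFactors = FALSE)
  if (any(edges$t_b < edges$t_a))
    stop("edge with t_b < t_a; assignments are inconsistent")
  ids <- sort(unique(c(edges$source, edges$destination)))
  role <- vapply(ids, function(g) {
    is_reg <- g %in% edges$source
    is_tgt <- g %in% edges$destination
    if (is_reg && is_tgt) "both" else if (is_reg) "regulator" else "target"
  }, "")
  act <- lapply(ids, function(g)
    sort(unique(c(edges$t_a[edges$source == g],
                  edges$t_b[edges$destination == g]))))
  vertices <- data.frame(gene_id = ids, role = unname(role),
                         stringsAsFactors = FALSE)
  vertices$activation_times <- act
  structure(list(vertices = vertices, edges = edges,
                 sample_id = as.character(sample_id)[1]),
            class = "timed_network")
}

#' @export
print.timed_network <- function(x, ...) {
  cat(sprintf("timed_network '%s': %d vertices, %d edges (%d self-loops)\n",
              x$sample_id, nrow(x$vertices), nrow(x$edges),
              sum(x$edges$source == x$edges$destination)))
  invisible(x)
}

#' Convert a timed network to an igraph graph
#'
#' Vertex attributes: `role` and `activation_times` (comma-separated
#' string, GraphML-safe). Edge attributes: `t_a`, `t_b`.
#'
#' @param network a `timed_network`.
#' @return a directed [igraph::igraph] graph.
#' @export
as_igraph <- function(network) {
  v <- network$vertices
  vdf <- data.frame(name = v$gene_id, role = v$role,
                    activation_times = vapply(v$activation_times,
                                              paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = vdf)
  igraph::graph_attr(g, "sample_id") <- network$sample_id
  g
}

#' Activity snapshot of a timed network at one grid hour
#'
#' A vertex is active at `hour` when `hour` is one of its activation
#' times; an edge is active when `t_a <= hour <= t_b` (the window is
#' closed at both ends). Inactive vertices and edges are kept, flagged
#' inactive — whether to hide or grey them is a rendering decision.
#'
#' @param network a `timed_network`.
#' @param hour one hour of the grid.
#' @param grid the valid hours (default `c(3, 4, 5, 6, 8)`).
#' @return list of class `network_snapshot`: `hour`, `vertices` and
#'   `edges` data.frames each with a logical `active` column.
#' @export
snapshot <- function(network, hour, grid = c(3, 4, 5, 6, 8)) {
  if (!hour %in% grid)
    stop("hour ", hour, " is not on the grid (", paste(grid, collapse = ", "), ")")
  v <- network$vertices
  v$active <- vapply(v$activation_times, function(t) hour %in% t, TRUE)
  e <- network$edges
  e$active <- e$t_a <= hour & hour <= e$t_b
  structure(list(hour = hour, vertices = v, edges = e),
            class = "network_snapshot")
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat(sprintf("snapshot at %g h: %d/%d vertices active, %d/%d edges active\n",
              x$hour, sum(x$vertices$active), nrow(x$vertices),
              sum(x$edges$active), nrow(x$edges)))
  invisible(x)
}

#' Export a timed network to GraphML or JSON
#'
#' GraphML carries `t_a` and `t_b` as edge attributes and the activation
#' times as a comma-separated vertex attribute; JSON uses a plain temporal
#' schema (`sample_id`, `vertices` with `gene_id` / `role` /
#' `activation_times`, `edges` with `source` / `destination` / `t_a` /
#' `t_b`). Both formats round-trip through [read_network()].
#'
#' @param network a `timed_network`.
#' @param path output path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    if (nrow(network$vertices) == 0L) {
      # igraph cannot write attribute-less empty graphs helpfully; emit a
      # minimal valid GraphML document instead
      writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
                   '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
                   sprintf('<graph id="%s" edgedefault="directed"/>',
                           network$sample_id),
                   '</graphml>'), path)
    } else {
      igraph::write_graph(as_igraph(network), path, format = "graphml")
    }
  } else {
    v <- network$vertices
    obj <- list(sample_id = network$sample_id,
                vertices = data.frame(gene_id = v$gene_id, role = v$role,
                                      stringsAsFactors = FALSE),
                edges = network$edges)
    obj$vertices$activation_times <- v$activation_times
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a timed network written by [export_network()]
#'
#' @param path path to a `.graphml` or `.json` file.
#' @param format `"graphml"` or `"json"`; default guesses from the file
#'   extension.
#' @return a `timed_network`.
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else "json"
  format <- match.arg(format, c("graphml", "json"))
  if (format == "graphml") {
    doc <- readLines(path, n = 5L)
    g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                  error = function(e) NULL)
    if (is.null(g) || igraph::vcount(g) == 0L) {
      sid <- sub('.*<graph id="([^"]*)".*', "\\1",
                 paste(readLines(path), collapse = ""))
      return(empty_network(if (nzchar(sid)) sid else "sample"))
    }
    v <- igraph::as_data_frame(g, what = "vertices")
    e <- igraph::as_data_frame(g, what = "edges")
    net <- structure(list(
      vertices = data.frame(gene_id = v$name, role = v$role,
                            stringsAsFactors = FALSE),
      edges = data.frame(source = e$from, destination = e$to,
                         t_a = as.numeric(e$t_a), t_b = as.numeric(e$t_b),
                         stringsAsFactors = FALSE),
      sample_id = igraph::graph_attr(g, "sample_id")), class = "timed_network")
    net$vertices$activation_times <- lapply(strsplit(v$activation_times, ","),
                                            as.numeric)
    ord <- order(net$vertices$gene_id)
    net$vertices <- net$vertices[ord, , drop = FALSE]
    rownames(net$vertices) <- NULL
    net
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(obj$vertices) == 0L)
      return(empty_network(obj$sample_id))
    v <- data.frame(
      gene_id = vapply(obj$vertices, function(x) x$gene_id, ""),
      role = vapply(obj$vertices, function(x) x$role, ""),
      stringsAsFactors = FALSE)
    v$activation_times <- lapply(obj$vertices, function(x)
      as.numeric(unlist(x$activation_times)))
    e <- data.frame(
      source = vapply(obj$edges, function(x) x$source, ""),
      destination = vapply(obj$edges, function(x) x$destination, ""),
      t_a = vapply(obj$edges, function(x) as.numeric(x$t_a), 1.0),
      t_b = vapply(obj$edges, function(x) as.numeric(x$t_b), 1.0),
      stringsAsFactors = FALSE)
    structure(list(vertices = v, edges = e,
                   sample_id = obj$sample_id), class = "timed_network")
  }
}

empty_network <- function(sample_id = "sample") {
  v <- data.frame(gene_id = character(), role = character(),
                  stringsAsFactors = FALSE)
  v$activation_times <- list()
  structure(list(vertices = v,
                 edges = data.frame(source = character(),
                                    destination = character(),
                                    t_a = numeric(), t_b = numeric(),
                                    stringsAsFactors = FALSE),
                 sample_id = sample_id),
            class = "timed_network")
}

#' Plot per-hour snapshots of a timed network
#'
#' Draws the directed graph once per grid hour, colouring active vertices
#' green and active edges dark; a static stand-in for an animated view.
#'
#' @param x a `timed_network`.
#' @param hours grid hours to draw (default `c(3, 4, 5, 6, 8)`).
#' @param ... passed to [igraph::plot.igraph()].
#' @return invisibly, the layout matrix used.
#' @export
plot.timed_network <- function(x, hours = c(3, 4, 5, 6, 8), ...) {
  if (nrow(x$vertices) == 0L) {
    graphics::plot.new()
    graphics::title(main = sprintf("%s (empty network)", x$sample_id))
    return(invisible(NULL))
  }
  g <- as_igraph(x)
  lay <- igraph::layout_with_fr(g)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(hours)),
                       mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(old))
  for (hr in hours) {
    sn <- snapshot(x, hr, grid = hours)
    vcol <- ifelse(sn$vertices$active, "palegreen3", "grey85")
    ecol <- ifelse(sn$edges$active, "grey20", "grey80")
    igraph::plot.igraph(g, layout = lay, vertex.color = vcol,
                        edge.color = ecol, vertex.label.cex = 0.7,
                        edge.arrow.size = 0.3,
                        main = sprintf("%s, %g h", x$sample_id, hr), ...)
  }
  invisible(lay)
}
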