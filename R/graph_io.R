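# Graph representation and I/O.
#
# Graphs are plain igraph objects: undirected, simple (no loops, no
# multi-edges), with an optional positive `weight` edge attribute and a
# `name` vertex attribute carrying opaque node identifiers.

#' Validate a graph for the robustness engine
#'
#' Checks that `graph` is an undirected simple igraph object with at least
#' 2 nodes and 1 edge, and that the `weight` edge attribute, if present, is
#' strictly positive and finite.
#'
#' @param graph An igraph object.
#' @param arg Name used in error messages.
#' @return `graph`, invisibly, with vertex names added (`"1".."n"`) if the
#'   input had none.
#' @export
check_graph <- function(graph, arg = "graph") {
  if (!igraph::is_igraph(graph)) {
    stop(sprintf("`%s` must be an igraph object", arg), call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  }
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    stop(sprintf("`%s` must be simple (no self-loops or duplicate edges)", arg),
         call. = FALSE)
  }
  if (igraph::vcount(graph) < 2L) {
    stop(sprintf("`%s` must have at least 2 nodes", arg), call. = FALSE)
  }
  if (igraph::ecount(graph) < 1L) {
    stop(sprintf("`%s` must have at least 1 edge", arg), call. = FALSE)
  }
  w <- igraph::edge_attr(graph, "weight")
  if (!is.null(w) && (anyNA(w) || any(!is.finite(w)) || any(w <= 0))) {
    stop(sprintf("`%s` has non-positive or non-finite edge weights", arg),
         call. = FALSE)
  }
  if (is.null(igraph::vertex_attr(graph, "name"))) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  invisible(graph)
}

graph_is_weighted <- function(graph) {
  !is.null(igraph::edge_attr(graph, "weight"))
}

#' Read a graph from a standard plain-text format
#'
#' @param path Path to an existing file.
#' @param format One of `"edgelist"` (whitespace-delimited `u v [weight]`
#'   with `#` comments), `"graphml"`, or `"mtx"` (MatrixMarket coordinate,
#'   square symmetric, interpreted as a weighted adjacency matrix). Guessed
#'   from the file extension when missing.
#' @return An undirected simple igraph object. Symmetric duplicate entries
#'   are collapsed (first weight wins), diagonal/self-loop entries dropped,
#'   explicit zeros absent. MTX input that is not symmetric is rejected.
#' @export
read_graph <- function(path, format = c("edgelist", "graphml", "mtx")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) format <- guess_graph_format(path)
  format <- match.arg(format)
  g <- switch(format,
    edgelist = read_edgelist_file(path),
    graphml  = read_graphml_file(path),
    mtx      = read_mtx_file(path)
  )
  check_graph(g, arg = path)
  g
}

guess_graph_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
    graphml = "graphml",
    xml     = "graphml",
    mtx     = "mtx",
    "edgelist")
}

read_edgelist_file <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      colClasses = "character", fill = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed edge list '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(df) < 2L || ncol(df) > 3L) {
    stop("edge list '", path, "' must have 2 or 3 columns, found ", ncol(df),
         call. = FALSE)
  }
  weighted <- ncol(df) == 3L
  if (weighted) {
    w <- suppressWarnings(as.numeric(df[[3L]]))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1L]
      stop("edge list '", path, "': non-numeric weight in entry ", bad,
           call. = FALSE)
    }
    df[[3L]] <- w
    names(df) <- c("from", "to", "weight")
  } else {
    names(df) <- c("from", "to")
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  simplify_keep_first(g)
}

read_graphml_file <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) stop("malformed GraphML '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  g <- igraph::as_undirected(g, mode = "collapse",
                             edge.attr.comb = list(weight = "first", "ignore"))
  simplify_keep_first(g)
}

read_mtx_file <- function(path) {
  m <- tryCatch(
    Matrix::readMM(path),
    error = function(e) stop("malformed MatrixMarket file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(m) != ncol(m)) {
    stop("MTX adjacency '", path, "' must be square, got ",
         nrow(m), "x", ncol(m), call. = FALSE)
  }
  m <- methods::as(m, "CsparseMatrix")
  if (!Matrix::isSymmetric(m, tol = 0)) {
    stop("MTX adjacency '", path, "' is not symmetric; ",
         "only undirected graphs are supported", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  if (graph_is_weighted(g) && all(igraph::E(g)$weight == 1)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  g
}

simplify_keep_first <- function(g) {
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "first", "ignore"))
}

#' Write a graph to a standard plain-text format
#'
#' The graph is validated before anything is written; round-tripping through
#' [read_graph()] reproduces the node set, edge set and weights (exactly for
#' edgelist and MTX, to writer precision of ~1e-15 relative for GraphML).
#' MTX carries no node identifiers: it round-trips the full labeling only
#' when node names are the indices `"1".."n"`.
#'
#' @inheritParams read_graph
#' @param graph A valid graph (see [check_graph()]).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("edgelist", "graphml", "mtx")) {
  graph <- check_graph(graph)
  if (missing(format)) format <- guess_graph_format(path)
  format <- match.arg(format)
  switch(format,
    edgelist = {
      el <- igraph::as_edgelist(graph, names = TRUE)
      lines <- if (graph_is_weighted(graph)) {
        paste(el[, 1], el[, 2],
              formatC(igraph::E(graph)$weight, digits = 17, format = "g"))
      } else {
        paste(el[, 1], el[, 2])
      }
      writeLines(lines, path)
    },
    graphml = igraph::write_graph(graph, path, format = "graphml"),
    mtx = {
      el <- igraph::as_edgelist(graph, names = FALSE)
      w <- if (graph_is_weighted(graph)) igraph::E(graph)$weight else
        rep(1, nrow(el))
      n <- igraph::vcount(graph)
      m <- Matrix::sparseMatrix(i = pmax(el[, 1], el[, 2]),
                                j = pmin(el[, 1], el[, 2]),
                                x = w, dims = c(n, n), symmetric = TRUE)
      Matrix::writeMM(m, path)
    }
  )
  invisible(path)
}

# Canonical numeric keys for the edge set: (min-1)*n + (max-1), i<j.
# Safe in doubles for n < 9e7.
edge_keys <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  n <- igraph::vcount(graph)
  pair_keys(el[, 1], el[, 2], n)
}

pair_keys <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n + (hi - 1)
}

# Order-independent fingerprint of a graph's edge set (+ weights).
edge_set_hash <- function(graph) {
  k <- sort(edge_keys(graph))
  if (graph_is_weighted(graph)) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    o <- order(pair_keys(el[, 1], el[, 2], igraph::vcount(graph)))
    paste(c(format(k, trim = TRUE),
            formatC(igraph::E(graph)$weight[o], digits = 15, format = "g")),
          collapse = ",")
  } else {
    paste(format(k, trim = TRUE), collapse = ",")
  }
}
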