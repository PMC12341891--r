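# Uniform contract over igraph community-detection algorithms.
#
# The algorithms themselves are delegated to igraph; what this module owns
# is the contract: a validated (name, params) specification, deterministic
# behaviour under a seed, and automatic use of edge weights where the
# algorithm supports them.

.method_catalogue <- list(
  louvain = list(
    fn = function(g, p) igraph::cluster_louvain(
      g, resolution = p$resolution %||% 1),
    params = list(resolution = list(default = 1, check = "positive"))
  ),
  leiden = list(
    fn = function(g, p) igraph::cluster_leiden(
      g, objective_function = p$objective %||% "modularity",
      resolution = p$resolution %||% 1,
      n_iterations = p$n_iterations %||% 2L),
    params = list(
      resolution = list(default = 1, check = "positive"),
      objective = list(default = "modularity",
                       check = c("modularity", "CPM")),
      n_iterations = list(default = 2L, check = "positive_integer"))
  ),
  walktrap = list(
    fn = function(g, p) igraph::cluster_walktrap(g, steps = p$steps %||% 4L),
    params = list(steps = list(default = 4L, check = "positive_integer"))
  ),
  fastgreedy = list(
    fn = function(g, p) igraph::cluster_fast_greedy(g),
    params = list()
  ),
  infomap = list(
    fn = function(g, p) igraph::cluster_infomap(
      g, nb.trials = p$trials %||% 10L),
    params = list(trials = list(default = 10L, check = "positive_integer"))
  ),
  labelprop = list(
    fn = function(g, p) igraph::cluster_label_prop(g),
    params = list()
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a community-detection method
#'
#' Builds a validated method specification from the catalogue:
#' `louvain` (resolution), `leiden` (resolution, objective, n_iterations),
#' `walktrap` (steps), `fastgreedy`, `infomap` (trials), `labelprop`.
#' Specifications print as `"name"` or `"name:param=value,..."`, the form
#' also accepted on the command line.
#'
#' @param name Method name from the catalogue.
#' @param ... Named algorithm parameters.
#' @return A `detection_method` object.
#' @export
#' @examples
#' detection_method("leiden", resolution = 0.5)
detection_method <- function(name, ...) {
  if (!name %in% names(.method_catalogue)) {
    stop("unknown method '", name, "'; catalogue: ",
         paste(names(.method_catalogue), collapse = ", "), call. = FALSE)
  }
  params <- list(...)
  spec <- .method_catalogue[[name]]
  bad <- setdiff(names(params), names(spec$params))
  if (length(bad) || (length(params) && is.null(names(params)))) {
    stop("invalid parameter(s) for ", name, ": ",
         paste(bad, collapse = ", "), "; allowed: ",
         if (length(spec$params)) paste(names(spec$params), collapse = ", ")
         else "(none)", call. = FALSE)
  }
  for (pn in names(params)) {
    v <- params[[pn]]
    chk <- spec$params[[pn]]$check
    ok <- if (identical(chk, "positive")) {
      is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0
    } else if (identical(chk, "positive_integer")) {
      is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 1 &&
        v == as.integer(v)
    } else {
      is.character(v) && length(v) == 1L && v %in% chk
    }
    if (!ok) {
      stop("parameter '", pn, "' of ", name, " must be ",
           if (is.character(chk) && length(chk) > 1L)
             paste("one of", paste(chk, collapse = "/"))
           else gsub("_", " ", chk),
           call. = FALSE)
    }
  }
  structure(list(name = name, params = params,
                 label = method_label(name, params)),
            class = "detection_method")
}

method_label <- function(name, params) {
  if (!length(params)) return(name)
  params <- params[order(names(params))]
  paste0(name, ":", paste(names(params), unlist(params),
                          sep = "=", collapse = ","))
}

#' @exportS3Method
format.detection_method <- function(x, ...) x$label

#' @exportS3Method
print.detection_method <- function(x, ...) {
  cat("<detection_method>", x$label, "\n")
  invisible(x)
}

#' Parse a `"name:param=value,..."` method string
#'
#' @param spec Character specification, e.g. `"leiden:resolution=0.5"`.
#' @return A `detection_method`.
#' @export
parse_method <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  name <- parts[1L]
  params <- list()
  if (length(parts) > 1L) {
    for (kv in strsplit(parts[2L], ",", fixed = TRUE)[[1L]]) {
      eq <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(eq) != 2L) stop("malformed parameter '", kv, "'", call. = FALSE)
      v <- suppressWarnings(as.numeric(eq[2L]))
      params[[eq[1L]]] <- if (is.na(v)) eq[2L] else v
    }
  }
  do.call(detection_method, c(list(name = name), params))
}

#' Sweep one parameter of a method
#'
#' @param name Catalogue method name.
#' @param param_name Parameter to vary.
#' @param values Vector of parameter values.
#' @return A list of `detection_method` objects, one per value.
#' @export
#' @examples
#' method_grid("leiden", "resolution", c(0.5, 1, 2))
method_grid <- function(name, param_name, values) {
  lapply(values, function(v) {
    args <- stats::setNames(list(v), param_name)
    do.call(detection_method, c(list(name = name), args))
  })
}

#' Detect communities with a catalogued method
#'
#' Runs the specified algorithm on the graph (using edge weights where the
#' algorithm supports them) under a fixed RNG substream, so the result is a
#' pure function of `(graph, method, seed)` — including for inherently
#' stochastic algorithms such as Louvain's node ordering or label
#' propagation.
#'
#' @param graph A valid graph (see [check_graph()]).
#' @param method A `detection_method` (or a string accepted by
#'   [parse_method()]).
#' @param seed Integer seed.
#' @return Community labels (integers) named by node id.
#' @export
#' @examples
#' sim <- sbm_graph(c(20, 20), 0.5, 0.02, seed = 1)
#' table(detect_communities(sim$graph, detection_method("louvain"), seed = 2))
detect_communities <- function(graph, method, seed = 1L) {
  graph <- check_graph(graph)
  if (is.character(method)) method <- parse_method(method)
  stopifnot(inherits(method, "detection_method"))
  fn <- .method_catalogue[[method$name]]$fn
  comm <- with_seed(seed, fn(graph, method$params))
  m <- igraph::membership(comm)
  stats::setNames(as.integer(m), igraph::V(graph)$name)
}
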