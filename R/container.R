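# Versioned single-file index container -------------------------------------

PANTAG_MAGIC <- "PANTAGIDX"
PANTAG_VERSION <- 1L

#' Build a complete queryable index for a graph
#'
#' Convenience orchestrator: builds the whole-text index and tag array
#' (optionally per weakly connected component followed by the interleaving
#' merge, which yields the identical array) plus the sampled tag array for
#' coordinate translation.
#'
#' @param graph A `pangenome_graph` or path to a GFA file.
#' @param k,degree,max_rounds As in [build_tags()].
#' @param per_component Build per component and merge (default `FALSE`).
#' @return An object of class `pantag_index` with elements `graph`,
#'   `index`, `tags`, `sampled` and `report`.
#' @export
pantag_build <- function(graph, k = 31, degree = 64, max_rounds = 256,
                         per_component = FALSE) {
  if (is.character(graph)) graph <- read_gfa(graph)
  if (per_component) {
    text <- build_text(graph)
    index <- build_msbwt(text)
    comps <- sort(unique(vapply(graph$walks,
                                function(w) graph$comp[w$steps[1L, 1L]], 0L)))
    parts <- lapply(comps, function(ci)
      build_component(graph, ci, k = k, degree = degree,
                      max_rounds = max_rounds))
    tags <- merge_components(index, parts, graph)
    report <- list(per_component = lapply(parts, function(p)
      c(component = p$component, p$report$coverage)))
  } else {
    res <- build_tags(graph, k = k, degree = degree, max_rounds = max_rounds)
    index <- res$index; tags <- res$tags; report <- res$report
  }
  structure(list(graph = graph, index = index, tags = tags,
                 sampled = build_sampled(tags), report = report, k = k),
            class = "pantag_index")
}

#' @export
print.pantag_index <- function(x, ...) {
  print(x$graph); print(x$index); print(x$tags); print(x$sampled)
  invisible(x)
}

#' Save / load an index container
#'
#' Writes a single-file container with a magic string and version header; a
#' version mismatch refuses to load. Structures round-trip bit-exactly.
#'
#' @param x A `pantag_index`.
#' @param path File path.
#' @return `save_index`: `path`, invisibly. `load_index`: the
#'   `pantag_index`.
#' @export
save_index <- function(x, path) {
  if (!inherits(x, "pantag_index")) err_domain("expected a pantag_index")
  y <- unclass(x)
  y$tags$acc <- NULL                     # transient access counter
  saveRDS(list(magic = PANTAG_MAGIC, version = PANTAG_VERSION, payload = y),
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) err_usage(sprintf("index file '%s' not found", path))
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$magic, PANTAG_MAGIC))
    err_format("not a pantag index container")
  if (!identical(obj$version, PANTAG_VERSION))
    err_format(sprintf("container version %s not supported", obj$version))
  y <- obj$payload
  acc <- new.env(parent = emptyenv()); acc$n <- 0
  y$tags$acc <- acc
  structure(y, class = "pantag_index")
}
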