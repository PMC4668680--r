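#' Build a region adjacency graph
#'
#' Constructs the areal adjacency structure consumed by the conditional
#' autoregressive (CAR) priors and by the synthetic truth generators. The
#' graph must be connected: the intrinsic CAR precision has rank
#' `n_regions - 1` exactly when it is.
#'
#' @param n_regions Number of regions (at least 2).
#' @param topology One of `"ring"`, `"line"`, `"grid"`, or `"custom"`.
#'   For `"grid"` the regions are arranged row-major on an
#'   `grid_rows x ceiling(n_regions/grid_rows)` lattice with 4-neighbour
#'   adjacency. For `"custom"` supply `edges`.
#' @param grid_rows Number of rows for the `"grid"` topology.
#' @param edges For `topology = "custom"`: a two-column data frame or
#'   matrix of 1-based region index pairs (unordered; duplicates and
#'   self-loops are rejected).
#' @param region_names Optional character labels, recycled to
#'   `n_regions`. Defaults to `"R01"`, `"R02"`, ...
#' @return An object of class `region_graph`: a list with `regions`
#'   (tibble: `region`, `name`) and `edges` (tibble: `from`, `to`,
#'   with `from < to`).
#' @export
#' @examples
#' g <- make_region_graph(4, "ring")
#' g$edges
make_region_graph <- function(n_regions, topology = c("ring", "line", "grid", "custom"),
                              grid_rows = 2, edges = NULL, region_names = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.numeric(n_regions), n_regions >= 2)
  n <- as.integer(n_regions)
  e <- switch(topology,
    ring = cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L)),
    line = cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
    grid = grid_edges(n, as.integer(grid_rows)),
    custom = {
      if (is.null(edges)) rlang::abort("custom topology requires `edges`")
      em <- as.matrix(edges[, 1:2])
      storage.mode(em) <- "integer"
      em
    }
  )
  if (topology == "ring" && n == 2) e <- cbind(1L, 2L)  # avoid duplicated edge
  e <- t(apply(e, 1, sort))
  if (any(e[, 1] == e[, 2])) rlang::abort("self-loops are not allowed")
  if (any(e < 1 | e > n)) rlang::abort("edge indices outside 1..n_regions")
  e <- unique(e)
  nm <- region_names %||% sprintf("R%02d", seq_len(n))
  g <- structure(list(
    regions = tibble::tibble(region = seq_len(n), name = rep_len(nm, n)),
    edges = tibble::tibble(from = as.integer(e[, 1]), to = as.integer(e[, 2]))
  ), class = "region_graph")
  comp <- graph_components(g)
  if (max(comp) > 1) {
    sizes <- table(comp)
    rlang::abort(sprintf(
      "adjacency graph is disconnected: %d components (sizes %s); CAR priors require a connected graph",
      length(sizes), paste(sizes, collapse = ", ")))
  }
  g
}

grid_edges <- function(n, rows) {
  cols <- ceiling(n / rows)
  idx <- function(r, c) (r - 1L) * cols + c
  e <- NULL
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- idx(r, c)
    if (i > n) next
    if (c < cols && idx(r, c + 1L) <= n) e <- rbind(e, c(i, idx(r, c + 1L)))
    if (r < rows && idx(r + 1L, c) <= n) e <- rbind(e, c(i, idx(r + 1L, c)))
  }
  e
}

# Connected-component labels by breadth-first search over the edge list.
graph_components <- function(graph) {
  n <- nrow(graph$regions)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[k]; j <- graph$edges$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph: %d regions, %d edges>\n",
              nrow(x$regions), nrow(x$edges)))
  invisible(x)
}

#' Number of regions in a region graph
#' @param graph A `region_graph`.
#' @return Integer count.
#' @export
n_regions <- function(graph) nrow(graph$regions)

#' Default 10-region adjacency
#'
#' A documented default edge list for a 10-region study area, digitized
#' from a national survey region map: a central capital region surrounded
#' by neighbouring central regions, with eastern, northern and western
#' blocks. Shipped so demonstrations run out of the box; all CAR code
#' takes adjacency as input, so analyses of other geographies simply pass
#' their own graph.
#'
#' @return A `region_graph` with 10 regions.
#' @export
#' @examples
#' default_region_graph()
default_region_graph <- function() {
  names10 <- c("Central 1", "Central 2", "Capital", "East Central", "Eastern",
               "North", "Northeast", "West Nile", "Western", "Southwest")
  e <- rbind(
    c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(4, 5), c(5, 6), c(5, 7),
    c(6, 7), c(6, 8), c(2, 6), c(2, 9), c(6, 9), c(8, 9), c(9, 10), c(1, 10),
    c(1, 9), c(4, 6)
  )
  make_region_graph(10, "custom", edges = e, region_names = names10)
}

#' Read / write a region graph as an edge-list CSV
#'
#' The CSV has columns `from`, `to` (1-based region indices) and
#' optionally `name_from`, `name_to`.
#'
#' @param graph A `region_graph`.
#' @param path File path.
#' @return `write_region_graph()` returns `path` invisibly;
#'   `read_region_graph()` returns a `region_graph`.
#' @export
write_region_graph <- function(graph, path) {
  nm <- graph$regions$name
  out <- dplyr::mutate(graph$edges,
                       name_from = nm[.data$from], name_to = nm[.data$to])
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_region_graph
#' @export
read_region_graph <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_df_has(df, c("from", "to"), "adjacency file")
  n <- max(df$from, df$to)
  nm <- NULL
  if (all(c("name_from", "name_to") %in% names(df))) {
    nm <- character(n)
    nm[df$from] <- df$name_from
    nm[df$to] <- df$name_to
  }
  make_region_graph(n, "custom", edges = as.matrix(df[, c("from", "to")]),
                    region_names = nm)
}
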