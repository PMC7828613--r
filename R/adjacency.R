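#' Area adjacency graphs
#'
#' An `adjacency_graph` holds the neighbourhood structure of the study areas
#' (states) used by the structured spatial effect. It is an undirected simple
#' graph: no self-loops, edges stored once as unordered pairs. The intrinsic
#' CAR prior on the structured spatial effect is only proper on the
#' sum-to-zero subspace of a *connected* graph, so connectivity is checked
#' whenever a graph is built.
#'
#' @param n_areas number of areas (positive integer).
#' @param edges two-column integer matrix of area ids in `1..n_areas`, one row
#'   per undirected edge. Duplicate and reversed pairs are collapsed.
#' @param area_labels optional character vector of length `n_areas`.
#' @param regions optional factor/character vector of length `n_areas` giving
#'   a coarser grouping (geopolitical region) per area.
#'
#' @return An object of class `adjacency_graph` with elements `n_areas`,
#'   `edges` (canonical two-column matrix, `edges[,1] < edges[,2]`),
#'   `area_labels`, `regions`.
#' @export
adjacency_graph <- function(n_areas, edges, area_labels = NULL, regions = NULL) {
  n_areas <- as.integer(n_areas)
  if (length(n_areas) != 1L || is.na(n_areas) || n_areas < 1L)
    stop("n_areas must be a single positive integer")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n_areas))
      stop("edge endpoints must be area ids in 1..n_areas")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (!is.null(area_labels) && length(area_labels) != n_areas)
    stop("area_labels must have length n_areas")
  if (!is.null(regions) && length(regions) != n_areas)
    stop("regions must have length n_areas")
  structure(
    list(n_areas = n_areas, edges = edges,
         area_labels = area_labels, regions = regions),
    class = "adjacency_graph"
  )
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d areas, %d edges, %s\n",
              x$n_areas, nrow(x$edges),
              if (is_connected(x)) "connected" else "NOT connected"))
  invisible(x)
}

#' Neighbour counts (vertex degrees) of an adjacency graph
#' @param graph an [adjacency_graph()].
#' @return integer vector of length `n_areas`.
#' @export
graph_degrees <- function(graph) {
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n_areas)
}

#' Is the graph a single connected component?
#'
#' Breadth-first search from area 1.
#' @param graph an [adjacency_graph()].
#' @return logical scalar.
#' @export
is_connected <- function(graph) {
  n <- graph$n_areas
  if (n == 1L) return(TRUE)
  if (nrow(graph$edges) == 0L) return(FALSE)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1L]; j <- graph$edges[k, 2L]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Connected components of an adjacency graph
#' @param graph an [adjacency_graph()].
#' @return integer vector of component ids per area.
#' @keywords internal
graph_components <- function(graph) {
  n <- graph$n_areas
  comp <- integer(n)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1L]; j <- graph$edges[k, 2L]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

#' Rook-neighbour lattice graph
#'
#' Regular `rows` x `cols` lattice with horizontal and vertical neighbours,
#' used as a convenient connected stand-in for a real area map in simulations
#' and tests. Area ids run row-major.
#'
#' @param rows,cols lattice dimensions (positive integers).
#' @return An [adjacency_graph()] with `rows * cols` areas and
#'   `rows*(cols-1) + cols*(rows-1)` edges.
#' @examples
#' g <- make_lattice_adjacency(6, 6)  # 36 areas, 60 edges
#' @export
make_lattice_adjacency <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 1L || is.na(rows) || rows < 1L ||
      length(cols) != 1L || is.na(cols) || cols < 1L)
    stop("rows and cols must be positive integers")
  id <- function(r, c) (r - 1L) * cols + c
  e <- list()
  for (r in seq_len(rows)) for (co in seq_len(cols)) {
    if (co < cols) e[[length(e) + 1L]] <- c(id(r, co), id(r, co + 1L))
    if (r < rows)  e[[length(e) + 1L]] <- c(id(r, co), id(r + 1L, co))
  }
  edges <- if (length(e)) do.call(rbind, e) else matrix(integer(), ncol = 2L)
  adjacency_graph(rows * cols, edges)
}

#' Load a bundled area-contiguity fixture
#'
#' The `"nigeria37"` fixture is a hand-encoded, approximate contiguity graph
#' for Nigeria's 36 states plus the Federal Capital Territory, with each area
#' tagged by its geopolitical region. It is a synthetic stand-in encoded from
#' a printed map, not derived from GIS boundary data, and is intended for
#' simulation and testing of the spatial model at realistic scale.
#'
#' @param name fixture name; currently `"nigeria37"`.
#' @return An [adjacency_graph()] with labels and regions.
#' @export
load_area_fixture <- function(name = "nigeria37") {
  fixtures <- c("nigeria37")
  if (!name %in% fixtures)
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(fixtures, collapse = ", ")))
  areas <- utils::read.table(
    system.file("extdata", "nigeria37_synthetic_areas.tsv", package = "hapstar"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  edges_nm <- utils::read.table(
    system.file("extdata", "nigeria37_synthetic_edges.txt", package = "hapstar"),
    header = FALSE, stringsAsFactors = FALSE)
  i <- match(edges_nm[[1L]], areas$area)
  j <- match(edges_nm[[2L]], areas$area)
  if (any(is.na(i)) || any(is.na(j)))
    stop("fixture edge list names an unknown area")
  adjacency_graph(nrow(areas), cbind(i, j),
                  area_labels = areas$area, regions = areas$region)
}

#' Read an adjacency graph from an edge-list file
#'
#' One `"area_i area_j"` pair per line (integer ids, 1-based).
#' @param path file path.
#' @param n_areas number of areas; defaults to the largest id seen.
#' @return An [adjacency_graph()].
#' @export
read_adjacency <- function(path, n_areas = NULL) {
  e <- utils::read.table(path, header = FALSE)
  if (is.null(n_areas)) n_areas <- max(e[[1L]], e[[2L]])
  adjacency_graph(n_areas, cbind(e[[1L]], e[[2L]]))
}

#' Write an adjacency graph as an edge list
#' @param graph an [adjacency_graph()].
#' @param path output file path.
#' @export
write_adjacency <- function(graph, path) {
  utils::write.table(graph$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
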