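#' Build a synthetic areal lattice with rook contiguity
#'
#' Constructs `n_components` disconnected rectangular grids of `rows` x
#' `cols` areas each, with rook (edge-sharing) contiguity within every
#' component and no edges between components. This stands in for an
#' administrative areal geography (neighbourhood tabulation areas) whose
#' contiguity graph may be disconnected, as for an island borough.
#'
#' @param rows,cols grid dimensions of each component (positive integers).
#' @param n_components number of disconnected sub-lattices (default 1).
#' @param population_range length-2 numeric, min and max persons per area;
#'   populations are drawn uniformly on this range.
#' @param seed integer seed for the population draw.
#' @return An object of class `area_lattice`: a list with elements
#'   `areas` (data.frame: `area_id`, `component`, `row`, `col`,
#'   `population`), `adj` (symmetric 0/1 adjacency matrix, zero diagonal),
#'   `n_areas`, `n_components`.
#' @examples
#' lat <- make_lattice(3, 3, seed = 1)
#' rowSums(lat$adj)  # corner areas have degree 2, centre degree 4
#' @export
make_lattice <- function(rows, cols, n_components = 1L,
                         population_range = c(15000, 120000), seed = 1L) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("configuration error: 'rows' and 'cols' must be positive integers")
  if (n_components < 1 || n_components != round(n_components))
    stop("configuration error: 'n_components' must be a positive integer")
  if (rows * cols < 2)
    stop("configuration error: each component needs at least 2 areas")
  if (rows * cols < 4)
    warning("fewer than 4 areas per component; spatial structure is weak")
  if (length(population_range) != 2 || any(population_range <= 0) ||
      population_range[1] > population_range[2])
    stop("configuration error: invalid 'population_range'")

  per <- rows * cols
  n <- per * n_components
  areas <- data.frame(
    area_id = sprintf("A%03d", seq_len(n)),
    component = rep(seq_len(n_components), each = per),
    row = rep(rep(seq_len(rows), each = cols), n_components),
    col = rep(rep(seq_len(cols), times = rows), n_components),
    stringsAsFactors = FALSE
  )
  adj <- matrix(0L, n, n, dimnames = list(areas$area_id, areas$area_id))
  for (c_i in seq_len(n_components)) {
    off <- (c_i - 1L) * per
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        k <- off + (r - 1L) * cols + cc
        if (cc < cols) { adj[k, k + 1L] <- 1L; adj[k + 1L, k] <- 1L }
        if (r < rows) { adj[k, k + cols] <- 1L; adj[k + cols, k] <- 1L }
      }
    }
  }
  set.seed(as.integer(seed))
  areas$population <- stats::runif(n, population_range[1], population_range[2])

  structure(list(areas = areas, adj = adj, n_areas = n,
                 n_components = as.integer(n_components)),
            class = "area_lattice")
}

#' @export
print.area_lattice <- function(x, ...) {
  cat("area_lattice:", x$n_areas, "areas,",
      sum(x$adj) / 2, "edges,", x$n_components, "component(s)\n")
  invisible(x)
}

#' Connected components of a symmetric adjacency matrix
#'
#' Breadth-first labelling; isolated nodes (degree zero) form their own
#' components.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return integer vector of component labels (1-based).
#' @export
graph_components <- function(adj) {
  n <- nrow(adj)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      k <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[k, ] != 0 & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Construct an area_lattice from an explicit adjacency matrix
#'
#' @param adj symmetric 0/1 adjacency matrix (row/col names used as area
#'   ids when present).
#' @param population optional per-area population vector.
#' @return `area_lattice` object; components are computed from the graph.
#' @export
lattice_from_adjacency <- function(adj, population = NULL) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || any(adj != t(adj)))
    stop("adjacency must be a symmetric square matrix")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("A%03d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  comp <- graph_components(adj)
  if (is.null(population)) population <- rep(NA_real_, n)
  areas <- data.frame(area_id = ids, component = comp,
                      row = NA_integer_, col = NA_integer_,
                      population = population, stringsAsFactors = FALSE)
  structure(list(areas = areas, adj = adj, n_areas = n,
                 n_components = max(comp)),
            class = "area_lattice")
}

#' Write / read a plain-text adjacency edge list
#'
#' One edge per line, two whitespace-separated area ids. Isolated areas are
#' written as single-id lines so the full node set round-trips.
#'
#' @param lattice an `area_lattice`.
#' @param path file path.
#' @rdname adjacency_io
#' @export
write_adjacency <- function(lattice, path) {
  adj <- lattice$adj
  ids <- rownames(adj)
  idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
  lines <- sprintf("%s %s", ids[idx[, 1]], ids[idx[, 2]])
  iso <- ids[rowSums(adj) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @param population optional population vector passed to the rebuilt
#'   lattice (matched by sorted area id order).
#' @rdname adjacency_io
#' @export
read_adjacency <- function(path, population = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- sort(unique(unlist(parts)))
  n <- length(ids)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (p in parts) {
    if (length(p) == 2) {
      adj[p[1], p[2]] <- 1L
      adj[p[2], p[1]] <- 1L
    }
  }
  lattice_from_adjacency(adj, population = population)
}
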