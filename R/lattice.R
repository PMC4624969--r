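#' Build a square lattice with von Neumann neighbourhoods
#'
#' Constructs the spatial graph the dynamics run on: a `rows` x `cols` grid in
#' which every site is joined to its orthogonal neighbours (4 in the interior,
#' 3 on an edge, 2 in a corner). Boundaries are reflecting — boundary sites
#' simply have fewer neighbours, there is no wraparound. Sites are indexed
#' row-major starting at 1 (site of row i, column j is `(i - 1) * cols + j`).
#'
#' The per-edge migration weight `w` is stored as the constant 1/4 regardless
#' of a site's degree. Every event probability in the dynamics is a ratio in
#' which the same `w` appears in numerator and denominator, so this convention
#' is equivalent to `w = 1/degree(i)`; see [event_distribution()].
#'
#' @param rows,cols Positive integers; `rows * cols >= 2` (a single site has
#'   nobody to compete with).
#' @return An object of class `moran_lattice`: a list with elements `rows`,
#'   `cols`, `n_sites`, `neighbors` (per-site integer vectors, 1-based),
#'   `degree`, and `w` (the constant edge weight, 0.25).
#' @examples
#' lat <- build_lattice(3, 3)
#' lat$degree
#' @export
build_lattice <- function(rows, cols) {
  check_count(rows, "rows")
  check_count(cols, "cols")
  if (rows * cols < 2) {
    abort("`rows * cols` must be at least 2: a 1x1 lattice admits no competition.")
  }
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  n <- rows * cols
  idx <- function(i, j) (i - 1L) * cols + j
  neighbors <- vector("list", n)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      nb <- integer(0)
      if (i > 1L) nb <- c(nb, idx(i - 1L, j))
      if (i < rows) nb <- c(nb, idx(i + 1L, j))
      if (j > 1L) nb <- c(nb, idx(i, j - 1L))
      if (j < cols) nb <- c(nb, idx(i, j + 1L))
      neighbors[[idx(i, j)]] <- nb
    }
  }
  degree <- lengths(neighbors)
  nbr_mat <- matrix(-1L, nrow = n, ncol = 4L)
  for (s in seq_len(n)) nbr_mat[s, seq_len(degree[s])] <- neighbors[[s]] - 1L
  structure(
    list(rows = rows, cols = cols, n_sites = n,
         neighbors = neighbors, degree = degree, w = 0.25,
         nbr_mat = nbr_mat),
    class = "moran_lattice"
  )
}

#' Convert between site index and (row, column) coordinates
#'
#' The lattice uses row-major, 1-based site indexing; these helpers make the
#' bijection explicit so fitness fields and occupancy vectors can be aligned
#' with spatial positions.
#'
#' @param lattice A [build_lattice()] object.
#' @param site Integer vector of site indices in `1:n_sites`.
#' @param row,col Integer vectors of coordinates (recycled).
#' @return `site_coords()` returns a tibble with columns `site`, `row`, `col`;
#'   `site_index()` returns an integer vector of site indices.
#' @examples
#' lat <- build_lattice(3, 4)
#' site_index(lat, 2, 3)
#' site_coords(lat, 7)
#' @export
site_coords <- function(lattice, site = seq_len(lattice$n_sites)) {
  stopifnot(inherits(lattice, "moran_lattice"))
  site <- as.integer(site)
  if (any(site < 1L | site > lattice$n_sites)) {
    abort("`site` out of range for this lattice.")
  }
  tibble::tibble(
    site = site,
    row = (site - 1L) %/% lattice$cols + 1L,
    col = (site - 1L) %% lattice$cols + 1L
  )
}

#' @rdname site_coords
#' @export
site_index <- function(lattice, row, col) {
  stopifnot(inherits(lattice, "moran_lattice"))
  if (any(row < 1L | row > lattice$rows) || any(col < 1L | col > lattice$cols)) {
    abort("coordinates out of range for this lattice.")
  }
  as.integer((row - 1L) * lattice$cols + col)
}

#' @export
print.moran_lattice <- function(x, ...) {
  cat(sprintf("<moran_lattice> %d x %d (N = %d sites), von Neumann, reflecting boundaries\n",
              x$rows, x$cols, x$n_sites))
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
  invisible(x)
}
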