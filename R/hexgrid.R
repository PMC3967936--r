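# ---- Cylindrical hexagonal grid -----------------------------------------
#
# Offset coordinates, "odd-r" convention, 0-based: row 0 is the anterior
# border, rows run anterior -> posterior and do not wrap; columns run around
# the circumference and wrap modulo n_cols (the grid is a cylinder). Odd rows
# are shifted half a cell to the right:
#
#    row 0:   (0,0) (0,1) (0,2) ...
#    row 1:     (1,0) (1,1) (1,2) ...
#    row 2:   (2,0) (2,1) (2,2) ...
#
# Interior cells have exactly six distance-1 neighbours; cells on the
# anterior/posterior border rows have fewer.

#' Construct a cylindrical hexagonal grid
#'
#' @param n_rows number of cell rows along the anterior-posterior axis.
#' @param n_cols number of cells around the circumference (wraps).
#' @return an object of class `hex_grid`.
#' @export
hex_grid <- function(n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat("Hexagonal cylinder grid: ", x$n_rows, " rows x ", x$n_cols,
      " columns (", x$n_rows * x$n_cols, " cells)\n", sep = "")
  invisible(x)
}

#' Number of cells on a grid
#' @param grid a `hex_grid`.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Linear cell index of (row, col)
#'
#' Coordinates are 0-based. The linear index matches R's column-major layout
#' of an `n_rows x n_cols` field matrix, so `field[idx]` addresses cell
#' (row, col) directly.
#'
#' @param grid a `hex_grid`.
#' @param row,col 0-based coordinates.
#' @export
cell_index <- function(grid, row, col) col * grid$n_rows + row + 1L

#' 0-based (row, col) coordinates of linear cell indices
#' @param grid a `hex_grid`.
#' @param idx linear indices.
#' @export
cell_coords <- function(grid, idx) {
  idx0 <- idx - 1L
  cbind(row = idx0 %% grid$n_rows, col = idx0 %/% grid$n_rows)
}

# odd-r offset -> axial q (r is the row itself)
.axial_q <- function(row, col) col - (row - (row %% 2L)) / 2

#' Hexagonal distance between cells on the cylinder
#'
#' Distance in hex steps, minimised over the column wrap-around.
#'
#' @param grid a `hex_grid`.
#' @param a length-2 vector `c(row, col)` (0-based).
#' @param rows,cols vectors of target coordinates (0-based).
#' @return integer vector of distances.
#' @export
hex_distance <- function(grid, a, rows, cols) {
  q1 <- .axial_q(a[1], a[2]); r1 <- a[1]
  best <- NULL
  for (shift in c(-grid$n_cols, 0L, grid$n_cols)) {
    q2 <- .axial_q(rows, cols + shift); r2 <- rows
    dq <- q2 - q1; dr <- r2 - r1
    d <- (abs(dq) + abs(dr) + abs(dq + dr)) / 2
    best <- if (is.null(best)) d else pmin(best, d)
  }
  as.integer(best)
}

#' Cells within hexagonal distance k
#'
#' @param grid a `hex_grid`.
#' @param cell `c(row, col)` (0-based) or a linear index.
#' @param k neighbourhood radius (>= 1).
#' @return integer vector of linear cell indices, excluding the cell itself.
#' @export
neighbors <- function(grid, cell, k = 1L) {
  if (length(cell) == 1L) cell <- cell_coords(grid, cell)[1, ]
  if (cell[1] < 0 || cell[1] >= grid$n_rows ||
      cell[2] < 0 || cell[2] >= grid$n_cols) {
    stop("cell (", cell[1], ",", cell[2], ") is off the grid")
  }
  stopifnot(k >= 1)
  rows <- pmax(0L, cell[1] - k):pmin(grid$n_rows - 1L, cell[1] + k)
  cand <- expand.grid(row = rows, col = 0:(grid$n_cols - 1L))
  d <- hex_distance(grid, cell, cand$row, cand$col)
  sel <- d >= 1L & d <= k
  sort(cell_index(grid, cand$row[sel], cand$col[sel]))
}

# Precomputed neighbourhood table: n_cells x max_degree matrix of linear
# indices (NA-padded). Used by the integration step for fast neighbour sums.
neighbor_index <- function(grid, k = 1L) {
  n <- n_cells(grid)
  lists <- lapply(seq_len(n), function(i) neighbors(grid, i, k))
  width <- max(vapply(lists, length, integer(1)))
  out <- matrix(NA_integer_, nrow = n, ncol = width)
  for (i in seq_len(n)) out[i, seq_along(lists[[i]])] <- lists[[i]]
  out
}

# neighbour count satisfying a per-cell logical field
neighbor_count <- function(nb_idx, field_flag) {
  flag <- as.integer(field_flag)
  vals <- matrix(flag[nb_idx], nrow = nrow(nb_idx))
  rowSums(vals, na.rm = TRUE)
}

# does any neighbour satisfy the flag?
neighbor_any <- function(nb_idx, field_flag) neighbor_count(nb_idx, field_flag) > 0L
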