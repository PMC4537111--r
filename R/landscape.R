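#' Rectangular grid specification
#'
#' Defines the cellular array the foragers move over: its dimensions and
#' whether opposite edges are joined (toroidal topology, the default, which
#' removes edge effects and gives every cell a full 8-cell Moore
#' neighborhood).
#'
#' Cells are indexed 1..`n_rows * n_cols` in row-major order; cell `k` sits at
#' row `(k - 1) %/% n_cols + 1`, column `(k - 1) %% n_cols + 1`.
#'
#' @param n_rows,n_cols grid dimensions; both must be at least 3 so Moore
#'   neighborhoods are well defined.
#' @param toroidal logical; if `TRUE` (default) the grid wraps at the edges.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(20, 20)
#' n_cells(g)
#' @export
grid_spec <- function(n_rows = 20L, n_cols = 20L, toroidal = TRUE) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 3L || n_cols < 3L)
    stop("grid dimensions must be integers >= 3", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 toroidal = isTRUE(toroidal)),
            class = "grid_spec")
}

#' Number of cells (patches) in a grid
#' @param grid a [grid_spec()].
#' @return integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d (%d cells), %s\n", x$n_rows, x$n_cols,
              n_cells(x), if (x$toroidal) "toroidal" else "bounded"))
  invisible(x)
}

#' Moore neighborhood of a cell
#'
#' The up-to-eight cells surrounding cell `k` (diagonals included). On a
#' toroidal grid this is always 8 distinct cells; on a bounded grid only the
#' in-bounds cells are returned (3 at a corner, 5 on an edge). The focal cell
#' itself is never included. Order is deterministic: row-major over the
#' offsets (-1,-1), (-1,0), (-1,+1), (0,-1), (0,+1), (+1,-1), (+1,0), (+1,+1).
#'
#' @param k cell index in 1..`n_cells(grid)`.
#' @param grid a [grid_spec()].
#' @return integer vector of neighbor cell indices.
#' @examples
#' moore_neighbors(1, grid_spec(3, 3, toroidal = FALSE))
#' @export
moore_neighbors <- function(k, grid) {
  nc <- n_cells(grid)
  if (length(k) != 1L || is.na(k) || k < 1L || k > nc)
    stop("cell index out of range", call. = FALSE)
  row <- (k - 1L) %/% grid$n_cols
  col <- (k - 1L) %% grid$n_cols
  off <- .moore_offsets
  r <- row + off[, 1L]
  c <- col + off[, 2L]
  if (grid$toroidal) {
    r <- r %% grid$n_rows
    c <- c %% grid$n_cols
  } else {
    keep <- r >= 0L & r < grid$n_rows & c >= 0L & c < grid$n_cols
    r <- r[keep]
    c <- c[keep]
  }
  as.integer(r * grid$n_cols + c + 1L)
}

.moore_offsets <- cbind(
  rep(c(-1L, 0L, 1L), each = 3L),
  rep(c(-1L, 0L, 1L), times = 3L)
)[-5L, , drop = FALSE]  # drop (0,0): a cell is not its own neighbor

#' Neighbor index matrix for a whole grid
#'
#' Precomputes `moore_neighbors()` for every cell as an `n_cells x 8` integer
#' matrix, padded with `NA` (bounded grids) where a neighbor is out of bounds.
#' This is the lookup structure the tick engine uses.
#'
#' @param grid a [grid_spec()].
#' @return integer matrix with one row per cell.
#' @export
neighbor_index_matrix <- function(grid) {
  nc <- n_cells(grid)
  m <- matrix(NA_integer_, nrow = nc, ncol = 8L)
  for (k in seq_len(nc)) {
    nb <- moore_neighbors(k, grid)
    m[k, seq_along(nb)] <- nb
  }
  m
}

#' Mean of a per-cell quantity over a cell's Moore neighborhood
#'
#' The divisor is the actual neighbor count: 8 on a toroidal grid, fewer at
#' bounded edges, which keeps neighborhood means comparable across cells.
#' Applies identically to resources (giving the neighborhood-mean resource)
#' and occupancy counts (giving the neighborhood-mean occupancy).
#'
#' @param values numeric vector with one entry per cell.
#' @param k focal cell index.
#' @param grid a [grid_spec()].
#' @return scalar mean over the neighborhood of `k`.
#' @export
neighborhood_mean <- function(values, k, grid) {
  if (length(values) != n_cells(grid))
    stop("`values` must have one entry per cell", call. = FALSE)
  nb <- moore_neighbors(k, grid)
  sum(values[nb]) / length(nb)
}

#' Resource dynamics parameters
#'
#' Parameters of per-patch resource renewal and initialization. Each patch
#' renews according to
#' \deqn{R(t+1) = R^* + r (1 - R^*/s)(R^* + g)}
#' where \eqn{R^*} is the post-extraction stock, `r` the intrinsic growth
#' rate, `s` the saturation level and `g` a reservoir term that reseeds an
#' emptied patch. At the start of every generation each patch is initialized
#' uniformly at random on `[R_min, R_max]`.
#'
#' Defaults are the baseline configuration: the narrow initial range
#' `[2.99, 3]` keeps patches near-homogeneous while leaving just enough
#' stochasticity to randomize initial movements.
#'
#' @param r intrinsic growth rate per tick.
#' @param s saturation level (resource units).
#' @param g reservoir level (resource units).
#' @param R_min,R_max bounds of the initial-resource range.
#' @return An object of class `resource_params`.
#' @export
resource_params <- function(r = 0.1, s = 20, g = 0.1,
                            R_min = 2.99, R_max = 3.00) {
  if (r < 0 || s <= 0 || g < 0)
    stop("require r >= 0, s > 0, g >= 0", call. = FALSE)
  if (R_min < 0 || R_min > R_max)
    stop("require 0 <= R_min <= R_max", call. = FALSE)
  structure(list(r = r, s = s, g = g, R_min = R_min, R_max = R_max),
            class = "resource_params")
}

#' Initialize a landscape for a new generation
#'
#' Draws every cell's resource value independently and uniformly on
#' `[R_min, R_max]` and zeroes all occupancy counts. Called at the start of
#' every generation.
#'
#' @param grid a [grid_spec()].
#' @param params a [resource_params()].
#' @return An object of class `landscape`: list with elements `grid`, `R`
#'   (per-cell resource) and `J` (per-cell occupancy count).
#' @export
init_resources <- function(grid, params) {
  nc <- n_cells(grid)
  structure(list(grid = grid,
                 R = stats::runif(nc, params$R_min, params$R_max),
                 J = integer(nc)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d, R in [%.3g, %.3g], %d agents placed\n",
              x$grid$n_rows, x$grid$n_cols, min(x$R), max(x$R), sum(x$J)))
  invisible(x)
}

#' Resource renewal after extraction
#'
#' @param R_star post-extraction resource stock (scalar or vector).
#' @param params a [resource_params()].
#' @return resource value(s) at the next tick,
#'   `R* + r (1 - R*/s) (R* + g)`. With the baseline parameters this maps
#'   `[0, s]` into `(0, s]` and fixes `s`, so stocks stay positive and
#'   bounded once positive.
#' @export
regrow <- function(R_star, params) {
  if (any(R_star < 0))
    stop("negative post-extraction resource: extraction exceeded stock",
         call. = FALSE)
  R_star + params$r * (1 - R_star / params$s) * (R_star + params$g)
}

#' Export a landscape snapshot as a data frame
#'
#' One row per cell with its row/column coordinates, resource value and
#' occupancy count; suitable for writing to CSV.
#'
#' @param landscape a `landscape` object.
#' @return data.frame with columns `cell_row`, `cell_col`, `R`, `J`.
#' @export
landscape_snapshot <- function(landscape) {
  g <- landscape$grid
  k <- seq_len(n_cells(g))
  data.frame(cell_row = (k - 1L) %/% g$n_cols + 1L,
             cell_col = (k - 1L) %% g$n_cols + 1L,
             R = landscape$R,
             J = landscape$J)
}
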