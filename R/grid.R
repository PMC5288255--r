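#' Generate a triangular receiver-node grid
#'
#' Lays out receiver stations ("base nodes") on a triangular lattice with
#' alternate rows offset by half the spacing, keeps the `n_nodes` lattice
#' points closest to the lattice centre (a compact, roughly hexagonal
#' footprint), and perturbs each node by centred Gaussian placement jitter.
#' The defaults emulate a 166-node, 40-m field grid whose realised
#' inter-node distances are about 41 +/- 6 m.
#'
#' @param spacing Lattice spacing in metres (> 0).
#' @param n_nodes Number of receiver nodes (>= 3).
#' @param jitter_sd Standard deviation (m) of independent Gaussian placement
#'   jitter applied to each coordinate. 0 gives the exact lattice.
#' @param seed Optional integer seed; fixed seed gives a byte-identical grid.
#'
#' @return A [data.table::data.table] with columns `node_id`, `x`, `y`
#'   (metres), carrying attributes `spacing`, `jitter_sd` and `area_bounds`
#'   (`c(xmin, ymin, xmax, ymax)`).
#' @export
#' @examples
#' g <- generate_grid(spacing = 40, n_nodes = 166, jitter_sd = 0)
#' nrow(g)
generate_grid <- function(spacing = 40, n_nodes = 166, jitter_sd = 4,
                          seed = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number")
  }
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 3) {
    stop("`n_nodes` must be at least 3")
  }
  if (!is.numeric(jitter_sd) || jitter_sd < 0) {
    stop("`jitter_sd` must be non-negative")
  }
  n_nodes <- as.integer(n_nodes)

  # Build a lattice comfortably larger than needed, then keep the n_nodes
  # points nearest the central lattice node (ties broken by row, then column,
  # so n_nodes = 3 yields a node plus two adjacent neighbours: an
  # equilateral triangle of side `spacing`).
  h <- spacing * sqrt(3) / 2
  half <- ceiling(sqrt(n_nodes)) + 2L
  rows <- seq.int(-half, half)
  cols <- seq.int(-half, half)
  lat <- CJ(row = rows, col = cols)
  lat[, x := col * spacing + (row %% 2L) * spacing / 2]
  lat[, y := row * h]
  lat[, d2 := x^2 + y^2]
  setorder(lat, d2, row, col)
  lat <- lat[seq_len(n_nodes)]

  xy <- with_seed_if(seed, {
    cbind(lat$x + rnorm(n_nodes, 0, jitter_sd),
          lat$y + rnorm(n_nodes, 0, jitter_sd))
  })
  out <- data.table(
    node_id = sprintf("n%03d", seq_len(n_nodes)),
    x = xy[, 1], y = xy[, 2]
  )
  setattr(out, "spacing", spacing)
  setattr(out, "jitter_sd", jitter_sd)
  setattr(out, "area_bounds", c(
    xmin = min(out$x), ymin = min(out$y),
    xmax = max(out$x), ymax = max(out$y)
  ))
  out[]
}

#' Bounds of a node grid, optionally expanded
#'
#' @param grid A grid from [generate_grid()] (or any table with `x`, `y`).
#' @param expand Margin (m) added on every side.
#' @return Numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
grid_bounds <- function(grid, expand = 0) {
  b <- attr(grid, "area_bounds")
  if (is.null(b)) {
    b <- c(xmin = min(grid$x), ymin = min(grid$y),
           xmax = max(grid$x), ymax = max(grid$y))
  }
  b + c(-expand, -expand, expand, expand)
}
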