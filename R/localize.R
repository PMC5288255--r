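#' Bin detections into half-minute window summaries
#'
#' Windows are half-open `[k * window_s, (k + 1) * window_s)` aligned to
#' t = 0 of the experiment. Multiple beacons from the same node within one
#' window are summarised by their mean RSSI (aggregation in dB).
#'
#' @param records Detection table with columns `tag_id`, `node_id`, `t`,
#'   `rssi`.
#' @param window_s Window length (s), default 30.
#' @return `data.table` with one row per (`tag_id`, `window_index`,
#'   `node_id`): `mean_rssi`, `n_beacons`. Empty input gives an empty table.
#' @export
window_detections <- function(records, window_s = 30) {
  if (window_s <= 0) stop("`window_s` must be > 0")
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) {
    return(data.table(tag_id = character(), window_index = integer(),
                      node_id = character(), mean_rssi = numeric(),
                      n_beacons = integer()))
  }
  out <- rec[, .(mean_rssi = mean(rssi), n_beacons = .N),
             by = .(tag_id, window_index = as.integer(floor(t / window_s)),
                    node_id)]
  setorder(out, tag_id, window_index, node_id)
  out[]
}

#' Invert the log-distance path-loss model
#'
#' `d = d0 * 10^((rssi0 - rssi) / (10 * exponent))`; strictly decreasing in
#' `rssi`. Extrapolates beyond any calibration range; when `flag_beyond` is
#' given, a warning reports how many distances exceed it (e.g. 10 x the
#' grid spacing).
#'
#' @param rssi Observed RSSI (dB), vectorised.
#' @param rssi0 Model RSSI at `d0`.
#' @param d0 Reference distance (m).
#' @param exponent Path-loss exponent (> 0).
#' @param flag_beyond Optional distance (m) beyond which values are flagged.
#' @return Distances (m).
#' @export
rssi_to_distance <- function(rssi, rssi0 = -40, d0 = 1, exponent = 2.5,
                             flag_beyond = NULL) {
  if (exponent <= 0) stop("`exponent` must be > 0")
  d <- d0 * 10^((rssi0 - rssi) / (10 * exponent))
  if (!is.null(flag_beyond) && any(d > flag_beyond, na.rm = TRUE)) {
    warning(sum(d > flag_beyond, na.rm = TRUE),
            " distance(s) beyond ", flag_beyond,
            " m: outside the plausible calibration range")
  }
  d
}

# Per-window sum of squared RSSI residuals on a subset of rows.
# px, py: positions indexed by global window id G; lg: local group index
# (1..k, consecutive) for rowsum. Works on squared distances to avoid a
# sqrt: model = rssi0 - (10*gamma/(2*ln10)) * (log(d^2) - 2*log(d0)).
.mlat_obj_rows <- function(px, py, gidx, lg, nx, ny, rs, cfg) {
  d2 <- pmax((px[gidx] - nx)^2 + (py[gidx] - ny)^2, 1e-6)
  halfc <- 10 * cfg$path_loss_exponent / (2 * log(10))
  mod <- cfg$rssi0 - halfc * (log(d2) - 2 * log(cfg$d0))
  r <- rs - mod
  as.vector(rowsum(r * r, lg, reorder = TRUE))
}

# Damped Gauss-Newton on the multilateration objective, vectorised over
# windows, from one set of start positions. px0/py0: start per window;
# G/NX/NY/RS: long per-row vectors (sorted by window); cnt/starts: row
# counts and offsets per window. Per-window backtracking line search keeps
# the objective non-increasing; steps are capped at one grid spacing.
.mlat_gn <- function(px0, py0, G, NX, NY, RS, cnt, starts, config,
                     spacing, max_iter, tol) {
  W <- length(px0)
  px <- px0; py <- py0
  all_lg <- rep.int(seq_len(W), cnt)
  f <- .mlat_obj_rows(px, py, G, all_lg, NX, NY, RS, config)
  cfac <- 10 * config$path_loss_exponent / log(10)
  converged <- rep(FALSE, W)
  for (it in seq_len(max_iter)) {
    act <- which(!converged)
    if (!length(act)) break
    k <- length(act)
    ridx <- sequence(cnt[act], from = starts[act])
    gi <- G[ridx]
    lg <- rep.int(seq_len(k), cnt[act])
    nxs <- NX[ridx]; nys <- NY[ridx]; rss <- RS[ridx]
    dxv <- px[gi] - nxs
    dyv <- py[gi] - nys
    d2 <- pmax(dxv * dxv + dyv * dyv, 1e-6)
    mod <- config$rssi0 - (cfac / 2) * (log(d2) - 2 * log(config$d0))
    r <- rss - mod
    jx <- -cfac * dxv / d2
    jy <- -cfac * dyv / d2
    A11 <- as.vector(rowsum(jx * jx, lg))
    A12 <- as.vector(rowsum(jx * jy, lg))
    A22 <- as.vector(rowsum(jy * jy, lg))
    b1 <- as.vector(rowsum(jx * r, lg))
    b2 <- as.vector(rowsum(jy * r, lg))
    det <- A11 * A22 - A12 * A12 + 1e-12
    sx <- (A22 * b1 - A12 * b2) / det
    sy <- (A11 * b2 - A12 * b1) / det
    # cap the step at one grid spacing
    sn <- sqrt(sx * sx + sy * sy)
    cap <- pmin(1, spacing / pmax(sn, 1e-12))
    sx <- sx * cap; sy <- sy * cap
    step <- rep(1, k)
    pending <- rep(TRUE, k)
    newx <- px[act]; newy <- py[act]
    for (bt in 1:6) {
      if (!any(pending)) break
      trialx <- px; trialy <- py
      trialx[act] <- px[act] + step * sx
      trialy[act] <- py[act] + step * sy
      ftr <- .mlat_obj_rows(trialx, trialy, gi, lg, nxs, nys, rss, config)
      improved <- pending & (ftr <= f[act] + 1e-12)
      newx[improved] <- trialx[act][improved]
      newy[improved] <- trialy[act][improved]
      pending <- pending & !improved
      step[pending] <- step[pending] / 2
    }
    moved <- sqrt((newx - px[act])^2 + (newy - py[act])^2)
    px[act] <- newx; py[act] <- newy
    f[act] <- .mlat_obj_rows(px, py, gi, lg, nxs, nys, rss, config)
    converged[act] <- (moved < tol) | pending
  }
  list(px = px, py = py, f = f, converged = converged)
}

#' Estimate position fixes by RSSI multilateration
#'
#' Two-stage estimator, vectorised over all (tag, window) cells: (1) an
#' RSSI-weighted centroid of the contributing nodes (weights linear in
#' `rssi - min(rssi) + 1` within the window) as the initial guess; (2)
#' damped Gauss-Newton nonlinear least squares on the objective
#' `sum((observed_rssi - model_rssi(position))^2)` under the configured
#' path-loss model, with per-window backtracking line search so the
#' objective never increases. A second start at the strongest receiving
#' node guards against the centroid start's local minima (a bird sitting
#' outside the convex hull of its nodes); the better converged solution
#' wins. Windows with fewer than three distinct nodes
#' yield no fix. If the solver fails to improve on its start, does not
#' converge within `max_iter`, or leaves the grid bounds expanded by one
#' spacing, the weighted centroid is reported (`method =
#' "weighted_centroid"`).
#'
#' @param summaries Window summaries from [window_detections()].
#' @param grid Node grid ([generate_grid()]).
#' @param config [world_config()] carrying the propagation parameters.
#' @param window_s Window length (s) used for `t_mid`, default 30.
#' @param max_iter Maximum Gauss-Newton iterations (default 100).
#' @param tol Convergence tolerance on the step norm (m), default 1e-6.
#'
#' @return `data.table` of fixes: `tag_id`, `window_index`, `t_mid`, `x`,
#'   `y`, `n_nodes`, `rms_residual` (dB), `method`.
#' @export
estimate_positions <- function(summaries, grid, config, window_s = 30,
                               max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(config, "world_config"))
  ws <- as.data.table(summaries)
  empty <- data.table(tag_id = character(), window_index = integer(),
                      t_mid = numeric(), x = numeric(), y = numeric(),
                      n_nodes = integer(), rms_residual = numeric(),
                      method = character())
  if (nrow(ws) == 0L) return(empty)
  unknown <- setdiff(unique(ws$node_id), grid$node_id)
  if (length(unknown)) {
    stop("summaries reference unknown nodes: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  ws <- merge(ws, grid[, .(node_id, nx = x, ny = y)], by = "node_id")
  ws <- ws[, .(node_id, nx, ny, mean_rssi, tag_id, window_index)]
  # keep only cells with >= 3 distinct nodes
  ws[, n_nodes := .N, by = .(tag_id, window_index)]
  ws <- ws[n_nodes >= 3L]
  if (nrow(ws) == 0L) return(empty)
  # degenerate geometry: all contributing nodes at one coordinate
  degen <- ws[, .(is_degen = (max(nx) - min(nx) < 1e-9) &&
                    (max(ny) - min(ny) < 1e-9)),
              by = .(tag_id, window_index)]
  if (any(degen$is_degen)) {
    bad <- degen[is_degen == TRUE]
    stop("degenerate geometry: all contributing nodes share one location (",
         bad$tag_id[1], ", window ", bad$window_index[1], ")")
  }
  setorder(ws, tag_id, window_index, node_id)
  cells <- ws[, .(n_nodes = .N), by = .(tag_id, window_index)]
  W <- nrow(cells)
  ws[, g := rleid(tag_id, window_index)]

  # stage 1: weighted centroid
  ws[, w := mean_rssi - min(mean_rssi) + 1, by = g]
  cent <- ws[, .(x = sum(w * nx) / sum(w), y = sum(w * ny) / sum(w)), by = g]

  # plain vectors + per-window row ranges (ws is sorted by g)
  G <- ws$g; NX <- ws$nx; NY <- ws$ny; RS <- ws$mean_rssi
  cnt <- tabulate(G, W)
  ends <- cumsum(cnt); starts <- ends - cnt + 1L
  all_lg <- rep.int(seq_len(W), cnt)
  spacing <- attr(grid, "spacing")
  if (is.null(spacing)) spacing <- 40

  f0 <- .mlat_obj_rows(cent$x, cent$y, G, all_lg, NX, NY, RS, config)

  # second start: strongest node, nudged toward the centroid (a bird just
  # outside the node hull pulls the solver past the centroid basin)
  best_row <- ws[, .I[which.max(mean_rssi)], by = g]$V1
  sx0 <- NX[best_row]; sy0 <- NY[best_row]
  nudge <- 5
  vlen <- pmax(sqrt((cent$x - sx0)^2 + (cent$y - sy0)^2), 1e-9)
  sx0 <- sx0 + (cent$x - sx0) / vlen * pmin(nudge, vlen)
  sy0 <- sy0 + (cent$y - sy0) / vlen * pmin(nudge, vlen)

  run1 <- .mlat_gn(cent$x, cent$y, G, NX, NY, RS, cnt, starts, config,
                   spacing, max_iter, tol)
  run2 <- .mlat_gn(sx0, sy0, G, NX, NY, RS, cnt, starts, config,
                   spacing, max_iter, tol)
  take2 <- run2$converged & (run2$f < run1$f - 1e-12)
  px <- ifelse(take2, run2$px, run1$px)
  py <- ifelse(take2, run2$py, run1$py)
  f <- ifelse(take2, run2$f, run1$f)
  converged <- ifelse(take2, TRUE, run1$converged)

  nls_ok <- converged & (f <= f0 + 1e-9)
  # reject NLS solutions outside bounds expanded by one spacing
  b <- grid_bounds(grid, expand = spacing)
  inside <- px >= b[1] & px <= b[3] & py >= b[2] & py <= b[4]
  use_nls <- nls_ok & inside
  fx <- ifelse(use_nls, px, cent$x)
  fy <- ifelse(use_nls, py, cent$y)
  fobj <- ifelse(use_nls, f, f0)
  out <- cells[, .(tag_id, window_index, n_nodes)]
  out[, `:=`(
    t_mid = (window_index + 0.5) * window_s,
    x = fx, y = fy,
    rms_residual = sqrt(fobj / n_nodes),
    method = ifelse(use_nls, "nls", "weighted_centroid")
  )]
  setcolorder(out, c("tag_id", "window_index", "t_mid", "x", "y",
                     "n_nodes", "rms_residual", "method"))
  setorder(out, tag_id, window_index)
  out[]
}

#' Estimate a single position fix
#'
#' Convenience wrapper around [estimate_positions()] for one (tag, window)
#' summary. Returns `NULL` when fewer than three distinct nodes contribute.
#'
#' @inheritParams estimate_positions
#' @param summary One window's node-level summary (rows for a single
#'   `tag_id`/`window_index`).
#' @return One-row `data.table`, or `NULL`.
#' @export
estimate_position <- function(summary, grid, config, window_s = 30,
                              max_iter = 100, tol = 1e-6) {
  s <- as.data.table(summary)
  if (length(unique(s$node_id)) < 3L) return(NULL)
  fix <- estimate_positions(s, grid, config, window_s, max_iter, tol)
  if (nrow(fix) == 0L) NULL else fix
}

#' Assemble per-bird fix series
#'
#' Splits fixes into one strictly window-ordered series per tag. Gaps
#' (missing windows) are preserved, never interpolated. Duplicate
#' (tag, window) fixes are a contract violation.
#'
#' @param fixes Fix table from [estimate_positions()].
#' @return Named list of `data.table`s, one per `tag_id`.
#' @export
build_tracks <- function(fixes) {
  fx <- as.data.table(fixes)
  if (anyDuplicated(fx[, .(tag_id, window_index)])) {
    stop("duplicate (tag_id, window_index) fixes")
  }
  setorder(fx, tag_id, window_index)
  split(fx, by = "tag_id")
}
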