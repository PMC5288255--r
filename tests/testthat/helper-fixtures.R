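library(data.table)

# Brute-force grid-search minimizer of the multilateration objective:
# coarse 8-m scan over the contributing nodes' bounding box expanded by
# `margin`, then an exhaustive 1-m scan around the coarse minimum. Returns
# the best 1-m grid point (integer-aligned coordinates).
bruteforce_fix <- function(nodes, rssi, cfg, margin = 40) {
  obj <- function(xs, ys) {
    # sum of squared RSSI residuals at every (xs, ys) combination
    o <- matrix(0, length(xs), length(ys))
    for (i in seq_len(nrow(nodes))) {
      d <- sqrt(outer((xs - nodes$x[i])^2, (ys - nodes$y[i])^2, "+"))
      d <- pmax(d, 1e-3)
      mod <- cfg$rssi0 - 10 * cfg$path_loss_exponent * log10(d / cfg$d0)
      o <- o + (rssi[i] - mod)^2
    }
    o
  }
  xs <- seq(floor(min(nodes$x) - margin), ceiling(max(nodes$x) + margin), by = 8)
  ys <- seq(floor(min(nodes$y) - margin), ceiling(max(nodes$y) + margin), by = 8)
  o <- obj(xs, ys)
  i <- which(o == min(o), arr.ind = TRUE)[1, ]
  xs2 <- seq(xs[i[1]] - 16, xs[i[1]] + 16, by = 1)
  ys2 <- seq(ys[i[2]] - 16, ys[i[2]] + 16, by = 1)
  o2 <- obj(xs2, ys2)
  j <- which(o2 == min(o2), arr.ind = TRUE)[1, ]
  c(x = xs2[j[1]], y = ys2[j[2]])
}

# Textbook re-implementations of the sampling-adequacy diagnostics,
# written against the formulas directly (independent of the package path).
ref_bartlett <- function(R, n) {
  p <- ncol(R)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(det(R))
  list(chi2 = chi2, df = p * (p - 1) / 2,
       p_value = stats::pchisq(chi2, p * (p - 1) / 2, lower.tail = FALSE))
}
ref_kmo <- function(R) {
  S <- solve(R)
  p <- ncol(R)
  Q <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) Q[i, j] <- -S[i, j] / sqrt(S[i, i] * S[j, j])
  num <- 0; den <- 0
  for (i in 1:p) for (j in 1:p) if (i != j) {
    num <- num + R[i, j]^2
    den <- den + R[i, j]^2 + Q[i, j]^2
  }
  num / den
}

# Random correlation matrix (positive definite) of dimension p.
random_corr <- function(p, n = 50) {
  X <- matrix(stats::rnorm(n * p), n, p)
  stats::cor(X)
}

# Hand-rolled association enumeration: all (partner, window) pairs within
# `radius` of the focal, optional mate exclusion. Triple loop on purpose.
bruteforce_associations <- function(fixes, focal, radius, mate = NA) {
  fixes <- as.data.frame(fixes)
  out <- list()
  foc <- fixes[fixes$tag_id == focal, ]
  for (k in seq_len(nrow(foc))) {
    win <- foc$window_index[k]
    others <- fixes[fixes$tag_id != focal & fixes$window_index == win, ]
    for (j in seq_len(nrow(others))) {
      dd <- sqrt((others$x[j] - foc$x[k])^2 + (others$y[j] - foc$y[k])^2)
      if (dd <= radius && !(identical(others$tag_id[j], mate))) {
        out[[length(out) + 1]] <- data.frame(
          partner_id = others$tag_id[j], window_index = win, distance = dd)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(partner_id = character(), window_index = integer(),
                      distance = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$window_index, res$partner_id), ]
}

# Random fix fixture: n_birds random walks over 120 windows in a small arena.
random_fix_fixture <- function(n_birds = 10, n_windows = 120, seed = 1) {
  withr::with_seed(seed, {
    rbindlist(lapply(seq_len(n_birds), function(b) {
      present <- sort(sample(seq_len(n_windows) - 1L,
                             size = round(n_windows * 0.8)))
      data.table(
        tag_id = sprintf("b%02d", b),
        window_index = present,
        t_mid = (present + 0.5) * 30,
        x = cumsum(stats::rnorm(length(present), 0, 4)) + stats::runif(1, 0, 60),
        y = cumsum(stats::rnorm(length(present), 0, 4)) + stats::runif(1, 0, 60)
      )
    }))
  })
}

# Small simulated world shared by localization tests: one bird, default
# radio config unless overridden.
sim_detection_world <- function(noise = 4, seed = 5, t1 = 7200,
                                anchor = c(10, 5), jitter = 0) {
  g <- generate_grid(40, 166, jitter, seed = 1)
  cfg <- world_config(rssi_noise_sd = noise)
  tr <- simulate_track(anchor, cfg, 0, t1, sex = "M", bird_id = "b1",
                       seed = seed)
  det <- simulate_detections(tr, g, cfg, seed = seed + 1)
  list(grid = g, config = cfg, track = tr, detections = det)
}
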