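#' Simulate a territory-anchored movement track
#'
#' Euler discretisation of a bivariate Ornstein-Uhlenbeck process around a
#' territory anchor: `X(t+dt) = X(t) + theta * (mu(t) - X(t)) * dt +
#' sigma * sqrt(dt) * eps`, with `eps` standard bivariate normal. Outside
#' any intrusion response window `mu(t)` is the anchor; during
#' `[t_start, t_end + post_window]` of a supplied scenario, non-focal birds
#' use the sex-dependent shifted anchor (see [intrusion_scenario()]).
#'
#' @param anchor Numeric `c(x, y)` (m): territory centre; also the start
#'   position.
#' @param config A [world_config()].
#' @param t0,t1 Track start/end times (s), `t1 > t0`.
#' @param dt Time step (s); defaults to the beacon period.
#' @param sex `"M"` or `"F"` (drives the scenario response).
#' @param bird_id Bird id recorded in the output (and compared with the
#'   scenario's `focal_id`; the focal keeps its anchor).
#' @param scenario Optional [intrusion_scenario()].
#' @param seed Optional seed.
#'
#' @return `data.table` with columns `bird_id`, `sex`, `t`, `x`, `y`;
#'   strictly increasing `t`.
#' @export
simulate_track <- function(anchor, config, t0 = 0, t1, dt = NULL,
                           sex = "F", bird_id = "bird1", scenario = NULL,
                           seed = NULL) {
  stopifnot(inherits(config, "world_config"),
            "`t1` must exceed `t0`" = t1 > t0)
  if (is.null(dt)) dt <- config$beacon_period
  if (dt <= 0) stop("`dt` must be > 0")
  if (dt >= 1 / config$ou_theta) {
    warning("`dt` >= 1/ou_theta: unstable OU discretisation")
  }
  tracks <- simulate_tracks(
    anchors = matrix(anchor, nrow = 1),
    sexes = sex, bird_ids = bird_id,
    config = config, t0 = t0, t1 = t1, dt = dt,
    scenario = scenario, seed = seed
  )
  tracks[]
}

# Multi-bird OU simulation: one time loop, matrix ops across birds.
# anchors: n x 2 matrix; returns long data.table(bird_id, sex, t, x, y).
simulate_tracks <- function(anchors, sexes, bird_ids, config,
                            t0 = 0, t1, dt = NULL, scenario = NULL,
                            seed = NULL) {
  if (is.null(dt)) dt <- config$beacon_period
  n <- nrow(anchors)
  times <- seq(t0, t1, by = dt)
  nt <- length(times)
  theta <- config$ou_theta
  sig <- config$ou_sigma

  mu_base <- anchors
  mu_shift <- anchors
  in_resp <- rep(FALSE, nt)
  if (!is.null(scenario)) {
    for (i in seq_len(n)) {
      if (!identical(bird_ids[i], scenario$focal_id)) {
        mu_shift[i, ] <- shifted_anchor(anchors[i, ], sexes[i], scenario)
      }
    }
    in_resp <- times >= scenario$t_start &
      times <= scenario$t_end + scenario$post_window
  }

  xs <- matrix(NA_real_, nt, n)
  ys <- matrix(NA_real_, nt, n)
  with_seed_if(seed, {
    X <- anchors
    xs[1, ] <- X[, 1]; ys[1, ] <- X[, 2]
    sdt <- sig * sqrt(dt)
    for (k in seq_len(nt - 1L)) {
      mu <- if (in_resp[k]) mu_shift else mu_base
      X <- X + theta * (mu - X) * dt
      if (sdt > 0) X <- X + matrix(rnorm(2L * n, 0, sdt), n, 2)
      xs[k + 1L, ] <- X[, 1]; ys[k + 1L, ] <- X[, 2]
    }
  })
  out <- data.table(
    bird_id = rep(bird_ids, each = nt),
    sex = rep(sexes, each = nt),
    t = rep(times, times = n),
    x = as.vector(xs), y = as.vector(ys)
  )
  out
}

#' Simulate beacon detections over a receiver grid
#'
#' Emits one tag beacon per `beacon_period` along the track (positions
#' linearly interpolated between track samples). Each node receives a
#' beacon independently with probability logistic in distance (0.5 at
#' `detect_range_50`, scale `detect_slope`), truncated to zero below 1e-6.
#' A received beacon's RSSI is `rssi0 - 10 * path_loss_exponent *
#' log10(d / d0)` plus Gaussian noise. Dropout draws are made before noise
#' draws, so runs that differ only in `rssi_noise_sd` share the same
#' detections and noise shape under the same seed.
#'
#' @param track A track from [simulate_track()] (one bird).
#' @param grid A node grid from [generate_grid()].
#' @param config A [world_config()].
#' @param tag_id Tag id to record; defaults to the track's `bird_id`.
#' @param seed Optional seed.
#'
#' @return `data.table` with columns `tag_id`, `node_id`, `t`, `rssi`.
#' @export
simulate_detections <- function(track, grid, config, tag_id = NULL,
                                seed = NULL) {
  stopifnot(inherits(config, "world_config"))
  if (nrow(grid) == 0L) stop("empty node grid")
  tr <- as.data.table(track)
  t0 <- min(tr$t); t1 <- max(tr$t)
  if (t1 - t0 < config$beacon_period) {
    stop("track must span at least one beacon period")
  }
  if (is.null(tag_id)) {
    tag_id <- if ("bird_id" %in% names(tr)) tr$bird_id[1L] else "tag1"
  }
  bt <- seq(t0, t1, by = config$beacon_period)
  bx <- approx(tr$t, tr$x, xout = bt, rule = 2)$y
  by <- approx(tr$t, tr$y, xout = bt, rule = 2)$y

  nb <- length(bt); nn <- nrow(grid)
  dx <- outer(bx, grid$x, "-")
  dy <- outer(by, grid$y, "-")
  d <- sqrt(dx * dx + dy * dy)                      # nb x nn
  p <- plogis((config$detect_range_50 - d) / config$detect_slope)
  p[p < 1e-6] <- 0                                   # truncation contract
  det <- with_seed_if(seed, {
    hit <- matrix(runif(nb * nn), nb, nn) < p
    idx <- which(hit)
    dd <- pmax(d[idx], 1e-6)
    rssi <- config$rssi0 -
      10 * config$path_loss_exponent * log10(dd / config$d0)
    if (config$rssi_noise_sd > 0) {
      rssi <- rssi + rnorm(length(idx), 0, config$rssi_noise_sd)
    }
    data.table(
      tag_id = tag_id,
      node_id = grid$node_id[((idx - 1L) %/% nb) + 1L],
      t = bt[((idx - 1L) %% nb) + 1L],
      rssi = rssi
    )
  })
  setorder(det, t, node_id)
  det[]
}

#' Default response-variable loading matrix
#'
#' Six observed playback-response variables on two latent factors: the four
#' vocal variables (song overlaps, total songs, songs during playback,
#' singing duration) load on the vocal factor; time near the speaker loads
#' positively and approach latency negatively on the spatial factor.
#'
#' @param strength Common absolute loading (default 0.92; with the default
#'   observation noise this puts ~60% / ~31% of total variance on the two
#'   components, eigenvalues near 3.6 and 1.9).
#' @return A 6 x 2 matrix with dimnames.
#' @export
default_loadings <- function(strength = 0.92) {
  L <- matrix(0, 6, 2, dimnames = list(
    c("n_overlaps", "n_songs_total", "n_songs_during",
      "sing_duration_s", "time_within_5m_s", "latency_s"),
    c("vocal", "spatial")
  ))
  L[1:4, 1] <- strength
  L[5, 2] <- strength
  L[6, 2] <- -strength
  L
}

# Affine maps from standardized latent scale to natural units. Variables
# are kept continuous (latent intensities): rounding/clamping would distort
# the correlation structure the scoring stage is meant to recover.
.response_scale <- data.frame(
  var = c("n_overlaps", "n_songs_total", "n_songs_during",
          "sing_duration_s", "time_within_5m_s", "latency_s"),
  center = c(4, 18, 12, 90, 60, 120),
  scale = c(2.5, 8, 6, 40, 30, 50)
)

#' Simulate a playback response table
#'
#' Generates per-subject latent vocal and spatial response strengths and
#' maps them through a loading matrix to the six observed playback-response
#' variables. The latent vocal strength depends on age class and body
#' condition: `q_vocal = age_effect * older + condition_effect * condition
#' + residual`, with the residual variance chosen so `q_vocal` has unit
#' variance at the defaults. Condition is realised as the residual of a
#' weight-on-tarsus regression (recoverable downstream with
#' [body_condition()]). Defaults give a two-block correlation structure
#' (4 vocal + 2 spatial variables) and a condition-to-vocal-component
#' correlation of about 0.6.
#'
#' @param n_subjects Number of subjects (>= 6). A warning is emitted when
#'   `n_subjects < 18` (fewer than three subjects per variable), the
#'   small-sample regime of a field playback season.
#' @param loadings 6 x 2 matrix (defaults to [default_loadings()]).
#' @param age_effect Latent vocal-strength difference of older birds (sd
#'   units).
#' @param condition_effect Latent effect of one sd of body condition.
#' @param noise_sd Observation noise sd on the standardized scale of each
#'   variable.
#' @param seed Optional seed.
#'
#' @return `data.table` with columns `subject_id`, the six response
#'   variables, `age_class` (`"2cy"`/`"older"`), `weight_g`, `tarsus_mm`,
#'   `exploration` (novel-environment score, independent of the latents).
#'   Attribute `latents`: the true `q_vocal`, `q_spatial`, `condition_z`.
#' @export
simulate_response_table <- function(n_subjects = 14,
                                    loadings = default_loadings(),
                                    age_effect = 0.8,
                                    condition_effect = 0.6,
                                    noise_sd = 0.36, seed = NULL) {
  if (n_subjects < 6) stop("`n_subjects` must be at least 6")
  if (!is.matrix(loadings) || !all(dim(loadings) == c(6L, 2L))) {
    stop("`loadings` must be a 6 x 2 matrix")
  }
  if (n_subjects < 18) {
    warning("fewer than 3 subjects per response variable; ",
            "component retention will be fragile")
  }
  n <- as.integer(n_subjects)
  with_seed_if(seed, {
    age01 <- rbinom(n, 1L, 0.5)
    cond_z <- rnorm(n)
    resid_var <- max(0, 1 - age_effect^2 / 4 - condition_effect^2)
    q_vocal <- age_effect * age01 + condition_effect * cond_z +
      rnorm(n, 0, sqrt(resid_var))
    q_spatial <- rnorm(n)
    Z <- cbind(q_vocal, q_spatial) %*% t(loadings) +
      matrix(rnorm(n * 6L, 0, noise_sd), n, 6L)
    tarsus <- rnorm(n, 19.5, 0.8)
    weight <- -0.5 + 0.95 * tarsus + 0.55 * cond_z
    out <- data.table(subject_id = sprintf("s%03d", seq_len(n)))
    for (j in seq_len(6L)) {
      set(out, j = .response_scale$var[j],
          value = .response_scale$center[j] + .response_scale$scale[j] * Z[, j])
    }
    out[, `:=`(
      age_class = ifelse(age01 == 1L, "older", "2cy"),
      weight_g = weight, tarsus_mm = tarsus,
      exploration = rnorm(n)
    )]
    setattr(out, "latents", data.table(
      subject_id = out$subject_id,
      q_vocal = q_vocal, q_spatial = q_spatial, condition_z = cond_z
    ))
    out[]
  })
}
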