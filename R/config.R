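#' World and radio-model configuration
#'
#' Bundles the parameters of the synthetic world: colony composition,
#' territory-anchored Ornstein-Uhlenbeck (OU) movement, tag beacon rate, and
#' the log-distance path-loss radio model with logistic detection.
#'
#' Movement defaults give a stationary territory "cloud" with per-axis
#' standard deviation `ou_sigma / sqrt(2 * ou_theta)` (about 30 m) and a
#' mean-reversion time scale `1 / ou_theta` of 5 minutes. Radio defaults:
#' -40 dB at the 1-m reference distance, path-loss exponent 2.5, 4 dB
#' i.i.d. Gaussian RSSI noise, 50% detection probability at 80 m with a
#' 10-m logistic scale, beacons every 5 s.
#'
#' @param n_males,n_females Colony composition.
#' @param beacon_period Tag beacon interval (s).
#' @param ou_theta OU mean-reversion rate (1/s), > 0.
#' @param ou_sigma OU diffusion (m/sqrt(s)), >= 0.
#' @param rssi0 RSSI (dB) at the reference distance `d0`.
#' @param d0 Reference distance (m) of the path-loss model.
#' @param path_loss_exponent Path-loss exponent (dimensionless), > 0.
#' @param rssi_noise_sd Gaussian RSSI noise standard deviation (dB), >= 0.
#' @param detect_range_50 Distance (m) at which detection probability is 0.5.
#' @param detect_slope Logistic scale (m) of the detection-probability curve.
#' @param seed Optional default seed carried with the config.
#'
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_males = 21, n_females = 23,
                         beacon_period = 5,
                         ou_theta = 1 / 300, ou_sigma = 2.45,
                         rssi0 = -40, d0 = 1, path_loss_exponent = 2.5,
                         rssi_noise_sd = 4,
                         detect_range_50 = 80, detect_slope = 10,
                         seed = NULL) {
  cfg <- list(
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    beacon_period = beacon_period,
    ou_theta = ou_theta, ou_sigma = ou_sigma,
    rssi0 = rssi0, d0 = d0, path_loss_exponent = path_loss_exponent,
    rssi_noise_sd = rssi_noise_sd,
    detect_range_50 = detect_range_50, detect_slope = detect_slope,
    seed = seed
  )
  stopifnot(
    "`ou_theta` must be > 0" = ou_theta > 0,
    "`ou_sigma` must be >= 0" = ou_sigma >= 0,
    "`beacon_period` must be > 0" = beacon_period > 0,
    "`path_loss_exponent` must be > 0" = path_loss_exponent > 0,
    "`rssi_noise_sd` must be >= 0" = rssi_noise_sd >= 0,
    "`d0` must be > 0" = d0 > 0,
    "`detect_range_50` must be > 0" = detect_range_50 > 0,
    "`detect_slope` must be > 0" = detect_slope > 0
  )
  structure(cfg, class = "world_config")
}

#' Territory-intrusion scenario
#'
#' Describes one simulated intrusion: where and when song is broadcast in
#' the focal male's territory, the focal's standardized vocal-response
#' score, and the sex-dependent anchor shifts it induces in neighbours.
#' During `[t_start, t_end + post_window]`, every non-focal bird's movement
#' anchor is displaced along its anchor-to-site axis by
#' `-shift * vocal_score` metres toward the site, where `shift` is
#' `attract_female` for females and `repel_male` for males: a negative
#' parameter therefore attracts (moves the anchor toward the site) for
#' positive vocal scores, a positive parameter repels. Displacement is
#' clamped so an anchor never overshoots the site.
#'
#' @param focal_id Bird id of the challenged territory owner.
#' @param site Numeric `c(x, y)` (m): playback location.
#' @param t_start,t_end Intrusion (playback) start/stop times (s),
#'   `t_end > t_start`.
#' @param vocal_score Standardized vocal-response score of the focal male.
#' @param attract_female Anchor-shift magnitude (m per unit vocal score) for
#'   females; negative = toward the site. Default -20.
#' @param repel_male Same for males; positive = away. Default 15.
#' @param post_window Duration (s) after `t_end` for which the shift
#'   persists (default 3600, the post-intrusion observation hour).
#'
#' @return A list of class `intrusion_scenario`.
#' @export
intrusion_scenario <- function(focal_id, site, t_start, t_end,
                               vocal_score = 0,
                               attract_female = -20, repel_male = 15,
                               post_window = 3600) {
  stopifnot(
    "`site` must be c(x, y)" = is.numeric(site) && length(site) == 2L,
    "`t_end` must exceed `t_start`" = t_end > t_start,
    "shift magnitudes must be finite" =
      is.finite(attract_female) && is.finite(repel_male),
    "`vocal_score` must be finite" = is.finite(vocal_score)
  )
  structure(list(
    focal_id = focal_id, site = as.numeric(site),
    t_start = t_start, t_end = t_end,
    vocal_score = vocal_score,
    attract_female = attract_female, repel_male = repel_male,
    post_window = post_window
  ), class = "intrusion_scenario")
}

# Shifted anchor for one bird under a scenario (identity for the focal or
# when no scenario applies). anchor, site: length-2 numerics.
shifted_anchor <- function(anchor, sex, scenario) {
  if (is.null(scenario)) return(anchor)
  shift <- if (identical(sex, "F")) scenario$attract_female else
    scenario$repel_male
  towards <- -shift * scenario$vocal_score   # metres moved toward the site
  v <- scenario$site - anchor
  len <- sqrt(sum(v^2))
  if (len < 1e-9) return(anchor)
  towards <- min(towards, len)               # never overshoot the site
  anchor + v / len * towards
}
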