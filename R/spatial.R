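#' Pre/post observation windows around an intrusion
#'
#' The pre window is the hour directly before playback start, half-open
#' `[t_start - duration, t_start)`; the post window is the hour directly
#' after playback end, `(t_end, t_end + duration]`. The playback itself
#' belongs to neither.
#'
#' @param t_start,t_end Playback start/stop (s).
#' @param duration Window length (s), default 3600.
#' @return List of class `trial_windows` with elements `pre`, `post`
#'   (each `c(from, to)` with a `bounds` attribute `"[)"` or `"(]"`).
#' @export
trial_windows <- function(t_start, t_end, duration = 3600) {
  stopifnot(t_end > t_start, duration > 0)
  pre <- structure(c(t_start - duration, t_start), bounds = "[)")
  post <- structure(c(t_end, t_end + duration), bounds = "(]")
  structure(list(pre = pre, post = post, duration = duration),
            class = "trial_windows")
}

# logical index of times inside a window honouring its bounds convention
.in_window <- function(t, window) {
  b <- attr(window, "bounds")
  if (identical(b, "(]")) t > window[1] & t <= window[2]
  else t >= window[1] & t < window[2]
}

#' Minimum approach distance to a site within a window
#'
#' Minimum Euclidean distance of a bird's fixes (by `t_mid`) to the
#' intrusion site within the window; `NA` when the bird has no fixes there.
#'
#' @param track Fix table for one bird (columns `t_mid`, `x`, `y`).
#' @param site Numeric `c(x, y)` (m).
#' @param window One element of [trial_windows()].
#' @return Distance (m), or `NA_real_`.
#' @export
min_approach_distance <- function(track, site, window) {
  tr <- as.data.table(track)
  keep <- .in_window(tr$t_mid, window)
  if (!any(keep)) return(NA_real_)
  min(sqrt((tr$x[keep] - site[1])^2 + (tr$y[keep] - site[2])^2))
}

#' Pre/post closest-neighbour distance change, per conspecific sex
#'
#' For each conspecific sex, the pre value is the minimum over that sex's
#' non-focal birds of their minimum approach distance to the intrusion site
#' in the pre window; the post value is the analogous minimum in the post
#' window (the closest individual may differ between windows). `delta =
#' post - pre`; negative delta means conspecifics came closer. A record is
#' flagged incomplete when either window holds no fixes for that sex.
#'
#' @param fixes Fix table for all birds (`tag_id`, `t_mid`, `x`, `y`).
#' @param manifest Bird table with `bird_id`, `sex`.
#' @param trial List with `focal_id`, `site`, `t_start`, `t_end` (and
#'   optionally `windows`, a [trial_windows()]).
#' @return `data.table`: `focal_id`, `conspecific_sex`, `min_dist_pre`,
#'   `min_dist_post`, `delta_min_dist`, `incomplete`.
#' @export
closest_neighbor_delta <- function(fixes, manifest, trial) {
  man <- as.data.table(manifest)
  fx <- as.data.table(fixes)
  wins <- trial$windows
  if (is.null(wins)) wins <- trial_windows(trial$t_start, trial$t_end)
  out <- lapply(c("M", "F"), function(s) {
    cand <- setdiff(man[sex == s, bird_id], trial$focal_id)
    vals <- lapply(list(wins$pre, wins$post), function(wnd) {
      dd <- vapply(cand, function(b) {
        min_approach_distance(fx[tag_id == b], trial$site, wnd)
      }, numeric(1))
      if (all(is.na(dd))) NA_real_ else min(dd, na.rm = TRUE)
    })
    data.table(
      focal_id = trial$focal_id, conspecific_sex = s,
      min_dist_pre = vals[[1]], min_dist_post = vals[[2]],
      delta_min_dist = vals[[2]] - vals[[1]],
      incomplete = is.na(vals[[1]]) || is.na(vals[[2]])
    )
  })
  rbindlist(out)
}

#' Close-range association events of a focal bird
#'
#' One event per (partner, half-minute window) in which both the focal and
#' the partner have a fix in the same window inside the observation window
#' and the inter-fix distance is at most `radius`. The focal's mate (from
#' `manifest$mate_id`) is excluded from the partners, mirroring the
#' exclusion of mates from female associates.
#'
#' @param fixes Fix table for all birds.
#' @param focal_id Focal bird id.
#' @param window One element of [trial_windows()].
#' @param radius Association radius (m), default 10.
#' @param manifest Optional bird table with `bird_id`, `sex`, `mate_id`
#'   (used for mate exclusion and partner sex).
#' @return `data.table`: `focal_id`, `partner_id`, `partner_sex` (`NA` when
#'   no manifest), `window_index`, `distance`.
#' @export
build_associations <- function(fixes, focal_id, window, radius = 10,
                               manifest = NULL) {
  if (radius <= 0) stop("`radius` must be > 0")
  fx <- as.data.table(fixes)
  fx <- fx[.in_window(t_mid, window)]
  foc <- fx[tag_id == focal_id, .(window_index, fx_ = x, fy_ = y)]
  oth <- fx[tag_id != focal_id,
            .(partner_id = tag_id, window_index, x, y)]
  ev <- merge(oth, foc, by = "window_index", allow.cartesian = TRUE)
  ev[, distance := sqrt((x - fx_)^2 + (y - fy_)^2)]
  ev <- ev[distance <= radius]
  ev[, `:=`(focal_id = focal_id, partner_sex = NA_character_)]
  if (!is.null(manifest)) {
    man <- as.data.table(manifest)
    mate <- man[bird_id == focal_id, mate_id]
    if (length(mate) == 1L && !is.na(mate)) ev <- ev[partner_id != mate]
    ev[, partner_sex := man$sex[match(partner_id, man$bird_id)]]
  }
  out <- ev[, .(focal_id, partner_id, partner_sex, window_index, distance)]
  setorder(out, window_index, partner_id)
  out[]
}

#' Summarise an association-event list
#'
#' Per partner sex: the number of unique associates and the average
#' association time, where each co-located half-minute window credits
#' `window_s` seconds and the average is total time divided by the number
#' of unique partners. Zero partners gives `NA` (missing), not 0 seconds.
#'
#' @param events Events from [build_associations()] (one focal, one
#'   observation window).
#' @param window_s Fix window length (s), default 30.
#' @return `data.table`: `partner_sex` (`"M"`, `"F"`), `n_associates`,
#'   `total_time`, `mean_assoc_time` (s).
#' @export
association_summary <- function(events, window_s = 30) {
  ev <- as.data.table(events)
  out <- rbindlist(lapply(c("M", "F"), function(s) {
    sub <- ev[partner_sex == s]
    n <- uniqueN(sub$partner_id)
    tot <- nrow(sub) * window_s
    data.table(partner_sex = s, n_associates = n,
               total_time = tot,
               mean_assoc_time = if (n > 0L) tot / n else NA_real_)
  }))
  out[]
}

#' Neighbourhood response table for a set of trials
#'
#' Combines, per focal trial and conspecific sex, the pre/post closest
#' neighbour distances ([closest_neighbor_delta()]) and the pre/post
#' proximity-network summaries ([build_associations()] +
#' [association_summary()]) into the long outcome table the mixed models
#' consume.
#'
#' @param fixes Fix table for all birds over the trial period.
#' @param manifest Bird table (`bird_id`, `sex`, `mate_id`).
#' @param trials List of trials (each with `focal_id`, `site`, `t_start`,
#'   `t_end`).
#' @param radius Association radius (m), default 10.
#' @param window_s Fix window length (s), default 30.
#' @return `data.table`, two rows (conspecific sexes) per trial, with
#'   distance deltas, associate counts and mean association times pre/post
#'   plus their deltas.
#' @export
neighbor_response <- function(fixes, manifest, trials, radius = 10,
                              window_s = 30) {
  res <- lapply(trials, function(tr) {
    wins <- trial_windows(tr$t_start, tr$t_end)
    dd <- closest_neighbor_delta(fixes, manifest, c(tr, list(windows = wins)))
    pre_ev <- build_associations(fixes, tr$focal_id, wins$pre, radius,
                                 manifest)
    post_ev <- build_associations(fixes, tr$focal_id, wins$post, radius,
                                  manifest)
    pre_s <- association_summary(pre_ev, window_s)
    post_s <- association_summary(post_ev, window_s)
    m <- merge(pre_s, post_s, by = "partner_sex",
               suffixes = c("_pre", "_post"))
    m <- m[, .(conspecific_sex = partner_sex,
               n_assoc_pre = n_associates_pre,
               n_assoc_post = n_associates_post,
               delta_n_assoc = n_associates_post - n_associates_pre,
               mean_time_pre = mean_assoc_time_pre,
               mean_time_post = mean_assoc_time_post,
               delta_mean_time = mean_assoc_time_post -
                 mean_assoc_time_pre)]
    merge(dd, m, by = "conspecific_sex")
  })
  out <- rbindlist(res)
  setcolorder(out, c("focal_id", "conspecific_sex"))
  setorder(out, focal_id, conspecific_sex)
  out[]
}
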