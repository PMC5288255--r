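#' Pipeline configuration with field-study defaults
#'
#' Nested configuration validated against the known schema; unknown keys
#' are errors (typos never pass silently). Defaults reproduce the study
#' constants: 40-m triangular grid of 166 nodes, 5-s beacons, 30-s fix
#' windows, 10-m association radius, 60-min pre/post windows, playback of
#' about two minutes starting one hour into each trial's time base.
#'
#' @param world Overrides for [world_config()] fields.
#' @param grid Overrides: `spacing`, `n_nodes`, `jitter_sd`.
#' @param trial Overrides: `t_start`, `playback_s`, `window_s`, `radius`,
#'   `duration` (pre/post length), `sim_radius` (simulate birds anchored
#'   within this distance of a site), `attract_female`, `repel_male`.
#' @param analysis Overrides: `gate_p`.
#' @param n_subjects Number of focal males with playback trials.
#' @param seed Default seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(world = list(), grid = list(), trial = list(),
                            analysis = list(), n_subjects = 13,
                            seed = 1L) {
  defaults <- list(
    grid = list(spacing = 40, n_nodes = 166, jitter_sd = 4),
    trial = list(t_start = 3600, playback_s = 127, window_s = 30,
                 radius = 10, duration = 3600, sim_radius = 250,
                 attract_female = -20, repel_male = 15),
    analysis = list(gate_p = 0.05)
  )
  check_keys <- function(given, known, where) {
    bad <- setdiff(names(given), names(known))
    if (length(bad)) {
      stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
    }
  }
  check_keys(world, formals(world_config), "world")
  check_keys(grid, defaults$grid, "grid")
  check_keys(trial, defaults$trial, "trial")
  check_keys(analysis, defaults$analysis, "analysis")
  cfg <- list(
    world = do.call(world_config, world),
    grid = utils::modifyList(defaults$grid, grid),
    trial = utils::modifyList(defaults$trial, trial),
    analysis = utils::modifyList(defaults$analysis, analysis),
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' Simulate a colony manifest
#'
#' Places territory anchors uniformly over the grid area (inset by half a
#' spacing), assigns sexes, biometrics, age classes and exploration scores,
#' and pairs each male with the nearest still-unpaired female as its mate.
#'
#' @param grid Node grid.
#' @param config [world_config()] (colony sizes).
#' @param seed Optional seed.
#' @return `data.table`: `bird_id`, `sex`, `age_class`, `weight_g`,
#'   `tarsus_mm`, `exploration`, `mate_id`, `anchor_x`, `anchor_y`.
#' @export
simulate_manifest <- function(grid, config, seed = NULL) {
  n <- config$n_males + config$n_females
  b <- grid_bounds(grid, expand = -attr(grid, "spacing") / 2)
  with_seed_if(seed, {
    man <- data.table(
      bird_id = c(sprintf("m%03d", seq_len(config$n_males)),
                  sprintf("f%03d", seq_len(config$n_females))),
      sex = rep(c("M", "F"), c(config$n_males, config$n_females)),
      age_class = sample(c("2cy", "older"), n, replace = TRUE),
      tarsus_mm = rnorm(n, 19.5, 0.8),
      exploration = rnorm(n),
      anchor_x = runif(n, b[1], b[3]),
      anchor_y = runif(n, b[2], b[4])
    )
    man[, weight_g := -0.5 + 0.95 * tarsus_mm + 0.55 * rnorm(n)]
    man[, mate_id := NA_character_]
    females <- man[sex == "F"]
    taken <- character()
    for (m in man[sex == "M", bird_id]) {
      free <- females[!bird_id %in% taken]
      if (nrow(free) == 0L) break
      mx <- man[bird_id == m]
      dd <- sqrt((free$anchor_x - mx$anchor_x)^2 +
                   (free$anchor_y - mx$anchor_y)^2)
      mate <- free$bird_id[which.min(dd)]
      man[bird_id == m, mate_id := mate]
      man[bird_id == mate, mate_id := m]
      taken <- c(taken, mate)
    }
    man[]
  })
}

# Simulate movement + detections for one trial: all birds anchored within
# sim_radius of the site (the focal always included), over [0, t_max].
simulate_trial_detections <- function(manifest, grid, config, scenario,
                                      sim_radius = 250, t_max = NULL,
                                      seed = NULL) {
  man <- as.data.table(manifest)
  if (is.null(t_max)) {
    t_max <- scenario$t_end + scenario$post_window + 40
  }
  dd <- sqrt((man$anchor_x - scenario$site[1])^2 +
               (man$anchor_y - scenario$site[2])^2)
  keep <- dd <= sim_radius | man$bird_id == scenario$focal_id
  sub <- man[keep]
  with_seed_if(seed, {
    tracks <- simulate_tracks(
      anchors = cbind(sub$anchor_x, sub$anchor_y),
      sexes = sub$sex, bird_ids = sub$bird_id,
      config = config, t0 = 0, t1 = t_max,
      scenario = scenario, seed = NULL
    )
    det <- rbindlist(lapply(split(tracks, by = "bird_id"), function(tr) {
      simulate_detections(tr, grid, config, tag_id = tr$bird_id[1],
                          seed = NULL)
    }))
    list(tracks = tracks, detections = det, birds = sub$bird_id)
  })
}

#' Simulate and analyse a full intrusion study
#'
#' The in-memory end-to-end chain: grid, colony manifest, playback-response
#' table for the focal males, component scoring, then one simulated
#' intrusion trial per focal male (territory-anchored movement with the
#' sex-dependent response shift scaled by the focal's vocal score, beacon
#' detections, multilateration to half-minute fixes, neighbourhood
#' metrics), and finally the sex-interaction mixed models.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed (defaults to the config's).
#' @param keep_tracks Keep true tracks per trial (for localization error
#'   checks); default FALSE to save memory.
#' @return List: `grid`, `manifest`, `responses`, `scored`, `pca`,
#'   `trials`, `fixes` (per-trial fix tables, rbind-ed, with `trial_id`),
#'   `neighbor` (outcome table with `pc1_vocal` merged in), `models`,
#'   `tracks` (optional).
#' @export
simulate_study <- function(config = pipeline_config(), seed = NULL,
                           keep_tracks = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed) %% 1000000L
  grid <- generate_grid(config$grid$spacing, config$grid$n_nodes,
                        config$grid$jitter_sd, seed = seed)
  manifest <- simulate_manifest(grid, config$world, seed = seed + 1L)
  n_sub <- min(config$n_subjects, config$world$n_males)
  focals <- manifest[sex == "M"][seq_len(n_sub), bird_id]

  responses <- simulate_response_table(n_subjects = max(7L, n_sub),
                                       seed = seed + 2L)
  responses <- responses[seq_len(n_sub)]
  responses[, subject_id := focals]
  scoring <- score_responses(responses)
  scored <- scoring$scored

  tw <- config$trial
  trials <- lapply(seq_len(n_sub), function(i) {
    f <- focals[i]
    anc <- manifest[bird_id == f]
    list(focal_id = f, site = c(anc$anchor_x, anc$anchor_y),
         t_start = tw$t_start, t_end = tw$t_start + tw$playback_s,
         vocal_score = scored[subject_id == f, pc1_vocal])
  })

  fixes_all <- vector("list", n_sub)
  tracks_all <- if (keep_tracks) vector("list", n_sub) else NULL
  neighbor <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    tr <- trials[[i]]
    sc <- intrusion_scenario(
      focal_id = tr$focal_id, site = tr$site,
      t_start = tr$t_start, t_end = tr$t_end,
      vocal_score = tr$vocal_score,
      attract_female = tw$attract_female, repel_male = tw$repel_male,
      post_window = tw$duration
    )
    sim <- simulate_trial_detections(manifest, grid, config$world, sc,
                                     sim_radius = tw$sim_radius,
                                     seed = seed + 100L + i)
    wsum <- window_detections(sim$detections, tw$window_s)
    fixes <- estimate_positions(wsum, grid, config$world, tw$window_s)
    fixes[, trial_id := tr$focal_id]
    fixes_all[[i]] <- fixes
    if (keep_tracks) {
      sim$tracks[, trial_id := tr$focal_id]
      tracks_all[[i]] <- sim$tracks
    }
    neighbor[[i]] <- neighbor_response(fixes, manifest, list(tr),
                                       radius = tw$radius,
                                       window_s = tw$window_s)
  }
  neighbor <- rbindlist(neighbor)
  neighbor <- merge(neighbor,
                    scored[, .(focal_id = subject_id, pc1_vocal)],
                    by = "focal_id")
  models <- analyze_neighborhood(neighbor, scored,
                                 gate_p = config$analysis$gate_p)
  out <- list(grid = grid, manifest = manifest, responses = responses,
              scored = scored, pca = scoring$pca, trials = trials,
              fixes = rbindlist(fixes_all), neighbor = neighbor,
              models = models)
  if (keep_tracks) out$tracks <- rbindlist(tracks_all)
  out
}

#' Sex-interaction models over the neighbourhood outcomes
#'
#' Fits the three outcome models (change in closest-neighbour minimum
#' distance, change in associate counts, rank-transformed change in mean
#' association time) against the main vocal score, with the likelihood-
#' ratio interaction test. When the minimum-distance interaction passes the
#' gate, the four specific vocal variables are tested in turn and per-sex
#' post hoc contrasts are reported for significant interactions.
#'
#' @param neighbor Outcome table from [neighbor_response()] with
#'   `pc1_vocal` merged per focal (column per subject).
#' @param scored Scored subject table (for the specific vocal variables).
#' @param gate_p Gate for specific-variable testing (default 0.05).
#' @return List: `min_dist`, `n_assoc`, `assoc_time` (interaction fits),
#'   `specific` (per-variable fits + post hocs, when gated in).
#' @export
analyze_neighborhood <- function(neighbor, scored, gate_p = 0.05) {
  nb <- as.data.table(neighbor)
  nb[, subject_id := focal_id]
  nb[, rank_delta_mean_time := rank_transform(delta_mean_time)]
  try_fit <- function(outcome, predictor) {
    tryCatch(fit_sex_interaction(nb, outcome, predictor),
             error = function(e) {
               message("model on ", outcome, " not fitted: ",
                       conditionMessage(e))
               NULL
             })
  }
  fits <- list(
    min_dist = fit_sex_interaction(nb, "delta_min_dist", "pc1_vocal"),
    n_assoc = try_fit("delta_n_assoc", "pc1_vocal"),
    assoc_time = try_fit("rank_delta_mean_time", "pc1_vocal")
  )
  fits$specific <- list()
  if (fits$min_dist$lrt_p < gate_p) {
    vars <- c("n_overlaps", "n_songs_total", "n_songs_during",
              "sing_duration_s")
    sc <- as.data.table(scored)
    for (v in vars) {
      nb2 <- merge(nb, sc[, c("subject_id", v), with = FALSE],
                   by = "subject_id")
      f <- fit_sex_interaction(nb2, "delta_min_dist", v)
      ph <- if (f$lrt_p < gate_p) posthoc_by_sex(f, gate_p) else NULL
      fits$specific[[v]] <- list(fit = f, posthoc = ph)
    }
  }
  fits
}

#' Run the pipeline and write its artifacts
#'
#' End-to-end run of [simulate_study()] with all tables written to
#' `out_dir`: `nodes.csv`, `manifest.csv`, `responses.csv`, `scored.csv`,
#' `fixes.csv`, `neighbor_response.csv`, `results.json` (model estimates,
#' LRTs, post hocs, PCA diagnostics) and `report.md`. Identical config and
#' seed give byte-identical `results.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (defaults to the config's).
#' @param verbose Log per-stage row counts.
#' @return Invisibly, the [simulate_study()] result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL,
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (verbose) message("[intrunet] ", ...)
  log_("seed = ", if (is.null(seed)) config$seed else seed,
       "; subjects = ", config$n_subjects)
  res <- simulate_study(config, seed = seed)
  wr <- function(x, f) {
    fwrite(x, file.path(out_dir, f))
    log_(f, ": ", nrow(x), " rows")
  }
  wr(res$grid, "nodes.csv")
  wr(res$manifest, "manifest.csv")
  wr(res$responses, "responses.csv")
  wr(res$scored, "scored.csv")
  wr(res$fixes, "fixes.csv")
  wr(res$neighbor, "neighbor_response.csv")
  fit_json <- function(f) if (is.null(f)) NULL else list(
    outcome = f$outcome, predictor = f$predictor,
    estimates = f$estimates, lrt_chi2 = f$lrt_chi2, lrt_p = f$lrt_p,
    n_obs = f$n_obs, n_groups = f$n_groups, singular = f$singular
  )
  results <- list(
    pca = list(eigenvalues = res$pca$eigenvalues,
               variance_explained = res$pca$variance_explained,
               k = res$pca$k, kmo = res$pca$kmo,
               bartlett = res$pca$bartlett,
               loadings = as.data.frame(res$pca$loadings)),
    models = list(
      min_dist = fit_json(res$models$min_dist),
      n_assoc = fit_json(res$models$n_assoc),
      assoc_time = fit_json(res$models$assoc_time),
      specific = lapply(res$models$specific, function(s) {
        c(fit_json(s$fit), list(posthoc = s$posthoc))
      })
    )
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  report <- c(
    "# Intrusion-response pipeline report", "",
    sprintf("Subjects: %d; grid: %d nodes; fixes: %d",
            config$n_subjects, nrow(res$grid), nrow(res$fixes)),
    "",
    sprintf("Retained components: %d (KMO %.2f, Bartlett p %.2g)",
            res$pca$k, res$pca$kmo, res$pca$bartlett$p_value),
    "",
    sprintf("sex x vocal on delta min distance: chi2(1) = %.2f, p = %.3g",
            res$models$min_dist$lrt_chi2, res$models$min_dist$lrt_p),
    sprintf("sex x vocal on delta associates: chi2(1) = %.2f, p = %.3g",
            res$models$n_assoc$lrt_chi2, res$models$n_assoc$lrt_p),
    sprintf("sex x vocal on rank delta association time: chi2(1) = %.2f, p = %.3g",
            res$models$assoc_time$lrt_chi2, res$models$assoc_time$lrt_p)
  )
  writeLines(report, file.path(out_dir, "report.md"))
  log_("results.json, report.md written")
  invisible(res)
}
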