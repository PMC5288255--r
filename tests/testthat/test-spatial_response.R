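make_fix <- function(tag, win, x, y) {
  data.table::data.table(tag_id = tag, window_index = as.integer(win),
                         t_mid = (win + 0.5) * 30, x = x, y = y)
}

test_that("trial windows are adjacent hours excluding the playback", {
  tw <- trial_windows(3600, 3727)
  expect_equal(unclass(tw$pre), c(0, 3600), ignore_attr = TRUE)
  expect_equal(unclass(tw$post), c(3727, 7327), ignore_attr = TRUE)
  # half-open conventions: playback start not in pre, end not in post
  expect_false(intrunet:::.in_window(3600, tw$pre))
  expect_true(intrunet:::.in_window(0, tw$pre))
  expect_false(intrunet:::.in_window(3727, tw$post))
  expect_true(intrunet:::.in_window(7327, tw$post))
  expect_error(trial_windows(100, 50))
})

test_that("minimum approach distance is the minimum over in-window fixes", {
  tw <- trial_windows(3600, 3727)
  site <- c(0, 0)
  f1 <- make_fix("a", 10, 0, 0)
  expect_equal(min_approach_distance(f1, site, tw$pre), 0)
  f2 <- make_fix("a", c(10, 20, 30), c(120, 85, 240), 0)
  expect_equal(min_approach_distance(f2, site, tw$pre), 85)
  expect_true(is.na(min_approach_distance(f2, site, tw$post)))

  # equals a brute-force scan on a random fixture
  fx <- random_fix_fixture(3, 120, seed = 4)
  d_all <- sqrt(fx$x^2 + fx$y^2)
  keep <- fx$t_mid < 3600 & fx$tag_id == "b01"
  expect_equal(min_approach_distance(fx[fx$tag_id == "b01"], site, tw$pre),
               min(d_all[keep]))
})

test_that("closest-neighbour deltas pick the per-window closest bird of each sex", {
  man <- data.table::data.table(
    bird_id = c("foc", "f1", "m1"), sex = c("M", "F", "M"),
    mate_id = NA_character_)
  trial <- list(focal_id = "foc", site = c(0, 0), t_start = 3600,
                t_end = 3727)
  fixes <- rbind(make_fix("f1", 10, 100, 0), make_fix("f1", 150, 60, 0),
                 make_fix("m1", 10, 50, 0), make_fix("m1", 150, 90, 0))
  dd <- closest_neighbor_delta(fixes, man, trial)
  expect_equal(dd[conspecific_sex == "F", delta_min_dist], -40)
  expect_equal(dd[conspecific_sex == "M", delta_min_dist], 40)
  expect_false(any(dd$incomplete))

  # identical pre/post tracks: delta 0
  fixes2 <- rbind(make_fix("f1", 10, 70, 0), make_fix("f1", 150, 70, 0))
  d2 <- closest_neighbor_delta(fixes2, man, trial)
  expect_equal(d2[conspecific_sex == "F", delta_min_dist], 0)
  expect_true(d2[conspecific_sex == "M", incomplete])

  # focal is never its own neighbour
  fixes3 <- rbind(fixes, make_fix("foc", 10, 1, 0), make_fix("foc", 150, 1, 0))
  d3 <- closest_neighbor_delta(fixes3, man, trial)
  expect_equal(d3[conspecific_sex == "M", min_dist_pre], 50)
})

test_that("association events respect the 10-m threshold and mate exclusion", {
  tw <- trial_windows(3600, 3727)
  man <- data.table::data.table(
    bird_id = c("foc", "f1", "f2", "m1"), sex = c("M", "F", "F", "M"),
    mate_id = c("f2", NA, "foc", NA))
  near <- rbind(make_fix("foc", 5, 0, 0), make_fix("f1", 5, 9.9, 0))
  expect_equal(nrow(build_associations(near, "foc", tw$pre, 10, man)), 1L)
  far <- rbind(make_fix("foc", 5, 0, 0), make_fix("f1", 5, 10.1, 0))
  expect_equal(nrow(build_associations(far, "foc", tw$pre, 10, man)), 0L)

  # same pair in 4 windows: 4 events, 1 unique partner
  multi <- rbind(make_fix("foc", 1:4, 0, 0), make_fix("f1", 1:4, 5, 0))
  ev <- build_associations(multi, "foc", tw$pre, 10, man)
  expect_equal(nrow(ev), 4L)
  expect_equal(length(unique(ev$partner_id)), 1L)

  # the focal's mate is excluded even when within radius
  with_mate <- rbind(multi, make_fix("f2", 1:4, -5, 0))
  ev2 <- build_associations(with_mate, "foc", tw$pre, 10, man)
  expect_false("f2" %in% ev2$partner_id)

  expect_error(build_associations(multi, "foc", tw$pre, 0, man), "radius")
})

test_that("association summary credits 30 s per co-located window", {
  tw <- trial_windows(3600, 3727)
  man <- data.table::data.table(
    bird_id = c("foc", "f1", "f2", "f3"), sex = c("M", "F", "F", "F"),
    mate_id = NA_character_)
  # 3 partners, 10 total co-located windows -> 300 s total, mean 100 s
  fixes <- rbind(
    make_fix("foc", 0:9, 0, 0),
    make_fix("f1", 0:4, 3, 0), make_fix("f2", 0:3, -3, 0),
    make_fix("f3", 0, 0, 3))
  ev <- build_associations(fixes, "foc", tw$pre, 10, man)
  s <- association_summary(ev)
  expect_equal(s[partner_sex == "F", total_time], 300)
  expect_equal(s[partner_sex == "F", n_associates], 3L)
  expect_equal(s[partner_sex == "F", mean_assoc_time], 100)
  # zero partners of a sex: count 0, mean missing (not 0)
  expect_equal(s[partner_sex == "M", n_associates], 0L)
  expect_true(is.na(s[partner_sex == "M", mean_assoc_time]))
})

test_that("associations match a brute-force enumeration and are symmetric", {
  tw <- trial_windows(3600, 3727)
  for (s in 1:5) {
    fx <- random_fix_fixture(6, 120, seed = s)
    man <- data.table::data.table(
      bird_id = sprintf("b%02d", 1:6),
      sex = rep(c("M", "F"), 3), mate_id = NA_character_)
    ev <- build_associations(fx, "b01", tw$pre, 10, man)
    bf <- bruteforce_associations(fx, "b01", 10)
    expect_equal(nrow(ev), nrow(bf))
    if (nrow(ev)) {
      expect_equal(ev$partner_id, bf$partner_id)
      expect_equal(ev$distance, bf$distance, tolerance = 1e-12)
    }
    # symmetry before mate exclusion: A in B's list iff B in A's
    ev2 <- build_associations(fx, "b02", tw$pre, 10, man)
    a_b <- ev[partner_id == "b02", window_index]
    b_a <- ev2[partner_id == "b01", window_index]
    expect_equal(sort(a_b), sort(b_a))
  }
})

test_that("injected sex-dependent shifts are recovered as opposite-signed deltas", {
  g <- generate_grid(40, 60, 0, seed = 1)
  cfg <- world_config(ou_theta = 1 / 100, ou_sigma = 3)
  man <- data.table::data.table(
    bird_id = c("foc", "f1", "m1"), sex = c("M", "F", "M"),
    mate_id = NA_character_)
  deltasF <- deltasM <- numeric(20)
  for (s in 1:20) {
    sc <- intrusion_scenario("foc", c(0, 0), 1800, 1900, vocal_score = 1.5,
                             attract_female = -20, repel_male = 15,
                             post_window = 1800)
    trF <- simulate_track(c(80, 0), cfg, 0, 3800, sex = "F", bird_id = "f1",
                          scenario = sc, seed = 1000 + s)
    trM <- simulate_track(c(-80, 0), cfg, 0, 3800, sex = "M", bird_id = "m1",
                          scenario = sc, seed = 2000 + s)
    fixes <- rbind(
      trF[, .(tag_id = "f1", window_index = as.integer(floor(t / 30)),
              t_mid = t, x, y)],
      trM[, .(tag_id = "m1", window_index = as.integer(floor(t / 30)),
              t_mid = t, x, y)])
    trial <- list(focal_id = "foc", site = c(0, 0), t_start = 1800,
                  t_end = 1900,
                  windows = trial_windows(1800, 1900, duration = 1800))
    dd <- closest_neighbor_delta(fixes, man, trial)
    deltasF[s] <- dd[conspecific_sex == "F", delta_min_dist]
    deltasM[s] <- dd[conspecific_sex == "M", delta_min_dist]
  }
  expect_lt(mean(deltasF), 0)
  expect_gt(mean(deltasM), 0)
  expect_lt(mean(deltasF), mean(deltasM))
})
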