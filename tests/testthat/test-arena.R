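# a frozen state helper: robots/food at chosen positions
state_vec <- function(x0, y0, th0, x1, y1, th1,
                      food = c(0.9, 0.9, 0.1, 0.9)) {
  c(x0, y0, th0, x1, y1, th1, food)
}

test_that("proximity sensors localize the partner and fall off linearly", {
  cfg <- arena_config()
  # partner beyond range in every direction -> all zeros
  s <- sense_proximity(state_vec(0.5, 0.5, 0, 0.8, 0.5, 0), 1, config = cfg)
  expect_equal(unname(s), rep(0, 8))
  # partner touching directly ahead -> front sensor saturates at 1
  s <- sense_proximity(state_vec(0.5, 0.5, 0, 0.57, 0.5, 0), 1, config = cfg)
  expect_equal(unname(s), c(1, rep(0, 7)))
  # partner behind -> the rear-facing sensor (index 5 = 180 degrees)
  s <- sense_proximity(state_vec(0.5, 0.5, 0, 0.43, 0.5, 0), 1, config = cfg)
  expect_equal(unname(s), c(rep(0, 4), 1, rep(0, 3)))
  # non-increasing in edge-to-edge distance along a fixed bearing
  d <- seq(0.07, 0.13, by = 0.005)
  act <- vapply(d, function(dd)
    sense_proximity(state_vec(0.5, 0.5, 0, 0.5 + dd, 0.5, 0), 1,
                    config = cfg)[1], numeric(1))
  expect_true(all(diff(act) <= 0))
  expect_equal(act[1], 1)           # contact
  expect_equal(act[length(act)], 0) # beyond 5 cm gap
})

test_that("camera sectors report color fractions with occlusion", {
  cfg <- arena_config()
  # no food or partner in the forward cone -> all zero
  s <- sense_camera(state_vec(0.5, 0.5, 0, 0.5, 0.8, 0,
                              food = c(0.5, 0.2, 0.2, 0.7)), 1,
                    config = cfg)
  expect_equal(unname(s), rep(0, 9))
  # mobile partner dead ahead, close enough to span the central sector:
  # half-angle asin(0.035/0.1) = 20.5 deg > 10 deg
  st <- state_vec(0.5, 0.5, 0, 0.6, 0.5, 0, food = c(0.5, 0.2, 0.2, 0.7))
  s <- sense_camera(st, 1, config = cfg)
  expect_equal(unname(s["green2"]), 1)
  expect_equal(unname(s["blue2"]), 0)
  # same geometry, stuck partner -> blue, not green
  s <- sense_camera(st, 1, stuck = c(FALSE, TRUE), config = cfg)
  expect_equal(unname(s["blue2"]), 1)
  expect_equal(unname(s["green2"]), 0)
  # food ahead renders red with the exact angular fraction
  stf <- state_vec(0.5, 0.5, 0, 0.5, 0.8, 0, food = c(0.7, 0.5, 0.2, 0.8))
  s <- sense_camera(stf, 1, config = cfg)
  frac <- 2 * asin(0.027 / 0.2) / (pi / 9)
  expect_equal(unname(s["red2"]), frac, tolerance = 1e-12)
  # a nearer partner occludes the food completely
  sto <- state_vec(0.5, 0.5, 0, 0.6, 0.5, 0, food = c(0.7, 0.5, 0.2, 0.8))
  s <- sense_camera(sto, 1, config = cfg)
  expect_equal(unname(s["red2"]), 0)
  expect_equal(unname(s["green2"]), 1)
})

test_that("invisible partners leave only food visible", {
  cfg <- arena_config()
  st <- state_vec(0.5, 0.5, 0, 0.6, 0.5, 0, food = c(0.7, 0.5, 0.2, 0.8))
  s <- sense_world(st, 1, config = cfg, partner_invisible = TRUE)
  expect_equal(unname(s[1:8]), rep(0, 8))                  # proximity blind
  expect_equal(unname(s[c("green1", "green2", "green3",
                          "blue1", "blue2", "blue3")]), rep(0, 6))
  # food now unoccluded: same red as with the partner far behind
  st_far <- state_vec(0.5, 0.5, 0, 0.3, 0.5, 0, food = c(0.7, 0.5, 0.2, 0.8))
  s_far <- sense_world(st_far, 1, config = cfg)
  expect_equal(unname(s[c("red1", "red2", "red3")]),
               unname(s_far[c("red1", "red2", "red3")]))
})

test_that("stuck episode durations follow the geometric hazards", {
  cfg <- arena_config()
  set.seed(301)
  n <- 4000
  unhelped <- stuck_episode_durations(n, cfg, helped = FALSE)
  helped <- stuck_episode_durations(n, cfg, helped = TRUE)
  # geometric means 1/5e-4 = 2000 and 1/(5 * 5e-4) = 400, 3 SE bands
  expect_lt(abs(mean(unhelped) - 2000), 3 * sd(unhelped) / sqrt(n))
  expect_lt(abs(mean(helped) - 400), 3 * sd(helped) / sqrt(n))
  # hazard ratio ~ help_multiplier
  ratio <- mean(unhelped) / mean(helped)
  se_ratio <- ratio * sqrt(var(unhelped) / (n * mean(unhelped)^2) +
                           var(helped) / (n * mean(helped)^2))
  expect_lt(abs(ratio - cfg$help_multiplier), 3 * se_ratio)
})

test_that("evaluations are seed-reproducible and conserve the world", {
  set.seed(302)
  ga <- random_genome(); gb <- random_genome()
  cfg <- arena_config(eval_steps = 3000L, p_stuck = 5e-3)
  set.seed(11); r1 <- run_evaluation(ga, gb, config = cfg,
                                     log_trajectory = TRUE)
  set.seed(11); r2 <- run_evaluation(ga, gb, config = cfg,
                                     log_trajectory = TRUE)
  expect_identical(r1$food_counts, r2$food_counts)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$stuck_episodes, r2$stuck_episodes)
  tr <- r1$trajectory
  # robots never overlap after collision resolution
  dx <- abs(tr[, 2] - tr[, 6]); dx <- pmin(dx, 1 - dx)
  dy <- abs(tr[, 3] - tr[, 7]); dy <- pmin(dy, 1 - dy)
  expect_true(all(sqrt(dx^2 + dy^2) >= 0.07 - 1e-9))
  # stuck robots do not move (compare steps fully spent stuck; collisions
  # never displace a stuck robot either)
  for (rb in 0:1) {
    flag <- tr[, 5 + 4 * rb]
    stuck_rows <- which(flag == 1)
    stuck_rows <- stuck_rows[stuck_rows > 1 & flag[stuck_rows - 1] == 1]
    if (length(stuck_rows)) {
      expect_identical(tr[stuck_rows, 2 + 4 * rb],
                       tr[stuck_rows - 1, 2 + 4 * rb])
      expect_identical(tr[stuck_rows, 3 + 4 * rb],
                       tr[stuck_rows - 1, 3 + 4 * rb])
    }
  }
  # food-count trace is non-decreasing (conservation: the arena always
  # holds n_food sources; every eaten item is a respawn event)
  expect_true(all(diff(tr[, 12]) >= 0))
  expect_true(all(diff(tr[, 13]) >= 0))
  # helped episodes of robot i equal helping given by robot j
  for (rb in 1:2) {
    ep <- r1$stuck_episodes[[rb]]
    expect_identical(sum(ep$helped, na.rm = TRUE),
                     r1$helping_given[[3 - rb]])
  }
})

test_that("trajectory logs write the documented TSV layout", {
  set.seed(310)
  r <- run_evaluation(random_genome(), random_genome(),
                      config = arena_config(eval_steps = 50L),
                      log_trajectory = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(r, path)
  df <- read.delim(path)
  expect_identical(nrow(df), 50L)
  expect_identical(names(df)[1:5], c("step", "x1", "y1", "heading1",
                                     "stuck1"))
  r2 <- run_evaluation(random_genome(), random_genome(),
                       config = arena_config(eval_steps = 10L))
  expect_error(write_trajectory(r2, path), "log_trajectory")
})

test_that("motionless robots gather nothing and stuck onsets match the rate", {
  cfg <- arena_config(eval_steps = 2000L, p_stuck = 0)
  set.seed(303)
  r <- run_evaluation(motionless_weights(), motionless_weights(),
                      config = cfg)
  expect_identical(r$food_counts, c(0L, 0L))
  expect_identical(nrow(r$stuck_episodes[[1]]), 0L)
  # binomial count oracle for stuck onsets over mobile steps
  cfg2 <- arena_config(eval_steps = 2000L)
  set.seed(304)
  reps <- 100
  onsets <- replicate(reps, {
    r <- run_evaluation(motionless_weights(), motionless_weights(),
                        config = cfg2)
    nrow(r$stuck_episodes[[1]]) + nrow(r$stuck_episodes[[2]])
  })
  # oracle: per-robot mobile/stuck two-state chain with symmetric 5e-4
  # rates; expected onsets = sum_t p_stuck * P(mobile at step t)
  p <- 5e-4
  pm <- 0.5 + 0.5 * (1 - 2 * p)^(0:1999)
  expected <- 2 * sum(p * pm)
  expect_lt(abs(mean(onsets) - expected), 4 * sd(onsets) / sqrt(reps))
})
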