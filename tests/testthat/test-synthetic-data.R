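test_that("noiseless trajectories equal the sampled ground truth", {
  rec <- fake_run_record(1600, 10)
  traj <- make_trajectory(rec, noise_model(localization_sd = 0), seed = 1)
  expect_equal(traj$x_nm[1], 0)
  expect_equal(traj$x_nm[nrow(traj)], 1600)
  expect_true(all(traj$y_nm == 0))
  expect_equal(nrow(traj), 101)  # 10 s at 0.1-s frames, inclusive
})

test_that("localization noise has the stated standard deviation", {
  rec <- fake_run_record(0, 1000)  # single 1000-s plateau at the origin
  traj <- make_trajectory(rec, noise_model(localization_sd = 2), seed = 2)
  expect_gte(nrow(traj), 1e4)
  expect_gt(sd(traj$x_nm), 1.8)
  expect_lt(sd(traj$x_nm), 2.2)
  expect_gt(sd(traj$y_nm), 1.8)
  expect_lt(sd(traj$y_nm), 2.2)
})

test_that("truth annotations count the relocation events in the window", {
  set.seed(4)
  rec <- simulate_run(lattice_state(lattice_geometry(n_sites = 300)),
                      motor_params("K560"), map = map_params("FL_MAP7"),
                      concentration = 300, max_time = 60)
  traj <- make_trajectory(rec, noise_model(), seed = 5)
  tru <- trajectory_truth(traj)
  ev <- rec$events
  n_moves <- sum(ev$event %in% c("STEP_F", "STEP_B", "STEP_S",
                                 "TETHER_JUMP") &
                   ev$time_s <= max(traj$t_s))
  expect_equal(nrow(tru), n_moves)
  expect_true(all(tru$event %in% c("STEP_F", "STEP_B", "STEP_S",
                                   "TETHER_JUMP")))
  # per-event displacements match the event log
  expect_equal(tru$dx_nm,
               ev$x_nm[match(tru$time_s, ev$time_s)] -
                 ev$x_nm[match(tru$time_s, ev$time_s) - 1])
})

test_that("trajectories and their truth sidecars round-trip through CSV", {
  set.seed(6)
  rec <- simulate_run(lattice_state(lattice_geometry(n_sites = 200)),
                      motor_params("K560"), max_time = 20)
  traj <- make_trajectory(rec, noise_model(), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  expect_true(file.exists(sub("\\.csv$", ".truth.csv", path)))
  back <- read_trajectory_csv(path)
  expect_equal(back$x_nm, traj$x_nm, tolerance = 1e-9)
  expect_equal(as.data.frame(trajectory_truth(back)),
               as.data.frame(trajectory_truth(traj)), tolerance = 1e-9)
})

test_that("generators are byte-identical under a fixed seed", {
  rec <- fake_run_record(800, 20)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(make_trajectory(rec, noise_model(), seed = 9), p1)
  write_trajectory_csv(make_trajectory(rec, noise_model(), seed = 9), p2)
  expect_identical(readLines(p1), readLines(p2))
  t1 <- make_titration("hill", list(rmax = 1, kd = 111, h = 1),
                       c(10, 111, 1000), n_per_point = 5, seed = 3)
  t2 <- make_titration("hill", list(rmax = 1, kd = 111, h = 1),
                       c(10, 111, 1000), n_per_point = 5, seed = 3)
  expect_identical(t1, t2)
})

test_that("titration noise has the stated multiplicative structure", {
  cc <- c(10, 111, 1000)
  exact <- make_titration("hill", list(rmax = 1, kd = 111, h = 1), cc,
                          noise = noise_model(intensity_cv = 0),
                          n_per_point = 5, seed = 1)
  expect_equal(exact$response, hill_curve(cc, 1, 111), tolerance = 1e-12)
  expect_equal(exact$sd, rep(0, 3))
  big <- make_titration("hill", list(rmax = 1, kd = 111, h = 1), 111,
                        noise = noise_model(intensity_cv = 0.1),
                        n_per_point = 4000, seed = 2)
  expect_lt(abs(big$response - 0.5), 0.005)       # mean at K_D is R_max/2
  expect_lt(abs(big$sd - 0.1 * big$response) / (0.1 * big$response),
            0.1)                                   # sd ~ cv * mean
})

test_that("kymographs rasterise runs deterministically", {
  # constant-velocity run: 100 nm/s in 1-s hops for 40 s
  tms <- 0:40
  mover <- structure(list(
    run_length_nm = 4000, duration_s = 40, n_productive = 40L,
    end_reason = "spontaneous", mean_velocity = 100, motor = "K560",
    events = tibble::tibble(
      time_s = tms, protofilament = 6L, axial = seq_along(tms),
      x_nm = 100 * tms, y_nm = 0,
      event = c("LAND", rep("STEP_F", 39), "DETACH"))),
    class = "run_record")
  stalled <- fake_run_record(0, 40)
  ky <- make_kymograph(list(mover), pixel_nm = 50, line_interval_s = 1)
  ky2 <- make_kymograph(list(mover), pixel_nm = 50, line_interval_s = 1)
  expect_identical(unclass(ky), unclass(ky2))
  # one occupied pixel per line, advancing diagonally
  px <- apply(unclass(ky), 1, function(r) which(r > 0))
  expect_true(all(lengths(px) == 1))
  expect_true(all(diff(unlist(px)) >= 0))
  # slope of the occupied-pixel track equals the simulated velocity
  lines <- seq_along(unlist(px))
  fitv <- coef(lm(I(unlist(px) * 50) ~ I(lines * 1)))[2]
  expect_lt(abs(fitv - 100), 50 / 1)   # within one pixel quantum per line
  kys <- make_kymograph(list(stalled), pixel_nm = 50, line_interval_s = 1,
                        x_range = c(0, 1000))
  pxs <- apply(unclass(kys), 1, function(r) which(r > 0))
  expect_true(all(unlist(pxs) == unlist(pxs)[1]))  # vertical line
})
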