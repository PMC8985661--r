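test_that("motor presets satisfy their structural constraints", {
  for (nm in c("K560", "K490", "FL_kinesin", "DDR")) {
    m <- motor_params(nm)
    expect_equal(m$p_forward0 + m$p_side0 + m$p_back0, 1)
  }
  expect_false(motor_params("K490")$binds_map7)
  expect_false(motor_params("DDR")$binds_map7)
  expect_true(motor_params("K560")$binds_map7)
  expect_true(motor_params("FL_kinesin")$binds_map7)
  expect_error(motor_params("K560", p_forward0 = 0.5),
               class = "motormap_domain_error")
})

test_that("mean on-axis drift matches the closed-form per-step expectation", {
  # net displacement per productive event: 16 (p_f - p_b) + 0 * p_s
  set.seed(2)
  k <- motor_params("K560", k_detach0 = 0)
  geom <- lattice_geometry(n_sites = 3000)
  disp <- replicate(80, {
    r <- simulate_run(lattice_state(geom), k, start = c(6, 1500),
                      max_productive = 100)
    r$events$x_nm[nrow(r$events)] - r$events$x_nm[1]
  })
  expected <- 100 * 16 * (0.88 - 0.03)
  se <- sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp) - expected), 3 * se)
})

test_that("landing on an occupied site is a precondition error", {
  st <- occupy(lattice_state(lattice_geometry(n_sites = 30)), 3, 10, "MAP7")
  expect_error(
    simulate_run(st, motor_params("K560"), start = c(3, 10), seed = 1),
    class = "motormap_precondition_error")
})

test_that("a fully decorated lattice stops an untethered motor immediately", {
  geom <- lattice_geometry(n_sites = 40)
  st <- lattice_state(geom)
  st$occ[] <- 1L
  st$occ[5, 20] <- 0L
  r <- simulate_run(st, motor_params("K490"), map = map_params("FL_MAP7"),
                    start = c(5, 20), seed = 3)
  expect_equal(r$n_productive, 0)
  expect_true(r$end_reason %in% c("obstacle", "spontaneous"))
})

test_that("MTBD-only decoration stalls kinesin, faster at high ATP", {
  # without the projection domain there is no tether: the motor is stuck
  # until its first obstacle encounter, so higher stepping rates cause
  # faster dissociation
  mtbd <- map_params("MTBD_only")
  geom <- lattice_geometry(n_sites = 200)
  dur <- function(k_step, seed) {
    set.seed(seed)
    mean(replicate(60, {
      st <- decorate_lattice(lattice_state(geom), mtbd, 500)
      simulate_run(st, motor_params("K560", k_step = k_step),
                   map = mtbd)$duration_s
    }))
  }
  d_slow <- dur(1, 1)
  d_fast <- dur(100, 2)
  expect_gt(d_slow, 5 * d_fast)
})

test_that("tether jumps stay within reach plus one step", {
  set.seed(7)
  fl <- map_params("FL_MAP7")
  k5 <- motor_params("K560")
  geom <- lattice_geometry(n_sites = 300)
  n_jumps <- 0
  for (i in 1:40) {
    r <- simulate_run(lattice_state(geom), k5, map = fl,
                      concentration = 1000, max_time = 60)
    ev <- r$events
    j <- which(ev$event == "TETHER_JUMP")
    if (length(j)) {
      d <- sqrt((ev$x_nm[j] - ev$x_nm[j - 1])^2 +
                  (ev$y_nm[j] - ev$y_nm[j - 1])^2)
      expect_true(all(d <= 50 + 16 + 1e-9))
      n_jumps <- n_jumps + length(j)
    }
    # exclusion never violated: final lattice holds no stray motors
    expect_equal(sum(r$state$occ == 2L), 0)
  }
  expect_gt(n_jumps, 50)
})

test_that("event sequences are reproducible given a seed", {
  fl <- map_params("FL_MAP7")
  geom <- lattice_geometry(n_sites = 200)
  r1 <- simulate_run(lattice_state(geom), motor_params("K560"), map = fl,
                     concentration = 200, seed = 11, max_time = 60)
  r2 <- simulate_run(lattice_state(geom), motor_params("K560"), map = fl,
                     concentration = 200, seed = 11, max_time = 60)
  expect_identical(r1$events, r2$events)
})

test_that("without tethering, run length decreases with MAP7 occupancy", {
  k4 <- motor_params("K490")
  fl <- map_params("FL_MAP7")
  geom <- lattice_geometry(n_sites = 600)
  mean_len <- function(conc, seed) {
    set.seed(seed)
    lens <- replicate(150, {
      st <- decorate_lattice(lattice_state(geom), fl, conc)
      simulate_run(st, k4, map = fl)$run_length_nm
    })
    c(mean(lens), sd(lens) / sqrt(length(lens)))
  }
  m0 <- mean_len(0, 1); m1 <- mean_len(50, 2); m2 <- mean_len(300, 3)
  expect_gt(m0[1] - m1[1], -3 * sqrt(m0[2]^2 + m1[2]^2))
  expect_gt(m1[1] - m2[1], -3 * sqrt(m1[2]^2 + m2[2]^2))
  expect_gt(m0[1], m2[1])  # clear decrease end to end
})

test_that("dynein clearance survival matches its closed form", {
  # completion probability (1 - theta)^n_clear; at 10 nM with K_D = 111
  # and n_clear = 8, theta = 0.0826 and survival is 1/2
  fl <- map_params("FL_MAP7")
  ddr8 <- motor_params("DDR", n_clear = 8L)
  fr <- run_frequency(ddr8, fl, 10, n_trials = 4000, seed = 5)
  theta <- 10 / 121
  expect_equal(fr$theta, theta)
  expect_lt(abs(fr$p_complete - (1 - theta)^8), 3 * fr$se_p + 1e-9)
  expect_equal(fr$landing_rate, 1e-3 * (1 - theta))
})

test_that("kinesin run frequency is biphasic in MAP7 concentration", {
  fl <- map_params("FL_MAP7")
  fr <- run_frequency(motor_params("K560"), fl,
                      c(0, 10, 50, 100, 500, 1000),
                      n_trials = 200, seed = 1)
  peak <- max(fr$frequency)
  expect_gt(peak, fr$frequency[1])
  expect_gt(peak, fr$frequency[nrow(fr)])
  expect_true(which.max(fr$frequency) %in% 2:(nrow(fr) - 1))
})

test_that("run statistics summarise length and velocity with recovery", {
  one <- run_statistics(fake_run_record(1600, 2))
  expect_equal(one$mean_velocity_nm_s, 800)
  expect_equal(one$mean_run_length_nm, 1600)
  set.seed(3)
  recs <- lapply(rexp(500, 1 / 1000), function(l) fake_run_record(l, l / 800))
  st <- run_statistics(recs, seed = 1)
  expect_lt(abs(st$exp_mean_run_length_nm - 1000), 3 * st$se_exp_mean)
  expect_lt(abs(st$mean_run_length_nm - 1000), 3 * st$se_run_length)
  expect_error(run_statistics(list()), class = "motormap_domain_error")
})

test_that("velocity decreases with MAP7 occupancy for tethered kinesin", {
  fl <- map_params("FL_MAP7")
  k5 <- motor_params("K560")
  geom <- lattice_geometry(n_sites = 300)
  vel <- function(conc, seed) {
    set.seed(seed)
    recs <- lapply(1:80, function(i) {
      simulate_run(lattice_state(geom), k5, map = fl,
                   concentration = conc, max_time = 120)
    })
    run_statistics(recs, seed = 1)[, c("mean_velocity_nm_s",
                                       "se_velocity")]
  }
  v0 <- vel(0, 4); v1 <- vel(300, 5); v2 <- vel(1000, 6)
  expect_gt(v0$mean_velocity_nm_s,
            v1$mean_velocity_nm_s - 3 * v1$se_velocity)
  expect_gt(v1$mean_velocity_nm_s,
            v2$mean_velocity_nm_s - 3 * v2$se_velocity)
  expect_gt(v0$mean_velocity_nm_s, v2$mean_velocity_nm_s)
})

test_that("assembly direction switches from minus- to plus-end with MAP7", {
  a <- assembly_direction(concentration = c(0, 10), n_assemblies = 400,
                          seed = 5, n_trials = 500)
  expect_lt(abs(a$p_plus[1] - 0.20), 0.05)   # calibrated baseline
  expect_lt(a$frac_plus[1], 0.5)
  expect_gt(a$frac_plus[2], 0.5)
  # dynein silenced: all assemblies are plus-end-directed
  dead_dynein <- motor_params("DDR", k_land_basal = 0)
  b <- assembly_direction(dynein = dead_dynein, concentration = 0,
                          n_assemblies = 50, seed = 1, n_trials = 100)
  expect_equal(b$p_plus, 1)
  expect_error(
    assembly_direction(kinesin = motor_params("K560", k_land_basal = 0),
                       dynein = dead_dynein, concentration = 0,
                       n_assemblies = 10, seed = 1, n_trials = 50),
    class = "motormap_undefined_direction_error")
})
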