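mk_traj <- function(x, y = rep(0, length(x)), dt = 0.1) {
  tibble::tibble(t_s = (seq_along(x) - 1) * dt, x_nm = x, y_nm = y)
}

test_that("a noiseless staircase is recovered exactly", {
  x <- rep(seq(0, 160, by = 16), each = 10)
  st <- find_steps(mk_traj(x))
  expect_equal(nrow(st), 10)
  expect_equal(st$dx_nm, rep(16, 10))
  expect_equal(st$dy_nm, rep(0, 10))
  expect_equal(st$frame, seq(11, 101, by = 10))
  expect_error(find_steps(mk_traj(rnorm(5))),
               class = "motormap_precondition_error")
})

test_that("flat noisy traces yield no steps (false-positive control)", {
  set.seed(1)
  fp <- sum(vapply(1:100, function(i) {
    nrow(find_steps(mk_traj(rnorm(200, 0, 2), rnorm(200, 0, 2)))) > 0
  }, logical(1)))
  expect_lt(fp / 100, 0.05)
})

test_that("16-nm steps under 2-nm noise are recovered with high power", {
  set.seed(5)
  hits <- 0; tot <- 0; sizes <- c()
  for (i in 1:25) {
    x <- rep(seq(0, 16 * 20, by = 16), each = 10)
    n <- length(x)
    st <- find_steps(mk_traj(x + rnorm(n, 0, 2), rnorm(n, 0, 2)))
    true_cp <- seq(11, n, by = 10)
    tot <- tot + length(true_cp)
    hits <- hits + sum(vapply(true_cp, function(cp) {
      any(abs(st$frame - cp) <= 1)
    }, logical(1)))
    sizes <- c(sizes, st$dx_nm)
  }
  expect_gte(hits / tot, 0.95)
  expect_lt(abs(mean(abs(sizes)) - 16), 1)
})

test_that("fit residual variance matches the injected noise", {
  set.seed(9)
  x <- rep(seq(0, 16 * 12, by = 16), each = 15)
  n <- length(x)
  st <- find_steps(mk_traj(x + rnorm(n, 0, 2), rnorm(n, 0, 2)))
  rs <- attr(st, "residual_sd")
  expect_lt(abs(rs[["x"]]^2 - 4) / 4, 0.2)
  expect_lt(abs(rs[["y"]]^2 - 4) / 4, 0.2)
})

test_that("greedy finder agrees with the exact DP changepoint oracle", {
  set.seed(13)
  agree <- 0
  for (i in 1:100) {
    k_true <- sample(1:5, 1)
    dwell <- sample(12:25, k_true + 1, replace = TRUE)
    n <- sum(dwell)
    if (n > 200) { dwell <- pmax(10, floor(dwell * 200 / n)); n <- sum(dwell) }
    dirs <- sample(c(16, -16), k_true, replace = TRUE)
    levels <- cumsum(c(0, dirs))
    x <- rep(levels, dwell) + rnorm(n, 0, 2)
    greedy <- motormap:::find_changepoints(x, penalty = 1.3)
    exact <- dp_changepoints(x, k_true)
    if (length(greedy) == k_true && all(greedy == exact)) agree <- agree + 1
  }
  expect_gte(agree / 100, 0.95)
})

test_that("classification covers the direction conventions", {
  steps <- tibble::tibble(
    t_step_s = 1:4, frame = 1:4,
    dx_nm = c(16, -16, 0.5, 40), dy_nm = c(0, 0, 6, -1),
    dwell_s = rep(1, 4))
  cl <- classify_steps(steps)
  expect_equal(cl$n_steps, 4)
  expect_equal(cl$forward_pct, 50)    # +16 and the 40-nm forward jump
  expect_equal(cl$backward_pct, 25)
  expect_equal(cl$sideways_pct, 25)
  expect_equal(cl$large_jump_count, 1)
  only_fwd <- classify_steps(steps[1, ])
  expect_equal(only_fwd$forward_pct, 100)
  expect_equal(only_fwd$sideways_pct, 0)
  expect_error(classify_steps(steps[0, ]), class = "motormap_domain_error")
})

test_that("classification is invariant under global translation", {
  set.seed(21)
  x <- rep(seq(0, 16 * 8, by = 16), each = 10) + rnorm(90, 0, 2)
  y <- rep(c(0, 6, 6, 0, 0, 0, 6, 0, 0), each = 10) + rnorm(90, 0, 2)
  st1 <- find_steps(mk_traj(x, y))
  st2 <- find_steps(mk_traj(x + 500, y - 300))
  expect_equal(st1$class, st2$class)
  expect_equal(classify_steps(st1), classify_steps(st2))
})

test_that("step-size histograms conserve counts and expose the 16-nm mode", {
  steps <- tibble::tibble(
    t_step_s = 1:6, frame = 1:6,
    dx_nm = c(16, 16.4, 15.7, -16, 32, 48), dy_nm = rep(0, 6),
    dwell_s = rep(1, 6))
  h <- step_size_histogram(steps, bin_nm = 4)
  expect_equal(sum(h$count[h$axis == "dx"]), 6)
  expect_equal(sum(h$count[h$axis == "dy"]), 6)
  expect_equal(modal_step_size(steps, 4), 16)
  expect_error(step_size_histogram(steps, 0),
               class = "motormap_domain_error")
  # all-16-nm table occupies a single bin
  h16 <- step_size_histogram(steps[1:3, ], bin_nm = 4)
  expect_equal(h16$bin_center_nm[h16$axis == "dx"], 16)
})
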