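test_that("the Hill fit recovers noiseless generating parameters", {
  cc <- c(0, 10, 30, 111, 300, 1000, 3000)
  tab <- tibble::tibble(concentration = cc,
                        response = hill_curve(cc, rmax = 1, kd = 111))
  fit <- fit_hill(tab)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_true(fit$converged)
  expect_equal(unname(est["kd"]), 111, tolerance = 1e-6)
  expect_equal(unname(est["rmax"]), 1, tolerance = 1e-6)
  expect_equal(unname(est["h"]), 1, tolerance = 1e-4)
  expect_error(fit_hill(tab[1:3, ]),
               class = "motormap_precondition_error")
})

test_that("constant responses are flagged non-identifiable, not thrown", {
  tab <- tibble::tibble(concentration = c(0, 10, 100, 1000),
                        response = rep(2, 4))
  fit <- fit_hill(tab)
  expect_false(fit$converged)
  expect_true("non_identifiable" %in% fit$flags)
  expect_error(predict(fit), class = "motormap_domain_error")
})

test_that("noisy titrations recover K_D within 15% in the median", {
  cc <- c(5, 15, 40, 111, 300, 800, 2000)
  kds <- vapply(1:10, function(s) {
    tab <- make_titration("hill", list(rmax = 1, kd = 111, h = 1), cc,
                          noise = noise_model(intensity_cv = 0.1),
                          n_per_point = 5, seed = s)
    fit <- fit_hill(tab)
    tidy(fit)$estimate[tidy(fit)$term == "kd"]
  }, numeric(1))
  expect_lt(abs(median(kds) - 111) / 111, 0.15)
})

test_that("the biphasic fit recovers its own curve and beats Hill only when real", {
  cc <- c(0, 2, 5, 10, 20, 50, 100, 200, 500, 1000)
  tab <- tibble::tibble(
    concentration = cc,
    response = biphasic_hill_curve(cc, a = 2, ec50 = 20, h1 = 1,
                                   ic50 = 300, h2 = 1, f0 = 0.1))
  fit <- fit_biphasic_hill(tab)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_true(fit$converged)
  expect_length(fit$flags, 0)
  expect_equal(unname(est["ec50"]), 20, tolerance = 0.01)
  expect_equal(unname(est["ic50"]), 300, tolerance = 0.01)
  expect_lt(fit$aic, fit$aic_alt)  # biphasic preferred on biphasic truth
  # single-Hill-generated data: AIC must prefer the single Hill
  tab2 <- tibble::tibble(concentration = cc,
                         response = hill_curve(cc, rmax = 1, kd = 50))
  fit2 <- fit_biphasic_hill(tab2)
  expect_true("no_biphasic_evidence" %in% fit2$flags)
})

test_that("the Langmuir inhibition fit recovers IC50 and flags rising data", {
  cc <- c(0, 2, 5, 10, 20, 50, 100)
  tab <- tibble::tibble(
    concentration = cc,
    response = langmuir_inhibition_curve(cc, f0 = 1, ic50 = 10))
  fit <- fit_langmuir_inhibition(tab)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["ic50"]), 10, tolerance = 1e-6)
  # half-max at IC50 by definition
  expect_equal(predict(fit, 10), est[["f0"]] / 2, tolerance = 1e-6,
               ignore_attr = TRUE)
  rising <- tibble::tibble(concentration = cc, response = 1 + cc / 10)
  expect_true("increasing_response" %in%
                fit_langmuir_inhibition(rising)$flags)
})

test_that("fits are scale-equivariant in the response", {
  cc <- c(0, 5, 15, 40, 111, 300, 800, 2000)
  tab <- make_titration("hill", list(rmax = 1, kd = 111, h = 1), cc,
                        n_per_point = 4, seed = 3)
  f1 <- fit_hill(tab)
  tab10 <- dplyr::mutate(tab, response = response * 10, sd = sd * 10)
  f2 <- fit_hill(tab10)
  e1 <- setNames(tidy(f1)$estimate, tidy(f1)$term)
  e2 <- setNames(tidy(f2)$estimate, tidy(f2)$term)
  expect_equal(unname(e2["rmax"] / e1["rmax"]), 10, tolerance = 1e-4)
  expect_equal(unname(e2["kd"]), unname(e1["kd"]), tolerance = 1e-4)
  expect_equal(unname(e2["h"]), unname(e1["h"]), tolerance = 1e-4)
})

test_that("bootstrap and covariance standard errors agree within 2x", {
  cc <- c(2, 8, 25, 80, 111, 250, 700, 2000)
  tab <- make_titration("hill", list(rmax = 1, kd = 111, h = 1), cc,
                        noise = noise_model(intensity_cv = 0.08),
                        n_per_point = 6, seed = 7)
  fit <- fit_hill(tab)
  bt <- dose_fit_bootstrap(fit, n_boot = 200, seed = 1)
  td <- tidy(fit)
  for (tm in c("kd", "rmax")) {
    ratio <- bt$se_boot[bt$term == tm] / td$std.error[td$term == tm]
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})
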