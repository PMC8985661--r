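# Dose-response model curves -------------------------------------------

#' Dose-response model curves
#'
#' `hill_curve()` is the Hill binding isotherm
#' \eqn{R_{max} c^h / (c^h + K_D^h)}; `biphasic_hill_curve()` is the
#' product of an activating and an inhibiting Hill term,
#' \eqn{A \frac{c^{h_1}}{c^{h_1}+EC_{50}^{h_1}}
#'        \frac{IC_{50}^{h_2}}{c^{h_2}+IC_{50}^{h_2}} + f_0},
#' which rises to an interior maximum and falls again;
#' `langmuir_inhibition_curve()` is single-site competitive suppression
#' \eqn{f_0\, IC_{50} / (IC_{50} + c)}.
#'
#' @param conc Concentration, nM (vectorised; defined at 0).
#' @param rmax,kd,h Hill amplitude, half-saturation and coefficient.
#' @param a,ec50,h1,ic50,h2,f0 Biphasic amplitude, half-activation,
#'   activation Hill coefficient, half-inhibition, inhibition Hill
#'   coefficient and baseline.
#' @return Numeric response vector.
#' @export
hill_curve <- function(conc, rmax, kd, h = 1) {
  ch <- conc^h
  rmax * ch / (ch + kd^h)
}

#' @rdname hill_curve
#' @export
biphasic_hill_curve <- function(conc, a, ec50, h1, ic50, h2, f0 = 0) {
  ch1 <- conc^h1
  ch2 <- conc^h2
  a * (ch1 / (ch1 + ec50^h1)) * (ic50^h2 / (ch2 + ic50^h2)) + f0
}

#' @rdname hill_curve
#' @export
langmuir_inhibition_curve <- function(conc, f0, ic50) {
  f0 * ic50 / (ic50 + conc)
}

# Fitting ---------------------------------------------------------------

new_dose_fit <- function(model, fit, data, flags, curve, aic_alt = NULL) {
  converged <- !is.null(fit)
  coefs <- if (converged) {
    sm <- summary(fit)$coefficients
    tibble(term = rownames(sm), estimate = sm[, "Estimate"],
           std.error = sm[, "Std. Error"])
  } else {
    tibble(term = character(0), estimate = numeric(0),
           std.error = numeric(0))
  }
  rss <- if (converged) sum(resid(fit)^2) else NA_real_
  n <- nrow(data)
  p <- nrow(coefs)
  structure(
    list(model = model, fit = fit, coef = coefs, data = data,
         rss = rss, aic = if (converged) n * log(rss / n) + 2 * p else
           NA_real_,
         aic_alt = aic_alt, converged = converged, flags = flags,
         curve = curve, n = n),
    class = "dose_fit")
}

fit_weights <- function(table) {
  if ("sd" %in% names(table) && all(is.finite(table$sd)) &&
      all(table$sd > 0)) 1 / table$sd^2 else rep(1, nrow(table))
}

check_titration <- function(table, min_conc) {
  if (!all(c("concentration", "response") %in% names(table))) {
    abort("titration table needs columns concentration and response",
          class = "motormap_domain_error")
  }
  if (length(unique(table$concentration)) < min_conc) {
    abort(sprintf("need >= %d distinct concentrations", min_conc),
          class = "motormap_precondition_error")
  }
  invisible(TRUE)
}

multistart_nls <- function(formula, data, starts_list, lower, upper,
                           weights) {
  best <- NULL
  data$.w <- weights
  for (st in starts_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper, weights = .w,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
    }
  }
  best
}

log_spaced_starts <- function(conc, k = 5) {
  pos <- conc[conc > 0]
  10^seq(log10(max(min(pos), 1e-3)), log10(max(pos)), length.out = k)
}

#' Fit the Hill equation to a titration table
#'
#' Weighted (1/sd^2 when `sd` is available) nonlinear least squares of
#' \eqn{R(c) = R_{max} c^h / (c^h + K_D^h)}, with multi-start
#' initialisation of \eqn{K_D} on a log-spaced grid. Standard errors come
#' from the covariance of the linearised fit; [dose_fit_bootstrap()]
#' provides a seeded bootstrap cross-check. Non-convergence and
#' non-identifiable (constant-response) inputs are flagged on the result,
#' not raised as errors.
#'
#' @param table Tibble with `concentration` (nM), `response`, optional
#'   `sd`, `n`; >= 4 distinct concentrations.
#' @return A `dose_fit` object; see [tidy.dose_fit()] /
#'   [glance.dose_fit()].
#' @export
fit_hill <- function(table) {
  check_titration(table, 4L)
  if (sd(table$response) < 1e-12 * (abs(mean(table$response)) + 1e-12)) {
    return(new_dose_fit("hill", NULL, table, "non_identifiable",
                        hill_curve))
  }
  starts <- lapply(log_spaced_starts(table$concentration),
                   function(kd) list(rmax = max(table$response),
                                     kd = kd, h = 1))
  fit <- multistart_nls(
    response ~ hill_curve(concentration, rmax, kd, h), table, starts,
    lower = c(rmax = 1e-12, kd = 1e-9, h = 0.2),
    upper = c(rmax = Inf, kd = Inf, h = 6),
    weights = fit_weights(table))
  flags <- if (is.null(fit)) "not_converged" else character(0)
  new_dose_fit("hill", fit, table, flags, hill_curve)
}

#' Fit the biphasic Hill equation
#'
#' Fits the activation-times-inhibition product
#' (see [biphasic_hill_curve()]) by multi-start weighted least squares and
#' reports the half-maximal activation (`ec50`) and inhibition (`ic50`)
#' concentrations. The fit is compared with a single Hill fit by AIC;
#' when the single Hill model is preferred the result is flagged
#' `"no_biphasic_evidence"`, and `"ec50_not_below_ic50"` flags optima
#' without a rising-then-falling shape.
#'
#' @param table Tibble as in [fit_hill()]; >= 6 distinct concentrations.
#' @return A `dose_fit` object (field `aic_alt` holds the single-Hill
#'   AIC).
#' @export
fit_biphasic_hill <- function(table) {
  check_titration(table, 6L)
  if (sd(table$response) < 1e-12 * (abs(mean(table$response)) + 1e-12)) {
    return(new_dose_fit("biphasic_hill", NULL, table, "non_identifiable",
                        biphasic_hill_curve))
  }
  grid <- log_spaced_starts(table$concentration)
  starts <- list()
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[j] > grid[i]) {
        starts[[length(starts) + 1L]] <-
          list(a = max(table$response), ec50 = grid[i], h1 = 1,
               ic50 = grid[j], h2 = 1, f0 = min(table$response))
      }
    }
  }
  w <- fit_weights(table)
  fit <- multistart_nls(
    response ~ biphasic_hill_curve(concentration, a, ec50, h1, ic50, h2,
                                   f0),
    table, starts,
    lower = c(a = 1e-12, ec50 = 1e-9, h1 = 0.2, ic50 = 1e-9, h2 = 0.2,
              f0 = 0),
    upper = c(a = Inf, ec50 = Inf, h1 = 6, ic50 = Inf, h2 = 6, f0 = Inf),
    weights = w)
  flags <- character(0)
  if (is.null(fit)) flags <- "not_converged"
  hill <- fit_hill(table)
  out <- new_dose_fit("biphasic_hill", fit, table, flags,
                      biphasic_hill_curve, aic_alt = hill$aic)
  if (out$converged) {
    est <- setNames(out$coef$estimate, out$coef$term)
    if (est[["ec50"]] >= est[["ic50"]]) {
      out$flags <- c(out$flags, "ec50_not_below_ic50")
    }
    if (is.finite(hill$aic) && hill$aic <= out$aic) {
      out$flags <- c(out$flags, "no_biphasic_evidence")
    }
  }
  out
}

#' Fit the Langmuir inhibition equation
#'
#' Weighted least squares of \eqn{f(c) = f_0\,IC_{50}/(IC_{50} + c)}.
#' Tables whose response increases with concentration are flagged
#' `"increasing_response"`.
#'
#' @param table Tibble as in [fit_hill()]; >= 4 distinct concentrations.
#' @return A `dose_fit` object.
#' @export
fit_langmuir_inhibition <- function(table) {
  check_titration(table, 4L)
  flags <- character(0)
  if (stats::cor(table$concentration, table$response) > 0) {
    flags <- "increasing_response"
  }
  starts <- lapply(log_spaced_starts(table$concentration),
                   function(ic) list(f0 = max(table$response), ic50 = ic))
  fit <- multistart_nls(
    response ~ langmuir_inhibition_curve(concentration, f0, ic50), table,
    starts,
    lower = c(f0 = 1e-12, ic50 = 1e-9), upper = c(f0 = Inf, ic50 = Inf),
    weights = fit_weights(table))
  if (is.null(fit)) flags <- c(flags, "not_converged")
  new_dose_fit("langmuir_inhibition", fit, table, flags,
               langmuir_inhibition_curve)
}

# Methods ---------------------------------------------------------------

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("<dose_fit> %s (%s)\n", x$model,
              if (x$converged) "converged" else "not converged"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "),
                           "\n")
  if (x$converged) {
    for (i in seq_len(nrow(x$coef))) {
      cat(sprintf("  %-6s %10.4g (se %.3g)\n", x$coef$term[i],
                  x$coef$estimate[i], x$coef$std.error[i]))
    }
    cat(sprintf("  RSS %.4g, AIC %.4g, n %d\n", x$rss, x$aic, x$n))
  }
  invisible(x)
}

#' Tidy and summarise dose-response fits
#'
#' Broom-style accessors: `tidy()` returns one row per parameter with
#' estimate and standard error; `glance()` returns one row of fit-level
#' summaries.
#'
#' @param x A `dose_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy dose_fit
tidy.dose_fit <- function(x, ...) x$coef

#' @rdname tidy.dose_fit
#' @export
#' @method glance dose_fit
glance.dose_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, aic = x$aic,
         aic_alt = x$aic_alt %||% NA_real_,
         converged = x$converged,
         flags = paste(x$flags, collapse = ";"), n = x$n)
}

#' @export
predict.dose_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) abort("cannot predict from a non-converged fit",
                               class = "motormap_domain_error")
  conc <- if (is.null(newdata)) object$data$concentration else
    if (is.data.frame(newdata)) newdata$concentration else newdata
  est <- as.list(setNames(object$coef$estimate, object$coef$term))
  do.call(object$curve, c(list(conc), est))
}

#' Bootstrap standard errors for a dose-response fit
#'
#' Residual-resampling bootstrap: responses are regenerated as fitted
#' values plus resampled residuals and the model is refit from the
#' original optimum. A cross-check on the covariance-based standard
#' errors reported by [tidy.dose_fit()].
#'
#' @param x A converged `dose_fit`.
#' @param n_boot Number of resamples.
#' @param seed Optional RNG seed.
#' @return Tibble `term`, `se_boot`.
#' @export
dose_fit_bootstrap <- function(x, n_boot = 200, seed = NULL) {
  if (!x$converged) abort("fit did not converge",
                          class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)
  fit_vals <- predict(x, x$data)
  est <- as.list(setNames(x$coef$estimate, x$coef$term))
  w <- fit_weights(x$data)
  # standardise residuals by the weight scale so heteroscedastic points
  # are resampled on a common scale
  scale_i <- 1 / sqrt(w)
  z_res <- (x$data$response - fit_vals) / scale_i
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(est))
  colnames(draws) <- names(est)
  for (b in seq_len(n_boot)) {
    tab <- x$data
    tab$response <- fit_vals + scale_i * sample(z_res, replace = TRUE)
    refit <- multistart_nls(
      formula(x$fit), tab, list(est),
      lower = rep(1e-12, length(est)),
      upper = rep(Inf, length(est)), weights = w)
    if (!is.null(refit)) draws[b, ] <- coef(refit)[names(est)]
  }
  tibble(term = names(est),
         se_boot = apply(draws, 2, sd, na.rm = TRUE))
}
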