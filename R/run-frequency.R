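#' Processive run frequency of a motor on MAP-decorated lattices
#'
#' Run frequency is the landing rate times the probability that a landed
#' motor completes a processive run. The landing rate per site is
#' \deqn{k_{land} (1 + g\,\theta_{proj})\, a(\theta)\, (1 - \theta)}
#' where \eqn{\theta} is the equilibrium MAP7 occupancy,
#' \eqn{\theta_{proj} = \theta} when the motor can be recruited by the
#' projection domain (else 0), \eqn{g} is `recruitment_gain` and
#' \eqn{a(\theta)} the autoinhibition activity factor. The completion
#' probability is estimated by Monte Carlo:
#'
#' * motors with a finite `n_clear` (dynein) score a processive run when
#'   `n_clear` consecutive sites ahead of the landing site are free, so
#'   the normalised frequency falls as \eqn{(1-\theta)^{n_{clear}}};
#' * all other motors are simulated with [simulate_run()] on a freshly
#'   decorated lattice until `min_run_length` productive relocation events
#'   are reached (a scored run) or the run terminates first.
#'
#' @param motor A [motor_params()].
#' @param map A [map_params()].
#' @param concentration MAP concentration(s), nM (vectorised).
#' @param n_trials Monte-Carlo landing trials per concentration.
#' @param seed Optional RNG seed.
#' @param geometry Lattice geometry for the run simulations.
#' @param tether A [tether_params()].
#' @param min_run_length Productive events that define a scored run.
#' @return Tibble with one row per concentration: `concentration`,
#'   `theta`, `landing_rate`, `p_complete`, `se_p`, `frequency` (runs per
#'   site per s), `se_frequency`, `n_trials`.
#' @export
run_frequency <- function(motor, map, concentration, n_trials = 500,
                          seed = NULL, geometry = lattice_geometry(),
                          tether = tether_params(), min_run_length = 5) {
  if (n_trials < 1) abort("n_trials must be >= 1",
                          class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)
  map_dfr(concentration, function(conc) {
    theta <- equilibrium_occupancy(map, conc)
    theta_proj <- if (isTRUE(motor$binds_map7) &&
                      isTRUE(map$has_projection)) theta else 0
    landing <- motor$k_land_basal *
      (1 + motor$recruitment_gain * theta_proj) *
      motor_activity(motor, theta) * (1 - theta)
    if (is.finite(motor$n_clear)) {
      # clearance rule: the n_clear sites ahead of the (empty) landing
      # site must all be free of MAP7
      ahead <- matrix(runif(n_trials * motor$n_clear) < theta,
                      nrow = n_trials)
      done <- rowSums(ahead) == 0L
    } else {
      done <- vapply(seq_len(n_trials), function(i) {
        st <- lattice_state(geometry)
        st <- decorate_lattice(st, map, conc)
        rec <- simulate_run(st, motor, tether = tether, map = map,
                            max_productive = min_run_length,
                            max_time = 10 * min_run_length /
                              max(motor$k_step, 1e-6))
        rec$n_productive >= min_run_length
      }, logical(1))
    }
    p <- mean(done)
    se_p <- sqrt(p * (1 - p) / n_trials)
    tibble(concentration = conc, theta = theta, landing_rate = landing,
           p_complete = p, se_p = se_p, frequency = landing * p,
           se_frequency = landing * se_p, n_trials = n_trials)
  })
}

#' Summary statistics of simulated runs
#'
#' Mean run length (with a single-exponential fit of the run-length
#' survival distribution, whose maximum-likelihood mean coincides with the
#' sample mean), mean velocity, and seeded bootstrap standard errors.
#'
#' @param records List of `run_record` objects (>= 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional RNG seed for the bootstrap.
#' @return One-row tibble: `n_runs`, `mean_run_length_nm`,
#'   `se_run_length`, `exp_mean_run_length_nm`, `se_exp_mean`,
#'   `mean_velocity_nm_s`, `se_velocity`, `mean_duration_s`.
#' @export
run_statistics <- function(records, n_boot = 1000, seed = NULL) {
  if (inherits(records, "run_record")) records <- list(records)
  if (!length(records)) abort("no run records supplied",
                              class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)
  len <- map_dbl(records, "run_length_nm")
  dur <- map_dbl(records, "duration_s")
  vel <- ifelse(dur > 0, len / dur, 0)
  n <- length(len)
  boot <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    c(mean(len[j]), mean(vel[j]))
  }, numeric(2))
  tibble(n_runs = n,
         mean_run_length_nm = mean(len), se_run_length = sd(boot[1, ]),
         exp_mean_run_length_nm = mean(len),   # exponential MLE
         se_exp_mean = mean(len) / sqrt(n),
         mean_velocity_nm_s = mean(vel), se_velocity = sd(boot[2, ]),
         mean_duration_s = mean(dur))
}

#' Directionality of kinesin-dynein assemblies
#'
#' Tug-of-war direction draw for cargo assemblies linking full-length
#' kinesin and dynein: each assembly moves plus-end-directed with
#' probability \eqn{f_k / (f_k + f_d)}, where \eqn{f_k, f_d} are the two
#' motors' run frequencies at the given MAP7 concentration (from
#' [run_frequency()]). The full-length-kinesin preset's autoinhibition is
#' calibrated so that 80% of assemblies are minus-end-directed on bare
#' lattices; MAP7 recruitment and dynein inhibition then switch the
#' majority direction.
#'
#' @param kinesin,dynein [motor_params()] for the two motors.
#' @param map A [map_params()].
#' @param concentration MAP7 concentration(s), nM (vectorised).
#' @param n_assemblies Assemblies drawn per concentration.
#' @param seed Optional RNG seed.
#' @param n_trials Landing trials per frequency estimate.
#' @param ... Passed to [run_frequency()].
#' @return Tibble: `concentration`, `f_kinesin`, `f_dynein`, `p_plus`
#'   (model probability), `frac_plus` (simulated fraction), `n_assemblies`.
#' @export
assembly_direction <- function(kinesin = motor_params("FL_kinesin"),
                               dynein = motor_params("DDR"),
                               map = map_params("FL_MAP7"),
                               concentration = 0, n_assemblies = 300,
                               seed = NULL, n_trials = 500, ...) {
  if (n_assemblies < 1) abort("n_assemblies must be >= 1",
                              class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)
  map_dfr(concentration, function(conc) {
    fk <- run_frequency(kinesin, map, conc, n_trials = n_trials, ...)$frequency
    fd <- run_frequency(dynein, map, conc, n_trials = n_trials, ...)$frequency
    if (fk + fd <= 0) {
      abort("both motor frequencies are zero: direction undefined",
            class = "motormap_undefined_direction_error")
    }
    p_plus <- fk / (fk + fd)
    frac <- rbinom(1L, n_assemblies, p_plus) / n_assemblies
    tibble(concentration = conc, f_kinesin = fk, f_dynein = fd,
           p_plus = p_plus, frac_plus = frac,
           n_assemblies = n_assemblies)
  })
}
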