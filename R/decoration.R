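map_preset_table <- list(
  # k_on in /nM/s per site, k_off in /s. Only the ratio K_D = k_off/k_on is
  # constrained by binding data (K_D = 111 nM for full-length MAP7);
  # k_off = 1 /s is a convention since absolute exchange rates are unknown.
  FL_MAP7     = list(k_on = 1 / 111, k_off = 1, hill_h = 1,
                     has_mtbd = TRUE,  has_projection = TRUE,
                     tail_dependent = FALSE, tail_bound_fraction = 0.3),
  MTBD_only   = list(k_on = 1 / 111, k_off = 1, hill_h = 1,
                     has_mtbd = TRUE,  has_projection = FALSE,
                     tail_dependent = FALSE, tail_bound_fraction = 0),
  dMTBD       = list(k_on = 0, k_off = 1, hill_h = 1,
                     has_mtbd = FALSE, has_projection = TRUE,
                     tail_dependent = TRUE, tail_bound_fraction = 0.3),
  MAP7_N      = list(k_on = 1 / 111, k_off = 1, hill_h = 1,
                     has_mtbd = TRUE,  has_projection = FALSE,
                     tail_dependent = FALSE, tail_bound_fraction = 0.3),
  MAP7_C      = list(k_on = 0, k_off = 1, hill_h = 1,
                     has_mtbd = FALSE, has_projection = TRUE,
                     tail_dependent = FALSE, tail_bound_fraction = 0),
  tau_chimera = list(k_on = 1 / 111, k_off = 1, hill_h = 1,
                     has_mtbd = TRUE,  has_projection = TRUE,
                     tail_dependent = FALSE, tail_bound_fraction = 0))

#' MAP construct parameter presets
#'
#' Kinetic and structural parameters of a microtubule-associated protein
#' construct. Shipped presets:
#'
#' * `FL_MAP7`: full-length MAP7; lattice-binding MTBD (K_D = 111 nM) plus
#'   the kinesin-binding projection domain, plus weak tubulin-tail binding
#'   via the P123 region.
#' * `MTBD_only`: the microtubule-binding helix alone; blocks motor sites
#'   but cannot tether or recruit kinesin.
#' * `dMTBD`: MAP7 lacking the MTBD; associates only with the flexible
#'   tubulin tails (non-exclusive, does not occupy lattice sites) and
#'   retains the projection domain.
#' * `MAP7_N`: N-terminal half (MTBD + P123), no projection domain.
#' * `MAP7_C`: C-terminal half (projection domain only), no MT binding.
#' * `tau_chimera`: tau MTBD fused to the MAP7 projection domain; binds the
#'   lattice competitively and tethers kinesin, like full-length MAP7.
#'
#' @param name Preset name.
#' @param ... Named overrides of preset fields (`k_on`, `k_off`, `hill_h`,
#'   `has_mtbd`, `has_projection`, `tail_dependent`,
#'   `tail_bound_fraction`).
#' @return Object of class `map_params` with derived field `k_d =
#'   k_off / k_on` (Inf when `k_on = 0`).
#' @examples
#' map_params("FL_MAP7")$k_d # 111 nM
#' @export
map_params <- function(name = c("FL_MAP7", "MTBD_only", "dMTBD", "MAP7_N",
                                "MAP7_C", "tau_chimera"), ...) {
  name <- match.arg(name)
  p <- modifyList(map_preset_table[[name]], list(...))
  if (p$k_on < 0 || p$k_off <= 0) {
    abort("k_on must be >= 0 and k_off > 0", class = "motormap_domain_error")
  }
  p$name <- name
  p$k_d <- if (p$k_on > 0) p$k_off / p$k_on else Inf
  structure(p, class = "map_params")
}

#' @export
print.map_params <- function(x, ...) {
  cat(sprintf(
    "<map_params> %s: K_D = %.3g nM (k_on %.3g /nM/s, k_off %.3g /s), h = %g\n  MTBD %s, projection %s, tail-dependent %s\n",
    x$name, x$k_d, x$k_on, x$k_off, x$hill_h,
    x$has_mtbd, x$has_projection, x$tail_dependent))
  invisible(x)
}

#' Equilibrium lattice occupancy of a MAP construct
#'
#' Hill isotherm \eqn{\theta(c) = c^h / (c^h + K_D^h)} for lattice-binding
#' constructs; constructs without an MTBD never occupy lattice sites and
#' return 0.
#'
#' @param params A [map_params()].
#' @param concentration MAP concentration in nM (vectorised, >= 0).
#' @return Occupied fraction in \[0, 1\].
#' @export
equilibrium_occupancy <- function(params, concentration) {
  if (any(concentration < 0)) {
    abort("concentration must be >= 0", class = "motormap_domain_error")
  }
  if (!params$has_mtbd) return(rep(0, length(concentration)))
  h <- params$hill_h
  ch <- concentration^h
  ch / (ch + params$k_d^h)
}

#' Gillespie simulation of MAP7 decoration kinetics
#'
#' Exact continuous-time kinetic Monte Carlo of per-site MAP binding (rate
#' `k_on * concentration` per EMPTY site) and unbinding (rate `k_off` per
#' MAP7 site) on a lattice. Sites occupied by motors are never bound
#' (mutual exclusion). The steady-state mean occupancy converges to
#' [equilibrium_occupancy()] within Monte-Carlo error.
#'
#' @param state A [lattice_state()]; may contain pre-bound motors.
#' @param params A [map_params()].
#' @param concentration MAP concentration, nM.
#' @param duration Simulated time, s.
#' @param seed Optional RNG seed.
#' @param burn_in Time discarded before averaging (default `duration / 3`).
#' @param n_record Number of equally spaced occupancy samples kept in the
#'   time series.
#' @return Object of class `decoration_sim`: final `state`, occupancy
#'   `series` (tibble `time_s`, `occupancy`), time-averaged
#'   `mean_occupancy` with standard error `se`, post-burn-in event counts
#'   `n_bind` / `n_unbind`, and the closed-form `theta_eq`.
#' @export
simulate_decoration <- function(state, params, concentration, duration,
                                seed = NULL, burn_in = duration / 3,
                                n_record = 400) {
  if (duration <= 0) abort("duration must be > 0",
                           class = "motormap_domain_error")
  if (concentration < 0) abort("concentration must be >= 0",
                               class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)

  occ <- state$occ
  n_total <- length(occ)
  free_sites <- which(occ == OCC_CODES[["EMPTY"]])
  bound_sites <- which(occ == OCC_CODES[["MAP7"]])
  nf <- length(free_sites); nb <- length(bound_sites)
  length(free_sites) <- n_total
  length(bound_sites) <- n_total

  kb <- if (params$has_mtbd) params$k_on * concentration else 0
  ku <- params$k_off
  rec_t <- seq(0, duration, length.out = n_record)
  rec_occ <- numeric(n_record)
  ri <- 1L
  t_now <- 0
  occ_integral <- 0
  n_bind <- 0L; n_unbind <- 0L

  repeat {
    rb <- kb * nf; ru <- ku * nb; rt <- rb + ru
    dt <- if (rt > 0) rexp(1L, rt) else duration
    t_next <- t_now + dt
    frac <- nb / n_total
    while (ri <= n_record && rec_t[ri] <= min(t_next, duration) + 1e-12) {
      rec_occ[ri] <- frac
      ri <- ri + 1L
    }
    hi <- min(t_next, duration)
    if (hi > burn_in) occ_integral <- occ_integral +
        frac * (hi - max(t_now, burn_in))
    if (t_next >= duration) break
    t_now <- t_next
    if (runif(1L) * rt < rb) {
      i <- sample.int(nf, 1L)
      s <- free_sites[i]
      free_sites[i] <- free_sites[nf]; nf <- nf - 1L
      nb <- nb + 1L; bound_sites[nb] <- s
      occ[s] <- OCC_CODES[["MAP7"]]
      if (t_now > burn_in) n_bind <- n_bind + 1L
    } else {
      i <- sample.int(nb, 1L)
      s <- bound_sites[i]
      bound_sites[i] <- bound_sites[nb]; nb <- nb - 1L
      nf <- nf + 1L; free_sites[nf] <- s
      occ[s] <- OCC_CODES[["EMPTY"]]
      if (t_now > burn_in) n_unbind <- n_unbind + 1L
    }
  }

  state$occ <- occ
  post <- rec_occ[rec_t > burn_in]
  # batch-means standard error over the recorded grid
  n_batch <- 10L
  se <- if (length(post) >= n_batch * 2) {
    bm <- tapply(post, cut(seq_along(post), n_batch), mean)
    stats::sd(bm) / sqrt(n_batch)
  } else NA_real_
  structure(
    list(state = state,
         series = tibble(time_s = rec_t, occupancy = rec_occ),
         mean_occupancy = occ_integral / (duration - burn_in),
         se = se,
         theta_eq = equilibrium_occupancy(params, concentration),
         n_bind = n_bind, n_unbind = n_unbind,
         params = params, concentration = concentration,
         duration = duration, burn_in = burn_in),
    class = "decoration_sim")
}

#' @export
print.decoration_sim <- function(x, ...) {
  cat(sprintf(
    "<decoration_sim> %s at %g nM: mean occupancy %.4f (se %.2g), Hill equilibrium %.4f\n",
    x$params$name, x$concentration, x$mean_occupancy, x$se, x$theta_eq))
  invisible(x)
}

#' @export
#' @method tidy decoration_sim
tidy.decoration_sim <- function(x, ...) {
  tibble(concentration = x$concentration,
         mean_occupancy = x$mean_occupancy, se = x$se,
         theta_eq = x$theta_eq,
         n_bind = x$n_bind, n_unbind = x$n_unbind)
}

#' Simulated decoration titration
#'
#' Runs [simulate_decoration()] at each concentration and assembles a
#' titration table (concentration, steady-state occupancy, standard error)
#' ready for [fit_hill()]. The default duration at each point scales with
#' the equilibration time `1 / (k_on * c + k_off)`.
#'
#' @param params A [map_params()].
#' @param concentrations Vector of concentrations, nM.
#' @param geometry Lattice geometry (default 13 x 300 sites).
#' @param seed RNG seed.
#' @param relax_multiples Simulated duration in units of the relaxation
#'   time (default 45; the first third is discarded as burn-in).
#' @return A titration tibble with columns `concentration`, `response`,
#'   `sd`, `n` (`n` = number of lattice sites averaged).
#' @export
decoration_titration <- function(params, concentrations,
                                 geometry = lattice_geometry(),
                                 seed = NULL, relax_multiples = 45) {
  if (!is.null(seed)) set.seed(seed)
  map_dfr(concentrations, function(conc) {
    tau <- 1 / (params$k_on * conc + params$k_off)
    sim <- simulate_decoration(lattice_state(geometry), params, conc,
                               duration = relax_multiples * tau)
    tibble(concentration = conc, response = sim$mean_occupancy,
           sd = sim$se, n = length(sim$state$occ))
  })
}

#' Steady-state MAP binding under assay conditions
#'
#' Reproduces the single-concentration binding assay comparing MAP
#' constructs on bare microtubules, microtubules pre-decorated with rigor
#' kinesin, and subtilisin-treated microtubules (flexible tubulin tails
#' removed). Lattice (MTBD-mediated) binding is measured by a short
#' Gillespie simulation; tail-mediated binding of the P123 region is a
#' non-exclusive surface association modelled by a constant bound
#' fraction. Intensities are normalised to full-length MAP7 on the bare
#' lattice.
#'
#' @param params A [map_params()].
#' @param lattice_condition One of `"bare"`, `"kinesin_predecorated"`,
#'   `"subtilisin"`.
#' @param concentration Assay concentration, nM (default 1000).
#' @param seed Optional RNG seed.
#' @param geometry Lattice geometry for the stochastic occupancy estimate.
#' @return One-row tibble: `construct`, `condition`, `concentration`,
#'   `intensity` (normalised).
#' @export
binding_assay <- function(params,
                          lattice_condition = c("bare",
                                                "kinesin_predecorated",
                                                "subtilisin"),
                          concentration = 1000, seed = NULL,
                          geometry = lattice_geometry(n_sites = 100L)) {
  if (is.character(lattice_condition) &&
      !lattice_condition[1] %in% c("bare", "kinesin_predecorated",
                                   "subtilisin")) {
    abort(sprintf("unknown lattice condition '%s'", lattice_condition[1]),
          class = "motormap_config_error")
  }
  lattice_condition <- match.arg(lattice_condition)
  if (!is.null(seed)) set.seed(seed)

  state <- lattice_state(geometry)
  if (lattice_condition == "kinesin_predecorated") {
    state$occ[] <- OCC_CODES[["KINESIN"]]
  }
  lattice_signal <- if (params$has_mtbd &&
                        any(state$occ == OCC_CODES[["EMPTY"]])) {
    tau <- 1 / (params$k_on * concentration + params$k_off)
    simulate_decoration(state, params, concentration,
                        duration = 45 * tau)$mean_occupancy
  } else 0
  tail_signal <- if (lattice_condition == "subtilisin") 0 else
    params$tail_bound_fraction

  fl <- map_params("FL_MAP7")
  reference <- equilibrium_occupancy(fl, concentration) +
    fl$tail_bound_fraction
  tibble(construct = params$name, condition = lattice_condition,
         concentration = concentration,
         intensity = (lattice_signal + tail_signal) / reference)
}
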