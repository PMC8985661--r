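motor_preset_table <- list(
  # Direction probabilities on an unobstructed lattice: forward 0.88,
  # sideways 0.09, backward 0.03 (bare-lattice stepping statistics).
  # k_step = 1 /s corresponds to limiting ATP (~1 s dwells); k_detach0
  # gives ~60 steps per run. k_land_basal sets an arbitrary per-site
  # landing scale; run frequencies are compared as ratios.
  K560 = list(polarity = 1L, step_size_sites = 2L, k_step = 1,
              p_forward0 = 0.88, p_side0 = 0.09, p_back0 = 0.03,
              k_detach0 = 1 / 60, binds_map7 = TRUE,
              k_land_basal = 1e-3, recruitment_gain = 20,
              n_clear = NA_integer_, activity0 = 1,
              activity_theta_half = 0.1),
  K490 = list(polarity = 1L, step_size_sites = 2L, k_step = 1,
              p_forward0 = 0.88, p_side0 = 0.09, p_back0 = 0.03,
              k_detach0 = 1 / 60, binds_map7 = FALSE,
              k_land_basal = 1e-3, recruitment_gain = 0,
              n_clear = NA_integer_, activity0 = 1,
              activity_theta_half = 0.1),
  # Full-length kinesin is autoinhibited on bare lattices; activity0 is
  # calibrated so a kinesin-dynein assembly is 80% minus-end-directed at
  # 0 nM MAP7 (activity0 = 0.25 / P(5 steps survive detachment) = 0.272).
  FL_kinesin = list(polarity = 1L, step_size_sites = 2L, k_step = 1,
                    p_forward0 = 0.88, p_side0 = 0.09, p_back0 = 0.03,
                    k_detach0 = 1 / 60, binds_map7 = TRUE,
                    k_land_basal = 1e-3, recruitment_gain = 20,
                    n_clear = NA_integer_, activity0 = 0.272,
                    activity_theta_half = 0.1),
  # Dynein-dynactin-BicDR1: minus-end-directed, no MAP7 tether. A landed
  # motor scores a processive run only when n_clear consecutive sites
  # ahead are free, so the normalised run frequency falls as
  # (1 - theta)^(n_clear + 1) (one extra factor from landing-site
  # availability). n_clear = 6 is the integer for which a Langmuir fit of
  # that curve recovers the 10 nM half-inhibition constant given
  # K_D = 111 nM.
  DDR = list(polarity = -1L, step_size_sites = 1L, k_step = 1,
             p_forward0 = 0.88, p_side0 = 0.09, p_back0 = 0.03,
             k_detach0 = 1 / 60, binds_map7 = FALSE,
             k_land_basal = 1e-3, recruitment_gain = 0,
             n_clear = 6L, activity0 = 1,
             activity_theta_half = 0.1))

#' Motor construct parameter presets
#'
#' Kinetic rate set defining a motor construct. Presets: `K560`
#' (constitutively active truncated kinesin-1, binds the MAP7 projection
#' domain), `K490` (further-truncated kinesin lacking the MAP7-binding
#' stalk), `FL_kinesin` (full-length, autoinhibited kinesin relieved by
#' MAP7), and `DDR` (processive dynein-dynactin-BicDR1; minus-end-directed,
#' not tethered by MAP7, inhibited by obstacles via the `n_clear`
#' clearance rule).
#'
#' The simulated position is the labelled motor domain, which advances
#' `step_size_sites` dimer sites (16 nm for kinesin, hand-over-hand) per
#' catalytic cycle.
#'
#' @param name Preset name.
#' @param ... Named overrides of preset fields.
#' @return Object of class `motor_params`.
#' @examples
#' motor_params("K560", k_step = 100) # saturating ATP
#' @export
motor_params <- function(name = c("K560", "K490", "FL_kinesin", "DDR"),
                         ...) {
  name <- match.arg(name)
  p <- modifyList(motor_preset_table[[name]], list(...))
  psum <- p$p_forward0 + p$p_side0 + p$p_back0
  if (abs(psum - 1) > 1e-9) {
    abort("p_forward0 + p_side0 + p_back0 must equal 1",
          class = "motormap_domain_error")
  }
  if (p$k_step < 0 || p$k_detach0 < 0 || p$k_land_basal < 0) {
    abort("rates must be >= 0", class = "motormap_domain_error")
  }
  p$name <- name
  structure(p, class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf(
    "<motor_params> %s: polarity %+d, %d-site steps at %g /s, p(F/S/B) = %.2f/%.2f/%.2f\n  detach %g /s, binds MAP7 %s%s\n",
    x$name, x$polarity, x$step_size_sites, x$k_step,
    x$p_forward0, x$p_side0, x$p_back0, x$k_detach0, x$binds_map7,
    if (is.finite(x$n_clear)) sprintf(", n_clear %d", x$n_clear) else ""))
  invisible(x)
}

#' Tether (projection-domain) parameters
#'
#' Governs tethered diffusion: after a motor releases the lattice while
#' bound to a MAP7 projection domain, it attempts rebinding at rate
#' `k_rebind` to an empty site within `reach_nm` of the anchoring MAP7,
#' or the tether releases at rate `k_release` (ending the run).
#' Candidate sites are drawn with a 2D Gaussian weight centred on the
#' motor's release position (the tethered head diffuses about where it
#' let go, constrained to the anchor's reach), with axial width
#' `axial_sd_nm` and lateral width `lateral_sd_nm`. Setting both widths
#' to `Inf` recovers a uniform choice among all reachable empty sites.
#' The default widths are calibrated so that, at near-saturating MAP7
#' decoration, the detected step-direction mix reproduces the measured
#' sideways/backward stepping fractions.
#'
#' @param reach_nm Maximum rebinding distance from the anchor, nm
#'   (default 50, spanning the observed 16-64 nm trajectory jumps).
#' @param k_rebind Rebinding attempt rate, /s.
#' @param k_release Tether release rate, /s.
#' @param lateral_sd_nm Lateral Gaussian width of the rebinding kernel,
#'   nm.
#' @param axial_sd_nm Axial Gaussian width of the rebinding kernel, nm.
#' @param axial_shift_nm Axial centre of the rebinding kernel relative to
#'   the release position, nm; negative values hold the tethered motor
#'   slightly behind the blocking MTBD (the projection domain emerges at
#'   the rear of the MTBD helix), compensating the forward offset of the
#'   anchor-centred reach.
#' @return Object of class `tether_params`.
#' @export
tether_params <- function(reach_nm = 50, k_rebind = 5, k_release = 0.5,
                          lateral_sd_nm = 4.3, axial_sd_nm = 24,
                          axial_shift_nm = -16) {
  if (reach_nm <= 0) abort("reach_nm must be > 0",
                           class = "motormap_domain_error")
  if (k_rebind < 0 || k_release < 0) {
    abort("tether rates must be >= 0", class = "motormap_domain_error")
  }
  structure(list(reach_nm = reach_nm, k_rebind = k_rebind,
                 k_release = k_release, lateral_sd_nm = lateral_sd_nm,
                 axial_sd_nm = axial_sd_nm,
                 axial_shift_nm = axial_shift_nm),
            class = "tether_params")
}

#' @export
print.tether_params <- function(x, ...) {
  cat(sprintf(
    "<tether_params> reach %g nm, rebind %g /s, release %g /s, kernel sd (axial %g, lateral %g) nm\n",
    x$reach_nm, x$k_rebind, x$k_release, x$axial_sd_nm,
    x$lateral_sd_nm))
  invisible(x)
}

# Fraction of landing-competent motors at MAP7 occupancy theta.
# Autoinhibited full-length kinesin (activity0 < 1) is progressively
# activated by the projection domain.
motor_activity <- function(motor, theta) {
  if (motor$activity0 >= 1) return(rep(1, length(theta)))
  motor$activity0 + (1 - motor$activity0) *
    theta / (theta + motor$activity_theta_half)
}
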