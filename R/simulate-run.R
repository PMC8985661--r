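RUN_EVENT_LEVELS <- c("LAND", "STEP_F", "STEP_B", "STEP_S", "TETHER_JUMP",
                      "DETACH")

# Relative site offsets reachable within the tether radius. dx includes
# the helical stagger, so it depends only on (dpf, dax), not on the
# absolute site. Rebinding weights are computed at draw time because the
# kernel is centred on the motor's release position, not the anchor.
tether_offsets <- function(geometry, tether) {
  max_dpf <- min(floor(tether$reach_nm / geometry$lateral_spacing),
                 geometry$n_protofilaments - 1L)
  max_dax <- ceiling((tether$reach_nm +
                        max_dpf * abs(geometry$lateral_offset)) /
                       geometry$axial_spacing)
  grid <- expand.grid(dpf = -max_dpf:max_dpf, dax = -max_dax:max_dax)
  dx <- grid$dax * geometry$axial_spacing + grid$dpf * geometry$lateral_offset
  dy <- grid$dpf * geometry$lateral_spacing
  keep <- sqrt(dx^2 + dy^2) <= tether$reach_nm
  list(dpf = grid$dpf[keep], dax = grid$dax[keep],
       dx = dx[keep], dy = dy[keep])
}

#' Simulate a single motor run on a decorated lattice
#'
#' Event-driven (Gillespie) simulation of one processive run. The motor
#' occupies one dimer site; competing events are:
#'
#' * a stepping attempt at rate `k_step`, with direction drawn from the
#'   motor's (forward, sideways, backward) probabilities. Forward and
#'   backward steps move `step_size_sites` sites along the protofilament
#'   (16 nm for kinesin's labelled head); sideways steps move one
#'   protofilament over. An EMPTY target is taken; a MAP7-occupied target
#'   either triggers tethering (when the motor binds the MAP7 projection
#'   domain) or ends the run (obstacle-induced detachment);
#' * spontaneous detachment at rate `k_detach0`, rescued into the tethered
#'   state with probability equal to the local MAP7 occupancy within the
#'   tether reach (when tethering is available), otherwise ending the run.
#'
#' While tethered the motor keeps its last position; at rate `k_rebind` it
#' rebinds an EMPTY site within `reach_nm` of the anchoring MAP7 (recorded
#' as a `TETHER_JUMP`), unless the tether releases first (`k_release`) or
#' no reachable empty site exists. Stepping off either lattice end
#' terminates the run (absorbing boundaries). MAP7 decoration is frozen
#' during the run (quasi-static approximation).
#'
#' @param state A [lattice_state()], normally pre-decorated at binding
#'   equilibrium (see [decorate_lattice()]).
#' @param motor A [motor_params()].
#' @param tether A [tether_params()].
#' @param map A [map_params()]; determines whether tethering is available
#'   (`has_projection`) and, with `concentration`, optional decoration.
#' @param concentration If non-NULL, the lattice is decorated at the
#'   equilibrium occupancy for this concentration (nM) before the run.
#' @param start Landing site `c(protofilament, axial)`; a random EMPTY
#'   site in the central half of the lattice when NULL. Landing on a
#'   non-empty site is a precondition error.
#' @param seed Optional RNG seed.
#' @param max_time Truncate the run at this time, s.
#' @param max_productive Stop after this many productive relocation events
#'   (steps plus tether jumps); used when only run completion is scored.
#' @return Object of class `run_record`: event table (`time_s`,
#'   `protofilament`, `axial`, `x_nm`, `y_nm`, `event`), `end_reason`,
#'   `n_productive`, `run_length_nm`, `duration_s`, `mean_velocity`.
#' @export
simulate_run <- function(state, motor, tether = tether_params(),
                         map = NULL, concentration = NULL, start = NULL,
                         seed = NULL, max_time = Inf,
                         max_productive = Inf) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(concentration)) {
    if (is.null(map)) abort("concentration given without map params",
                            class = "motormap_config_error")
    state <- decorate_lattice(state, map, concentration)
  }
  geom <- state$geometry
  occ <- state$occ
  npf <- geom$n_protofilaments
  nax <- geom$n_sites
  has_tether <- isTRUE(motor$binds_map7) && !is.null(map) &&
    isTRUE(map$has_projection) && tether$k_rebind > 0
  offs <- tether_offsets(geom, tether)

  if (is.null(start)) {
    lo <- max(1L, floor(nax / 4)); hi <- min(nax, ceiling(3 * nax / 4))
    cand <- which(occ[, lo:hi, drop = FALSE] == OCC_CODES[["EMPTY"]])
    if (!length(cand)) abort("no empty landing site available",
                             class = "motormap_precondition_error")
    s <- if (length(cand) > 1L) sample(cand, 1L) else cand
    pf <- (s - 1L) %% npf + 1L
    ax <- (s - 1L) %/% npf + lo
  } else {
    pf <- as.integer(start[1]); ax <- as.integer(start[2])
    check_site_bounds(geom, pf, ax)
    if (occ[pf, ax] != OCC_CODES[["EMPTY"]]) {
      abort("landing site is not empty",
            class = "motormap_precondition_error")
    }
  }
  motor_code <- if (motor$polarity > 0) OCC_CODES[["KINESIN"]] else
    OCC_CODES[["DYNEIN"]]
  occ[pf, ax] <- motor_code

  cap <- 256L
  ev_t <- numeric(cap); ev_pf <- integer(cap); ev_ax <- integer(cap)
  ev_tag <- integer(cap)
  ne <- 0L
  push <- function(t, p, a, tag) {
    if (ne == cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_pf) <<- cap
      length(ev_ax) <<- cap; length(ev_tag) <<- cap
    }
    ne <<- ne + 1L
    ev_t[ne] <<- t; ev_pf[ne] <<- p; ev_ax[ne] <<- a; ev_tag[ne] <<- tag
  }
  t_now <- 0
  push(0, pf, ax, 1L)
  n_productive <- 0L
  end_reason <- NULL
  sss <- motor$step_size_sites * motor$polarity
  k_tot <- motor$k_step + motor$k_detach0
  if (k_tot <= 0 && !is.finite(max_time)) {
    abort("k_step + k_detach0 is zero and max_time is infinite",
          class = "motormap_config_error")
  }

  # sample an empty site within reach of the anchor, weighted by the 2D
  # Gaussian kernel centred on the release position; returns c(pf, ax)
  # or NULL
  inv2ax <- if (is.finite(tether$axial_sd_nm)) {
    1 / (2 * tether$axial_sd_nm^2)
  } else 0
  inv2lat <- if (is.finite(tether$lateral_sd_nm)) {
    1 / (2 * tether$lateral_sd_nm^2)
  } else 0
  site_x <- function(p, a) (a - 1) * geom$axial_spacing +
    (p - 1) * geom$lateral_offset
  draw_rebind <- function(anchor_pf, anchor_ax, from_pf, from_ax) {
    tpf <- anchor_pf + offs$dpf
    tax <- anchor_ax + offs$dax
    ok <- tpf >= 1L & tpf <= npf & tax >= 1L & tax <= nax
    ok[ok] <- occ[cbind(tpf[ok], tax[ok])] == OCC_CODES[["EMPTY"]]
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    i <- if (length(idx) > 1L) {
      dxr <- site_x(tpf[idx], tax[idx]) - site_x(from_pf, from_ax) -
        tether$axial_shift_nm
      dyr <- (tpf[idx] - from_pf) * geom$lateral_spacing
      sample(idx, 1L, prob = exp(-dxr^2 * inv2ax - dyr^2 * inv2lat))
    } else idx
    c(tpf[i], tax[i])
  }
  local_map7_fraction <- function(at_pf, at_ax) {
    tpf <- at_pf + offs$dpf
    tax <- at_ax + offs$dax
    ok <- tpf >= 1L & tpf <= npf & tax >= 1L & tax <= nax
    if (!any(ok)) return(0)
    mean(occ[cbind(tpf[ok], tax[ok])] == OCC_CODES[["MAP7"]])
  }
  # tethered phase: returns TRUE when the motor rebinds, FALSE when the
  # run ends (setting end_reason)
  tether_phase <- function(anchor_pf, anchor_ax, from_pf = pf,
                           from_ax = ax) {
    repeat {
      dt <- rexp(1L, tether$k_rebind + tether$k_release)
      t_now <<- t_now + dt
      if (t_now > max_time) {
        t_now <<- max_time; end_reason <<- "max_time"; return(FALSE)
      }
      if (runif(1L) * (tether$k_rebind + tether$k_release) <
          tether$k_release) {
        end_reason <<- "tether_release"; return(FALSE)
      }
      site <- draw_rebind(anchor_pf, anchor_ax, from_pf, from_ax)
      if (is.null(site)) {
        end_reason <<- "no_rebind_site"; return(FALSE)
      }
      pf <<- site[1]; ax <<- site[2]
      stopifnot(occ[pf, ax] == OCC_CODES[["EMPTY"]])  # exclusion invariant
      occ[pf, ax] <<- motor_code
      push(t_now, pf, ax, 5L)
      n_productive <<- n_productive + 1L
      return(TRUE)
    }
  }

  repeat {
    if (n_productive >= max_productive) { end_reason <- "max_productive"; break }
    dt <- if (k_tot > 0) rexp(1L, k_tot) else Inf
    if (t_now + dt > max_time) { t_now <- max_time
      end_reason <- "max_time"; break }
    t_now <- t_now + dt
    if (runif(1L) * k_tot < motor$k_step) {
      u <- runif(1L)
      if (u < motor$p_forward0) {
        tpf <- pf; tax <- ax + sss; tag <- 2L
      } else if (u < motor$p_forward0 + motor$p_side0) {
        lat <- c(-1L, 1L)[c(pf > 1L, pf < npf)]
        if (!length(lat)) next  # single-protofilament lattice: no target
        tpf <- pf + if (length(lat) > 1L) sample(lat, 1L) else lat
        tax <- ax; tag <- 4L
      } else {
        tpf <- pf; tax <- ax - sss; tag <- 3L
      }
      if (tax < 1L || tax > nax) {
        occ[pf, ax] <- OCC_CODES[["EMPTY"]]
        end_reason <- "boundary"; break
      }
      tocc <- occ[tpf, tax]
      if (tocc == OCC_CODES[["EMPTY"]]) {
        occ[pf, ax] <- OCC_CODES[["EMPTY"]]
        pf <- tpf; ax <- tax
        occ[pf, ax] <- motor_code
        push(t_now, pf, ax, tag)
        n_productive <- n_productive + 1L
      } else if (tocc == OCC_CODES[["MAP7"]] && has_tether) {
        occ[pf, ax] <- OCC_CODES[["EMPTY"]]
        if (!tether_phase(tpf, tax)) break
      } else {
        occ[pf, ax] <- OCC_CODES[["EMPTY"]]
        end_reason <- "obstacle"; break
      }
    } else {
      # spontaneous detachment; rescue by a nearby projection domain
      theta_local <- if (has_tether) local_map7_fraction(pf, ax) else 0
      occ[pf, ax] <- OCC_CODES[["EMPTY"]]
      if (has_tether && runif(1L) < theta_local) {
        # anchor at a MAP7 site within reach of the point of release
        tpf <- pf + offs$dpf; tax <- ax + offs$dax
        ok <- tpf >= 1L & tpf <= npf & tax >= 1L & tax <= nax
        ok[ok] <- occ[cbind(tpf[ok], tax[ok])] == OCC_CODES[["MAP7"]]
        if (!any(ok)) { end_reason <- "spontaneous"; break }
        idx <- which(ok)
        i <- if (length(idx) > 1L) sample(idx, 1L) else idx
        if (!tether_phase(tpf[i], tax[i])) break
      } else {
        end_reason <- "spontaneous"; break
      }
    }
  }
  if (occ[pf, ax] == motor_code) occ[pf, ax] <- OCC_CODES[["EMPTY"]]
  push(t_now, pf, ax, 6L)

  state$occ <- occ
  idx <- seq_len(ne)
  pos <- site_position(geom, ev_pf[idx], ev_ax[idx])
  events <- tibble(time_s = ev_t[idx],
                   protofilament = ev_pf[idx], axial = ev_ax[idx],
                   x_nm = pos$x_nm, y_nm = pos$y_nm,
                   event = RUN_EVENT_LEVELS[ev_tag[idx]])
  run_length <- abs(events$x_nm[ne] - events$x_nm[1])
  duration <- events$time_s[ne]
  structure(
    list(events = events, end_reason = end_reason,
         n_productive = n_productive,
         run_length_nm = run_length, duration_s = duration,
         mean_velocity = if (duration > 0) run_length / duration else 0,
         motor = motor$name, state = state),
    class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf(
    "<run_record> %s: %d productive events, %.0f nm in %.2f s (%.0f nm/s), ended by %s\n",
    x$motor, x$n_productive, x$run_length_nm, x$duration_s,
    x$mean_velocity, x$end_reason))
  invisible(x)
}

#' @export
#' @method as_tibble run_record
as_tibble.run_record <- function(x, ...) x$events

#' Write run-record event tables as CSV
#'
#' One row per event, columns `time_s`, `pf`, `axial`, `x_nm`, `y_nm`,
#' `event_tag`, `run_id`.
#'
#' @param records A `run_record` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_records_csv <- function(records, path) {
  if (inherits(records, "run_record")) records <- list(records)
  tab <- map_dfr(seq_along(records), function(i) {
    ev <- records[[i]]$events
    tibble(time_s = ev$time_s, pf = ev$protofilament, axial = ev$axial,
           x_nm = ev$x_nm, y_nm = ev$y_nm, event_tag = ev$event,
           run_id = i)
  })
  readr::write_csv(tab, path)
  invisible(path)
}
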