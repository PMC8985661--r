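#' Microtubule lattice geometry
#'
#' Describes the tubulin-dimer site grid of a microtubule unrolled into 2D
#' image coordinates: `n_protofilaments` rows of `n_sites` dimer sites, with
#' an 8-nm axial repeat, a per-protofilament axial stagger of 12/13 nm (the
#' 3-start helical rise of a 13-protofilament lattice) and 6-nm lateral
#' spacing between protofilament rows. Protofilaments are laid out on a line
#' rather than a cylinder because downstream trajectory analyses operate in
#' 2D image coordinates; the seam is therefore never crossed and
#' `seam_index` is retained only as metadata.
#'
#' @param n_protofilaments Number of protofilaments (default 13).
#' @param n_sites Number of tubulin-dimer sites per protofilament.
#' @param axial_spacing Axial length of one dimer site, nm (default 8).
#' @param lateral_offset Axial stagger between adjacent protofilaments, nm
#'   (default 12/13, the 3-start helix rise divided by 13).
#' @param lateral_spacing Lateral distance between protofilament rows, nm
#'   (default 6).
#' @param seam_index Protofilament index of the lattice seam (metadata only).
#'
#' @return An object of class `lattice_geometry`.
#' @examples
#' geom <- lattice_geometry(n_sites = 100)
#' site_position(geom, 1, 3) # 16 nm along the axis
#' @export
lattice_geometry <- function(n_protofilaments = 13L, n_sites = 300L,
                             axial_spacing = 8, lateral_offset = 12 / 13,
                             lateral_spacing = 6,
                             seam_index = n_protofilaments) {
  if (n_protofilaments < 1 || n_sites < 1) {
    abort("n_protofilaments and n_sites must be >= 1",
          class = "motormap_domain_error")
  }
  if (axial_spacing <= 0 || lateral_spacing <= 0) {
    abort("axial_spacing and lateral_spacing must be > 0",
          class = "motormap_domain_error")
  }
  structure(
    list(n_protofilaments = as.integer(n_protofilaments),
         n_sites = as.integer(n_sites),
         axial_spacing = axial_spacing,
         lateral_offset = lateral_offset,
         lateral_spacing = lateral_spacing,
         seam_index = as.integer(seam_index)),
    class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf(
    "<lattice_geometry> %d protofilaments x %d sites (%.1f nm axial, %.1f nm lateral, %.3f nm stagger)\n",
    x$n_protofilaments, x$n_sites, x$axial_spacing, x$lateral_spacing,
    x$lateral_offset))
  invisible(x)
}

check_site_bounds <- function(geometry, protofilament, axial) {
  bad <- protofilament < 1 | protofilament > geometry$n_protofilaments |
    axial < 1 | axial > geometry$n_sites
  if (any(bad)) {
    abort(sprintf("site index out of lattice bounds (pf %s, axial %s)",
                  paste(protofilament[bad], collapse = ","),
                  paste(axial[bad], collapse = ",")),
          class = "motormap_bounds_error")
  }
  invisible(TRUE)
}

#' 2D position of lattice sites
#'
#' Maps (protofilament, axial) site indices (1-based) to on-axis /
#' off-axis coordinates in nm. Site (1, 1) is the origin. The on-axis
#' coordinate includes the helical stagger `lateral_offset` per
#' protofilament.
#'
#' @param geometry A [lattice_geometry()].
#' @param protofilament,axial Integer site indices (vectorised, recycled).
#' @return A tibble with columns `protofilament`, `axial`, `x_nm` (on-axis),
#'   `y_nm` (off-axis).
#' @export
site_position <- function(geometry, protofilament, axial) {
  n <- max(length(protofilament), length(axial))
  protofilament <- rep_len(as.integer(protofilament), n)
  axial <- rep_len(as.integer(axial), n)
  check_site_bounds(geometry, protofilament, axial)
  tibble(
    protofilament = protofilament, axial = axial,
    x_nm = (axial - 1) * geometry$axial_spacing +
      (protofilament - 1) * geometry$lateral_offset,
    y_nm = (protofilament - 1) * geometry$lateral_spacing)
}

#' Lattice occupancy state
#'
#' Creates an empty lattice: one occupant tag per tubulin-dimer site, one of
#' `EMPTY`, `MAP7`, `KINESIN`, `DYNEIN`. Exactly one tag per site at all
#' times -- the mutual-exclusion rule at the core of the model: MAP7's
#' microtubule-binding helix and a motor head cannot share a dimer site.
#'
#' @param geometry A [lattice_geometry()].
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(geometry = lattice_geometry()) {
  structure(
    list(geometry = geometry,
         occ = matrix(0L, nrow = geometry$n_protofilaments,
                      ncol = geometry$n_sites)),
    class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  fr <- occupancy_fractions(x)
  cat(sprintf("<lattice_state> %d x %d sites: %s\n",
              x$geometry$n_protofilaments, x$geometry$n_sites,
              paste(sprintf("%s %.3f", fr$occupant, fr$fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Occupant of lattice sites
#'
#' @param state A [lattice_state()].
#' @param protofilament,axial Site indices (vectorised).
#' @return Character vector of occupant tags.
#' @export
site_occupant <- function(state, protofilament, axial) {
  check_site_bounds(state$geometry, protofilament, axial)
  OCC_LEVELS[state$occ[cbind(protofilament, axial)] + 1L]
}

#' Place or remove an occupant on a lattice site
#'
#' `occupy()` places `occupant` on an EMPTY site; attempting to occupy a
#' non-empty site raises a `motormap_exclusion_error` -- the competitive
#' binding rule is never silently ignored. `vacate()` removes an occupant,
#' checking that the site indeed holds the stated tag.
#'
#' @param state A [lattice_state()].
#' @param protofilament,axial Site index.
#' @param occupant One of `"MAP7"`, `"KINESIN"`, `"DYNEIN"`.
#' @return The updated `lattice_state`.
#' @export
occupy <- function(state, protofilament, axial, occupant) {
  check_site_bounds(state$geometry, protofilament, axial)
  occupant <- match.arg(occupant, OCC_LEVELS[-1])
  if (state$occ[protofilament, axial] != OCC_CODES[["EMPTY"]]) {
    abort(sprintf(
      "exclusion violation: site (%d, %d) already holds %s",
      protofilament, axial, site_occupant(state, protofilament, axial)),
      class = "motormap_exclusion_error")
  }
  state$occ[protofilament, axial] <- OCC_CODES[[occupant]]
  state
}

#' @rdname occupy
#' @export
vacate <- function(state, protofilament, axial, occupant) {
  check_site_bounds(state$geometry, protofilament, axial)
  occupant <- match.arg(occupant, OCC_LEVELS[-1])
  if (state$occ[protofilament, axial] != OCC_CODES[[occupant]]) {
    abort(sprintf(
      "cannot vacate %s from site (%d, %d) holding %s",
      occupant, protofilament, axial,
      site_occupant(state, protofilament, axial)),
      class = "motormap_exclusion_error")
  }
  state$occ[protofilament, axial] <- OCC_CODES[["EMPTY"]]
  state
}

#' Sites within a Euclidean radius of a query site
#'
#' Returns all lattice sites whose 2D (on-axis, off-axis) distance from the
#' query site is at most `radius_nm`, excluding the query site itself,
#' sorted by distance, then protofilament, then axial index. Used for
#' tethered rebinding of motors near a MAP7 anchor.
#'
#' @param state A [lattice_state()].
#' @param protofilament,axial Query site index.
#' @param radius_nm Search radius in nm (>= 0).
#' @return Tibble with `protofilament`, `axial`, `x_nm`, `y_nm`,
#'   `distance_nm`, `occupant`.
#' @export
neighbors_within <- function(state, protofilament, axial, radius_nm) {
  if (radius_nm < 0) abort("radius_nm must be >= 0",
                           class = "motormap_domain_error")
  geom <- state$geometry
  check_site_bounds(geom, protofilament, axial)
  pf <- rep(seq_len(geom$n_protofilaments), times = geom$n_sites)
  ax <- rep(seq_len(geom$n_sites), each = geom$n_protofilaments)
  x <- (ax - 1) * geom$axial_spacing + (pf - 1) * geom$lateral_offset
  y <- (pf - 1) * geom$lateral_spacing
  x0 <- (axial - 1) * geom$axial_spacing +
    (protofilament - 1) * geom$lateral_offset
  y0 <- (protofilament - 1) * geom$lateral_spacing
  d <- sqrt((x - x0)^2 + (y - y0)^2)
  keep <- d <= radius_nm & !(pf == protofilament & ax == axial)
  out <- tibble(protofilament = pf[keep], axial = ax[keep],
                x_nm = x[keep], y_nm = y[keep], distance_nm = d[keep],
                occupant = OCC_LEVELS[state$occ[cbind(pf[keep], ax[keep])] + 1L])
  arrange(out, .data$distance_nm, .data$protofilament, .data$axial)
}

#' Occupancy fractions by tag
#'
#' @param state A [lattice_state()].
#' @return Tibble with `occupant`, `count`, `fraction`; fractions sum to 1.
#' @export
occupancy_fractions <- function(state) {
  counts <- tabulate(state$occ + 1L, nbins = length(OCC_LEVELS))
  tibble(occupant = OCC_LEVELS, count = counts,
         fraction = counts / length(state$occ))
}

#' @export
#' @method as_tibble lattice_state
as_tibble.lattice_state <- function(x, ...) {
  geom <- x$geometry
  pf <- rep(seq_len(geom$n_protofilaments), times = geom$n_sites)
  ax <- rep(seq_len(geom$n_sites), each = geom$n_protofilaments)
  pos <- site_position(geom, pf, ax)
  mutate(pos, occupant = OCC_LEVELS[x$occ[cbind(pf, ax)] + 1L])
}

#' Write a lattice snapshot as CSV
#'
#' One row per site with columns `protofilament`, `axial`, `occupant`.
#'
#' @param state A [lattice_state()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lattice_csv <- function(state, path) {
  readr::write_csv(
    as_tibble(state)[, c("protofilament", "axial", "occupant")], path)
  invisible(path)
}

#' Decorate a lattice with MAP7 at binding equilibrium
#'
#' Draws each EMPTY site as MAP7-bound independently with probability equal
#' to the equilibrium occupancy at the given concentration (quasi-static
#' snapshot used to freeze decoration during a motor run). Constructs
#' without a microtubule-binding domain leave the lattice untouched.
#'
#' @param state A [lattice_state()].
#' @param params A [map_params()] preset.
#' @param concentration MAP concentration, nM.
#' @param seed Optional RNG seed.
#' @return The decorated `lattice_state`.
#' @export
decorate_lattice <- function(state, params, concentration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- equilibrium_occupancy(params, concentration)
  if (theta > 0) {
    empty <- state$occ == OCC_CODES[["EMPTY"]]
    hit <- empty & (matrix(runif(length(state$occ)), nrow = nrow(state$occ))
                    < theta)
    state$occ[hit] <- OCC_CODES[["MAP7"]]
  }
  state
}
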