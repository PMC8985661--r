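#' Measurement noise model for synthetic data
#'
#' Additive Gaussian localization noise for single-particle trajectories
#' and multiplicative Gaussian noise for titration intensities.
#'
#' @param localization_sd Per-frame localization error, nm (default 2,
#'   nanometer-precision tracking).
#' @param frame_interval Camera frame interval, s (default 0.1; with ~1-s
#'   limiting-ATP dwells this gives ~10 frames per plateau).
#' @param intensity_cv Fractional (coefficient-of-variation) noise on
#'   titration responses (default 0.1).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(localization_sd = 2, frame_interval = 0.1,
                        intensity_cv = 0.1) {
  if (localization_sd < 0 || intensity_cv < 0 || frame_interval <= 0) {
    abort("noise parameters must be non-negative, frame_interval > 0",
          class = "motormap_domain_error")
  }
  structure(list(localization_sd = localization_sd,
                 frame_interval = frame_interval,
                 intensity_cv = intensity_cv), class = "noise_model")
}

#' Synthetic camera trajectory from a simulated run
#'
#' Samples the run's piecewise-constant labelled-head position at the
#' camera frame interval and adds independent Gaussian localization noise
#' to both coordinates. The ground-truth relocation events falling inside
#' the sampled window are retained as a hidden `truth` attribute (and a
#' sidecar file on disk; see [write_trajectory_csv()]) so detection tests
#' can score against them without leaking truth into the analysis input.
#'
#' @param run A `run_record` from [simulate_run()].
#' @param noise A [noise_model()].
#' @param seed Optional RNG seed.
#' @return A `trajectory` tibble (`t_s`, `x_nm`, `y_nm`) with attributes
#'   `frame_interval`, `noise_sd` and `truth` (tibble of true event
#'   times, frames, positions and displacements).
#' @export
make_trajectory <- function(run, noise = noise_model(), seed = NULL) {
  ev <- run$events
  if (!nrow(ev)) abort("empty run record",
                       class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)
  dt <- noise$frame_interval
  t <- seq(0, run$duration_s, by = dt)
  x <- approx(ev$time_s, ev$x_nm, xout = t, method = "constant",
              rule = 2, ties = "ordered")$y
  y <- approx(ev$time_s, ev$y_nm, xout = t, method = "constant",
              rule = 2, ties = "ordered")$y
  n <- length(t)
  traj <- tibble(
    t_s = t,
    x_nm = x + rnorm(n, 0, noise$localization_sd),
    y_nm = y + rnorm(n, 0, noise$localization_sd))
  moves <- ev[ev$event %in% c("STEP_F", "STEP_B", "STEP_S",
                              "TETHER_JUMP") &
                ev$time_s <= max(t), , drop = FALSE]
  truth <- tibble(
    time_s = moves$time_s,
    frame = pmin(floor(moves$time_s / dt) + 1L, n),
    x_nm = moves$x_nm, y_nm = moves$y_nm, event = moves$event)
  idx <- match(paste(moves$time_s, moves$event),
               paste(ev$time_s, ev$event))
  truth$dx_nm <- moves$x_nm - ev$x_nm[idx - 1L]
  truth$dy_nm <- moves$y_nm - ev$y_nm[idx - 1L]
  structure(traj, frame_interval = dt,
            noise_sd = noise$localization_sd, truth = truth,
            class = c("trajectory", class(traj)))
}

#' Ground-truth annotation of a synthetic trajectory
#'
#' @param traj A `trajectory` from [make_trajectory()] or
#'   [read_trajectory_csv()].
#' @return The hidden truth tibble, or NULL if absent.
#' @export
trajectory_truth <- function(traj) attr(traj, "truth")

#' Read and write trajectory CSV files
#'
#' Trajectories are stored as CSV with columns `t_s`, `x_nm`, `y_nm`.
#' Ground truth, when present, goes to a sidecar file with the same
#' basename and suffix `.truth.csv`, never into the analysis input.
#'
#' @param traj A `trajectory`.
#' @param path CSV path.
#' @param truth Write/read the sidecar (default TRUE; reading tolerates a
#'   missing sidecar).
#' @return `path` (write) or a `trajectory` (read).
#' @export
write_trajectory_csv <- function(traj, path, truth = TRUE) {
  readr::write_csv(as.data.frame(traj[, c("t_s", "x_nm", "y_nm")]), path)
  tr <- trajectory_truth(traj)
  if (truth && !is.null(tr)) {
    readr::write_csv(tr, sub("\\.csv$", ".truth.csv", path))
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, truth = TRUE) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  tp <- sub("\\.csv$", ".truth.csv", path)
  tr <- if (truth && file.exists(tp)) {
    readr::read_csv(tp, show_col_types = FALSE)
  } else NULL
  dt <- if (nrow(traj) > 1) traj$t_s[2] - traj$t_s[1] else NA_real_
  structure(traj, frame_interval = dt, noise_sd = NA_real_, truth = tr,
            class = c("trajectory", class(traj)))
}

#' Synthetic titration table
#'
#' Draws replicate responses from a named dose-response model with
#' multiplicative Gaussian noise and summarises them per concentration as
#' mean, standard deviation and replicate count -- the structure of a
#' binding or motility titration.
#'
#' @param generator_model `"hill"`, `"biphasic"` or `"langmuir"`.
#' @param params Named list of curve parameters (see [hill_curve()] and
#'   relatives).
#' @param concentrations Concentrations, nM (>= 1).
#' @param noise A [noise_model()]; `intensity_cv` sets the noise.
#' @param n_per_point Replicates per concentration (>= 2).
#' @param seed Optional RNG seed.
#' @return Titration tibble: `concentration`, `response`, `sd`, `n`.
#' @export
make_titration <- function(generator_model = c("hill", "biphasic",
                                               "langmuir"),
                           params, concentrations,
                           noise = noise_model(), n_per_point = 5,
                           seed = NULL) {
  generator_model <- match.arg(generator_model)
  if (!length(concentrations)) abort("need >= 1 concentration",
                                     class = "motormap_domain_error")
  if (n_per_point < 2) abort("n_per_point must be >= 2",
                             class = "motormap_domain_error")
  if (!is.null(seed)) set.seed(seed)
  curve <- switch(generator_model, hill = hill_curve,
                  biphasic = biphasic_hill_curve,
                  langmuir = langmuir_inhibition_curve)
  truth <- do.call(curve, c(list(concentrations), params))
  map_dfr(seq_along(concentrations), function(i) {
    reps <- truth[i] * (1 + rnorm(n_per_point, 0, noise$intensity_cv))
    tibble(concentration = concentrations[i], response = mean(reps),
           sd = sd(reps), n = n_per_point)
  })
}

#' Read and write titration CSV files
#'
#' Header columns `concentration_nM`, `response`, `sd`, `n`.
#'
#' @param table A titration tibble.
#' @param path CSV path.
#' @return `path` (write) or a titration tibble (read).
#' @export
write_titration_csv <- function(table, path) {
  out <- table
  names(out)[names(out) == "concentration"] <- "concentration_nM"
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  names(tab)[names(tab) == "concentration_nM"] <- "concentration"
  tab
}

#' Rasterise runs into a kymograph
#'
#' Deterministically rasterises on-axis position versus time for a set of
#' runs into a 2D intensity array (rows = time lines, columns = position
#' pixels), the standard kymograph representation of motility assays.
#'
#' @param records A `run_record` or list of them.
#' @param pixel_nm Pixel size along the axis, nm (> 0).
#' @param line_interval_s Time per kymograph line, s.
#' @param t_max Total time spanned (default: longest run).
#' @param x_range Axis range `c(min, max)` in nm (default: data range).
#' @return Integer matrix of class `kymograph` with attributes
#'   `pixel_nm`, `line_interval_s`, `x0_nm`.
#' @export
make_kymograph <- function(records, pixel_nm = 50, line_interval_s = 0.5,
                           t_max = NULL, x_range = NULL) {
  if (pixel_nm <= 0) abort("pixel_nm must be > 0",
                           class = "motormap_domain_error")
  if (inherits(records, "run_record")) records <- list(records)
  t_max <- t_max %||% max(map_dbl(records, "duration_s"))
  xs <- unlist(lapply(records, function(r) r$events$x_nm))
  x_range <- x_range %||% range(xs)
  n_lines <- max(1L, ceiling(t_max / line_interval_s))
  n_pix <- max(1L, ceiling(diff(x_range) / pixel_nm) + 1L)
  img <- matrix(0L, nrow = n_lines, ncol = n_pix)
  lt <- (seq_len(n_lines) - 0.5) * line_interval_s
  for (r in records) {
    ok <- lt <= r$duration_s
    if (!any(ok)) next
    x <- approx(r$events$time_s, r$events$x_nm, xout = lt[ok],
                method = "constant", rule = 2, ties = "ordered")$y
    px <- pmin(pmax(floor((x - x_range[1]) / pixel_nm) + 1L, 1L), n_pix)
    rows <- which(ok)
    for (i in seq_along(rows)) img[rows[i], px[i]] <- img[rows[i], px[i]] + 1L
  }
  structure(img, pixel_nm = pixel_nm, line_interval_s = line_interval_s,
            x0_nm = x_range[1], class = c("kymograph", "matrix", "array"))
}

#' Write a kymograph as a 16-bit grayscale TIFF
#'
#' Requires the `tiff` package.
#'
#' @param kymo A `kymograph`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(kymo, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the tiff package is required to write TIFF files",
          class = "motormap_config_error")
  }
  img <- unclass(kymo)
  img <- img / max(1L, max(img))
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
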