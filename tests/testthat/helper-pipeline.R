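# Shared end-to-end stepping pipeline: simulate K560 runs on a lattice
# decorated at `conc` nM full-length MAP7, image them with 2-nm / 0.1-s
# localization noise, detect steps, and pool the step tables. Results
# are cached per (conc, n_runs, seed) so several tests can share one
# computation.
.pipeline_cache <- new.env(parent = emptyenv())

step_pipeline <- function(conc, n_runs, seed, penalty = 1.3,
                          max_time = 120) {
  key <- paste(conc, n_runs, seed, penalty, max_time, sep = "_")
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  set.seed(seed)
  fl <- map_params("FL_MAP7")
  k5 <- motor_params("K560")
  geom <- lattice_geometry(n_sites = 300)
  steps <- vector("list", n_runs)
  truths <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rec <- simulate_run(lattice_state(geom), k5, map = fl,
                        concentration = conc, max_time = max_time)
    traj <- make_trajectory(rec, noise_model())
    if (nrow(traj) < 10) next
    st <- tryCatch(find_steps(traj, penalty = penalty),
                   error = function(e) NULL)
    if (!is.null(st) && nrow(st)) steps[[i]] <- as.data.frame(st)
    truths[[i]] <- trajectory_truth(traj)
  }
  out <- list(steps = dplyr::bind_rows(steps),
              truth = dplyr::bind_rows(truths))
  .pipeline_cache[[key]] <- out
  out
}
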