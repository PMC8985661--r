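# Exact dynamic-programming changepoint oracle: minimum-RSS piecewise
# constant fit with exactly k changepoints (k + 1 plateaus). Independent
# of the greedy step finder; O(k n^2), for small traces only.
dp_changepoints <- function(y, k) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  seg_cost <- function(a, b) {
    s <- cs[b + 1] - cs[a]
    s2 <- cs2[b + 1] - cs2[a]
    s2 - s^2 / (b - a + 1)
  }
  if (k == 0) return(integer(0))
  D <- matrix(Inf, k + 1, n)
  P <- matrix(0L, k + 1, n)
  D[1, ] <- vapply(1:n, function(b) seg_cost(1, b), numeric(1))
  for (j in 2:(k + 1)) {
    for (b in j:n) {
      a <- j:b  # first index of the last plateau
      cand <- D[j - 1, a - 1] + seg_cost(a, b)
      i <- which.min(cand)
      D[j, b] <- cand[i]
      P[j, b] <- a[i]
    }
  }
  cps <- integer(k)
  b <- n
  for (j in (k + 1):2) {
    cps[j - 1] <- P[j, b]
    b <- P[j, b] - 1L
  }
  sort(cps)
}

# brute-force Euclidean neighbour enumeration, independent of
# neighbors_within()
brute_neighbors <- function(geom, pf0, ax0, radius) {
  out <- 0L
  x0 <- (ax0 - 1) * geom$axial_spacing + (pf0 - 1) * geom$lateral_offset
  y0 <- (pf0 - 1) * geom$lateral_spacing
  for (p in seq_len(geom$n_protofilaments)) {
    for (a in seq_len(geom$n_sites)) {
      if (p == pf0 && a == ax0) next
      x <- (a - 1) * geom$axial_spacing + (p - 1) * geom$lateral_offset
      y <- (p - 1) * geom$lateral_spacing
      if (sqrt((x - x0)^2 + (y - y0)^2) <= radius) out <- out + 1L
    }
  }
  out
}

# minimal run_record stand-in for summary-statistics tests
fake_run_record <- function(run_length_nm, duration_s) {
  structure(list(run_length_nm = run_length_nm, duration_s = duration_s,
                 n_productive = NA_integer_, end_reason = "spontaneous",
                 mean_velocity = run_length_nm / duration_s,
                 motor = "K560",
                 events = tibble::tibble(
                   time_s = c(0, duration_s),
                   protofilament = c(6L, 6L), axial = c(1L, 1L),
                   x_nm = c(0, run_length_nm), y_nm = c(0, 0),
                   event = c("LAND", "DETACH"))),
            class = "run_record")
}
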