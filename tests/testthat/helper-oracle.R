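# Independent brute-force trajectory classifier used as an oracle.
# Enumerates all interior local extrema of z and applies the class
# definitions literally; shares no code with classify_trajectory().
oracle_classify <- function(traj, rel_tol = 0.01) {
  z <- traj$z
  z0 <- traj$z0
  zi <- traj$z_inf
  band <- rel_tol * z0
  if (abs(zi - z0) <= band && max(abs(z - z0)) <= band) {
    return("no-response")
  }
  dz <- diff(z)
  turn <- which(dz[-length(dz)] * dz[-1] < 0) + 1L
  lo <- min(z0, zi)
  hi <- max(z0, zi)
  tol <- rel_tol * abs(zi - z0)
  sig <- turn[z[turn] > hi + tol | z[turn] < lo - tol]
  # include the endpoints of flat plateaus missed by strict sign changes
  if (max(z) > hi + tol && !any(z[sig] > hi + tol)) {
    sig <- c(sig, which.max(z))
  }
  if (min(z) < lo - tol && !any(z[sig] < lo - tol)) {
    sig <- c(sig, which.min(z))
  }
  if (length(sig) == 0) {
    if (abs(zi - z0) <= band) return("ambiguous")
    return(if (zi > z0) "G+" else "G-")
  }
  beyond <- which(abs(z - z0) > band)
  if (length(beyond) == 0) return("ambiguous")
  slope <- if (z[beyond[1]] > z0) "+" else "-"
  if (zi > z0 + band) {
    tgt <- "+"
  } else if (zi < z0 - band) {
    tgt <- "-"
  } else if (zi != z0) {
    tgt <- if (zi > z0) "+" else "-"
  } else {
    return("ambiguous")
  }
  paste0("P", slope, "T", tgt)
}

# random toy-trajectory case with known ground truth
random_toy_case <- function() {
  shape <- sample(ffl_classes(), 1)
  z0 <- exp(runif(1, -1, 2))
  delta <- z0 * runif(1, 0.2, 2)
  grader <- substr(shape, 1, 1) == "G"
  sgn <- if (grader) substr(shape, 2, 2) else substr(shape, 4, 4)
  z_inf <- if (sgn == "+") z0 + delta else max(z0 - delta, 0.05 * z0)
  ph <- if (grader) NULL else delta * runif(1, 0.5, 3) + 0.1 * z0
  if (!grader && substr(shape, 2, 2) == "-") {
    # keep downward pulses positive
    ph <- min(ph, 0.9 * min(z0, z_inf))
    if (ph <= 2 * 0.01 * max(z0, abs(z_inf - z0))) return(NULL)
  }
  traj <- toy_trajectory(shape, z0 = z0, z_inf = z_inf, pulse_height = ph,
                         n = sample(300:800, 1),
                         t_max = runif(1, 5, 20))
  list(shape = shape, traj = traj)
}
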