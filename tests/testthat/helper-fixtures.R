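# shared fixtures and independent oracles, built in code at test time

default_geom <- function() transwell_geometry()

# the three-substrate dosing mixture used for the passive/P-gp probes
mixture_a <- function(final = 50) {
  donor_solution(list(
    probe_substrate("atenolol", "paracellular", 50, c(water = 0.5, DMSO = 0.5)),
    probe_substrate("propranolol", "transcellular", 50, c(DMSO = 1)),
    probe_substrate("fexofenadine", "P-gp", 100, c(DMSO = 1))),
    final_concentration = final)
}

mixture_c <- function(final = 50) {
  donor_solution(list(
    probe_substrate("metformin", "OCT", 100, c(water = 1)),
    probe_substrate("methotrexate", "OAT", 100, c(DMSO = 1))),
    final_concentration = final)
}

# wrap raw (times, q) into the container fit_linear_window consumes
make_ct <- function(times, q, censored = rep(FALSE, length(times))) {
  structure(list(times = times, q = q, censored = censored, unit = "nM.mL"),
            class = "cumulative_transport")
}

# independent mass-balance bookkeeping oracle: walk the schedule event by
# event, tracking the receiver amount and everything removed so far
oracle_cumulative <- function(values, v_receiver, removed_volumes) {
  n <- length(values)
  q <- numeric(n)
  removed_total <- 0
  for (k in seq_len(n)) {
    q[k] <- values[k] * v_receiver + removed_total
    removed_total <- removed_total + values[k] * removed_volumes[k]
  }
  q
}

# independent R^2 for an OLS line with intercept (normal equations)
oracle_r2 <- function(t, q) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% q)
  res <- q - X %*% beta
  1 - sum(res^2) / sum((q - mean(q))^2)
}

# first prefix drop at which the remaining window becomes linear; mirrors
# the trimming rule by brute force over all prefixes
oracle_trim <- function(t, q, thr = 0.970, min_points = 3) {
  for (k in 0:(length(t) - min_points)) {
    idx <- (k + 1):length(t)
    if (oracle_r2(t[idx], q[idx]) >= thr)
      return(list(n_dropped = k, r2 = oracle_r2(t[idx], q[idx])))
  }
  list(n_dropped = NA_integer_, r2 = NA_real_)
}
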