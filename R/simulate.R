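#' Configuration for a simulated transwell transport experiment
#'
#' Defaults reproduce the bidirectional study design the analysis pipeline
#' expects: 50 µM donor, 0.5 mL apical / 1.2 mL basolateral compartments on a
#' 0.3 cm² membrane, half-volume receiver samples at 0.5, 1 and 1.2 h with
#' medium replacement and a terminal 2 h sample, 5 nM limit of
#' quantification, and 5% multiplicative measurement noise.
#'
#' @param papp_true true passive apparent permeability in 10⁻⁶ cm/s.
#' @param active_clearance unidirectional basolateral-to-apical first-order
#'   clearance in mL/s (0 = passive only); models an apically directed
#'   efflux transporter.
#' @param geometry a [transwell_geometry()].
#' @param times sampling times in hours.
#' @param donor_concentration donor concentration in µM.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   observation noise.
#' @param loq limit of quantification in nM.
#' @param seed integer seed; identical configurations give identical output.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(papp_true, active_clearance = 0,
                              geometry = transwell_geometry(),
                              times = c(0.5, 1, 1.2, 2),
                              donor_concentration = 50, noise_cv = 0.05,
                              loq = 5, seed = 1L) {
  stopifnot(papp_true >= 0, active_clearance >= 0, noise_cv >= 0, loq > 0,
            donor_concentration > 0, inherits(geometry, "transwell_geometry"))
  structure(list(papp_true = papp_true, active_clearance = active_clearance,
                 geometry = geometry, times = times,
                 donor_concentration = donor_concentration,
                 noise_cv = noise_cv, loq = loq, seed = as.integer(seed)),
            class = "simulation_config")
}

# two-compartment rate matrix (concentration form), direction-aware.
# PA: passive Papp*Area (mL/s); CL: active B->A clearance (mL/s).
# State is c(C_donor, C_receiver) in nM.
.transport_matrix <- function(PA, CL, Vd, Vr, direction) {
  if (direction == "A2B") {
    # donor apical, receiver basolateral; active term returns receiver -> donor
    matrix(c(-PA / Vd, (PA + CL) / Vd,
             PA / Vr, -(PA + CL) / Vr), 2, 2, byrow = TRUE)
  } else {
    # donor basolateral, receiver apical; active term adds donor -> receiver
    matrix(c(-(PA + CL) / Vd, PA / Vd,
             (PA + CL) / Vr, -PA / Vr), 2, 2, byrow = TRUE)
  }
}

# exact propagation over dt seconds (eigendecomposition of the 2x2 system;
# the sign structure guarantees a real spectrum)
.twocomp_step <- function(state, M, dt) {
  if (all(M == 0)) return(state)
  e <- eigen(M)
  Re(e$vectors %*% (exp(e$values * dt) * solve(e$vectors, state)))
}

#' Simulate a bidirectional transwell transport experiment
#'
#' Integrates the two-compartment mass balance exactly (the linear model has
#' a closed-form solution between sampling events). Passive flux is
#' `Papp * A * (C_donor - C_receiver)`; an optional unidirectional
#' basolateral-to-apical clearance adds polarized (efflux-like) transport.
#' At each sampling event the scheduled receiver volume is removed (the
#' sample's true concentration is recorded), blank medium is added back, and
#' the receiver is diluted accordingly. Observations get multiplicative
#' lognormal noise with the configured CV (unit mean); the LOQ is attached
#' so the analysis pipeline can censor. Noise affects observations only,
#' never the simulated state.
#'
#' @param cfg a [simulation_config()].
#' @param direction transport direction.
#' @param insert_id,experiment_id identifiers for the generated series.
#' @return A [receiver_series()] with a `"truth"` attribute: a list holding
#'   the true Papp, the noise-free sample concentrations, the donor and
#'   receiver state at each event, removed amounts, the initial dose and the
#'   mass-balance residual.
#' @examples
#' s <- simulate_transport(simulation_config(papp_true = 10, noise_cv = 0))
#' attr(s, "truth")$papp_true
#' @export
simulate_transport <- function(cfg, direction = c("A2B", "B2A"),
                               insert_id = "sim1", experiment_id = "exp1") {
  stopifnot(inherits(cfg, "simulation_config"))
  direction <- match.arg(direction)
  geom <- cfg$geometry
  Vd <- donor_volume(geom, direction)
  Vr <- receiver_volume(geom, direction)
  side <- if (direction == "A2B") "basolateral" else "apical"
  sched <- validate_schedule(sampling_schedule(cfg$times, Vr / 2), geom, side)

  PA <- cfg$papp_true * 1e-6 * geom$membrane_area   # mL/s
  M <- .transport_matrix(PA, cfg$active_clearance, Vd, Vr, direction)
  C0 <- cfg$donor_concentration * 1000              # uM -> nM
  state <- c(C0, 0)
  dose <- C0 * Vd                                   # pmol

  n <- length(cfg$times)
  true_conc <- donor_state <- receiver_state <- removed <- numeric(n)
  t_prev <- 0
  for (k in seq_len(n)) {
    dt_s <- (sched$time[k] - t_prev) * 3600
    state <- .twocomp_step(state, M, dt_s)
    true_conc[k] <- state[2]
    donor_state[k] <- state[1]
    removed[k] <- state[2] * sched$removed_volume[k]
    # replacement with blank medium dilutes what remains; with no
    # replacement (terminal draw) the concentration is unchanged
    state[2] <- state[2] * (Vr - sched$removed_volume[k]) /
      (Vr - sched$removed_volume[k] + sched$replaced_volume[k])
    receiver_state[k] <- state[2]
    t_prev <- sched$time[k]
  }
  mass_residual <- donor_state[n] * Vd +
    state[2] * (Vr - sched$removed_volume[n] + sched$replaced_volume[n]) +
    sum(removed) - dose

  set.seed(cfg$seed)
  sdlog <- sqrt(log1p(cfg$noise_cv^2))
  noise <- function(x) if (cfg$noise_cv == 0) x else
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  obs <- noise(true_conc)
  donor_obs <- noise(C0)

  out <- receiver_series(values = obs, times = cfg$times,
                         direction = direction, donor_value = donor_obs,
                         loq = cfg$loq, substrate = "simulated",
                         insert_id = insert_id, geometry = geom,
                         schedule = sched, unit = "nM",
                         experiment_id = experiment_id)
  out <- censor_loq(out)
  attr(out, "truth") <- list(
    papp_true = cfg$papp_true, active_clearance = cfg$active_clearance,
    true_concentrations = true_conc, donor_state = donor_state,
    receiver_state_after_event = receiver_state,
    removed_amounts = removed, dose = dose, donor_value_true = C0,
    mass_residual = mass_residual,
    sink_fraction = max(true_conc / donor_state))
  out
}

#' Explicit-Euler reference integration of the transport simulation
#'
#' Small-step forward-Euler integration of the same two-compartment mass
#' balance, used as an independent check on the closed-form propagator of
#' [simulate_transport()]. Returns the noise-free sample concentrations.
#'
#' @param cfg a [simulation_config()].
#' @param direction transport direction.
#' @param dt time step in seconds (default 0.1).
#' @return Numeric vector of true receiver concentrations (nM) at the
#'   sampling times.
#' @export
simulate_transport_euler <- function(cfg, direction = c("A2B", "B2A"),
                                     dt = 0.1) {
  stopifnot(inherits(cfg, "simulation_config"))
  direction <- match.arg(direction)
  geom <- cfg$geometry
  Vd <- donor_volume(geom, direction)
  Vr <- receiver_volume(geom, direction)
  PA <- cfg$papp_true * 1e-6 * geom$membrane_area
  M <- .transport_matrix(PA, cfg$active_clearance, Vd, Vr, direction)
  state <- c(cfg$donor_concentration * 1000, 0)
  times_s <- cfg$times * 3600
  rem <- Vr / 2
  out <- numeric(length(cfg$times))
  t <- 0
  for (k in seq_along(times_s)) {
    nstep <- ceiling((times_s[k] - t) / dt)
    h <- (times_s[k] - t) / nstep
    for (i in seq_len(nstep)) state <- state + h * (M %*% state)
    out[k] <- state[2]
    replaced <- if (k == length(times_s)) 0 else rem
    state[2] <- state[2] * (Vr - rem) / (Vr - rem + replaced)
    t <- times_s[k]
  }
  out
}

#' Simulate a TEER maturation curve
#'
#' Logistic rise towards a plateau with additive Gaussian noise, emulating
#' barrier tightening over weeks in culture.
#'
#' @param plateau asymptotic TEER in Ω·cm² (default 721).
#' @param day50 day at which half the plateau is reached (default 32).
#' @param scale logistic time scale in days (default 3).
#' @param noise_sd additive noise SD in Ω·cm² (default 0).
#' @param days measurement days.
#' @param seed integer seed.
#' @param insert_id identifier.
#' @return A [teer_series()].
#' @export
simulate_teer_course <- function(plateau = 721, day50 = 32, scale = 3,
                                 noise_sd = 0, days = seq(5, 45, by = 5),
                                 seed = 1L, insert_id = "sim1") {
  stopifnot(plateau > 0, scale > 0)
  set.seed(seed)
  teer <- plateau / (1 + exp(-(days - day50) / scale))
  if (noise_sd > 0) teer <- teer + stats::rnorm(length(days), sd = noise_sd)
  teer_series(insert_id, days, teer)
}

#' 84-gene human drug-transporter panel
#'
#' Gene symbols (ABC and SLC superfamilies plus accessory genes) used as the
#' default target set by [simulate_ct_table()].
#'
#' @return Character vector of 84 gene symbols.
#' @export
transporter_panel_genes <- function() {
  c("ABCA1", "ABCA12", "ABCA13", "ABCA2", "ABCA3", "ABCA4", "ABCA9",
    "ABCB1", "ABCB11", "ABCB4", "ABCB5", "ABCB6", "ABCB8",
    "ABCC1", "ABCC10", "ABCC11", "ABCC12", "ABCC2", "ABCC3", "ABCC4",
    "ABCC5", "ABCC6", "ABCD1", "ABCD3", "ABCD4", "ABCF1", "ABCG2", "ABCG8",
    "AQP1", "AQP7", "AQP9", "ATP6V0C", "ATP7A", "ATP7B", "MVP",
    "SLC10A1", "SLC10A2", "SLC13A1", "SLC15A1", "SLC15A2", "SLC16A1",
    "SLC16A2", "SLC16A3", "SLC19A1", "SLC19A2", "SLC19A3", "SLC22A1",
    "SLC22A2", "SLC22A3", "SLC22A4", "SLC22A5", "SLC22A6", "SLC22A7",
    "SLC22A8", "SLC22A9", "SLC25A13", "SLC28A1", "SLC28A2", "SLC28A3",
    "SLC29A1", "SLC29A2", "SLC2A1", "SLC2A2", "SLC2A3", "SLC31A1",
    "SLC38A2", "SLC38A5", "SLC3A1", "SLC3A2", "SLC5A1", "SLC5A4",
    "SLC7A11", "SLC7A5", "SLC7A6", "SLC7A7", "SLC7A8", "SLC7A9",
    "SLCO1A2", "SLCO1B1", "SLCO1B3", "SLCO2A1", "SLCO2B1", "SLCO3A1",
    "SLCO4A1")
}

#' Simulate a transporter-panel Ct table
#'
#' Reference genes cluster near a common Ct; target genes get per-gene base
#' Cts spread over a wide expression range with small replicate noise; the
#' named undetectable genes are undetermined (`NA`) in every replicate.
#'
#' @param genes target gene symbols (default: an 84-gene human drug
#'   transporter panel).
#' @param undetectable_genes subset of `genes` to render undetermined in all
#'   replicates.
#' @param n_replicates number of replicates (default 3).
#' @param panel a [reference_panel()].
#' @param seed integer seed.
#' @return A data frame with columns `replicate`, `gene`, `ct`, suitable for
#'   [compute_delta_ct()].
#' @export
simulate_ct_table <- function(genes = transporter_panel_genes(),
                              undetectable_genes = c("SLC22A9", "SLCO1B1",
                                                     "SLCO1B3"),
                              n_replicates = 3, panel = reference_panel(),
                              seed = 1L) {
  stopifnot(all(undetectable_genes %in% genes))
  set.seed(seed)
  base <- stats::runif(length(genes), 22, 34)
  names(base) <- genes
  rows <- lapply(seq_len(n_replicates), function(r) {
    ref_ct <- stats::rnorm(length(panel$genes), mean = 20, sd = 0.3)
    tgt_ct <- base + stats::rnorm(length(genes), sd = 0.25)
    tgt_ct[undetectable_genes] <- NA_real_
    data.frame(replicate = sprintf("r%d", r),
               gene = c(panel$genes, genes),
               ct = c(ref_ct, unname(tgt_ct)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete barrier study
#'
#' Generates everything the full pipeline consumes: receiver time series for
#' several substrates in both directions over replicate inserts, per-insert
#' barrier QC values (TEER and leakage), and a transporter Ct table. True
#' parameters travel along for recovery testing.
#'
#' @param substrates data frame with columns `substrate`, `papp_true`
#'   (10⁻⁶ cm/s) and optionally `active_clearance` (mL/s).
#' @param n_inserts inserts per substrate and direction.
#' @param noise_cv observation noise CV.
#' @param teer_mean,teer_sd distribution of post-experiment TEER (Ω·cm²).
#' @param leakage_mean,leakage_sd distribution of leakage (%).
#' @param geometry a [transwell_geometry()].
#' @param loq limit of quantification (nM).
#' @param seed integer seed.
#' @param experiment_id identifier.
#' @return An object of class `"simulated_study"`: a list with `series`
#'   (list of [receiver_series()]), `qc` (data frame `insert_id`, `teer`,
#'   `leakage`), `ct` (Ct table) and `truth`.
#' @export
simulate_study <- function(substrates = data.frame(
                             substrate = c("paracellular_probe",
                                           "transcellular_probe"),
                             papp_true = c(0.4, 16),
                             active_clearance = c(0, 0)),
                           n_inserts = 3, noise_cv = 0.05,
                           teer_mean = 650, teer_sd = 50,
                           leakage_mean = 0.05, leakage_sd = 0.02,
                           geometry = transwell_geometry(), loq = 5,
                           seed = 1L, experiment_id = "exp1") {
  stopifnot(is.data.frame(substrates),
            all(c("substrate", "papp_true") %in% names(substrates)))
  if (is.null(substrates$active_clearance))
    substrates$active_clearance <- 0
  series <- list()
  idx <- 0L
  for (i in seq_len(nrow(substrates))) {
    for (dir in c("A2B", "B2A")) {
      for (j in seq_len(n_inserts)) {
        idx <- idx + 1L
        cfg <- simulation_config(
          papp_true = substrates$papp_true[i],
          active_clearance = substrates$active_clearance[i],
          geometry = geometry, noise_cv = noise_cv, loq = loq,
          seed = seed + 7919L * idx)
        s <- simulate_transport(cfg, direction = dir,
                                insert_id = sprintf("ins%02d", idx),
                                experiment_id = experiment_id)
        s$substrate <- substrates$substrate[i]
        series[[idx]] <- s
      }
    }
  }
  set.seed(seed)
  n <- length(series)
  qc <- data.frame(
    insert_id = vapply(series, `[[`, character(1), "insert_id"),
    teer = stats::rnorm(n, teer_mean, teer_sd),
    leakage = pmax(stats::rnorm(n, leakage_mean, leakage_sd), 0.001))
  ct <- simulate_ct_table(seed = seed)
  structure(list(series = series, qc = qc, ct = ct,
                 truth = list(substrates = substrates, seed = seed,
                              noise_cv = noise_cv)),
            class = "simulated_study")
}
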