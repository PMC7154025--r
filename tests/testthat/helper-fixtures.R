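# Shared fixtures. The calibrated twin runs are expensive, so they are
# computed once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

porcine_calibration <- function() {
  fixture("porcine_cal", gen_pump_driver(experiment_preset("porcine")))
}

pericardial_calibration <- function() {
  fixture("pericardial_cal",
          gen_pump_driver(experiment_preset("pericardial")))
}

porcine_dataset50 <- function() {
  fixture("porcine_ds50",
          gen_experiment(experiment_preset("porcine"), n_cycles = 50,
                         seed = 1, calibration = porcine_calibration()))
}

pericardial_dataset50 <- function() {
  fixture("pericardial_ds50",
          gen_experiment(experiment_preset("pericardial"), n_cycles = 50,
                         seed = 1, calibration = pericardial_calibration()))
}

# Random rotation matrix (Haar-ish via QR with positive diagonal).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random volume-preserving deformation gradient near the identity.
random_isochoric_F <- function(scale = 0.08) {
  F <- diag(3) + matrix(stats::rnorm(9, sd = scale), 3, 3)
  F / det(F)^(1 / 3)
}

# Independent central-finite-difference gradient of the strain energy,
# used as the oracle for the analytic first Piola-Kirchhoff stress.
fd_pk1 <- function(params, F, h = 1e-6) {
  G <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      G[i, j] <- (strain_energy(params, Fp) - strain_energy(params, Fm)) /
        (2 * h)
    }
  }
  G
}

# Scalar summaries of a twin run.
run_summary <- function(run) {
  s <- run$signals
  wq <- waveform(run$time, s$q_ao_mL_s)
  list(sv = stroke_volume(wq),
       q_peak = max(s$q_ao_mL_s),
       dp_max = max_forward_dp(waveform(run$time, s$p_lv_mmHg),
                               waveform(run$time, s$p_ao_mmHg), wq))
}
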