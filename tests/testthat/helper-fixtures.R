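# shared fixtures: coarse discretizations keep unit tests fast; the
# acceptance file runs the full default-resolution settings.

coarse_disc <- function(t_end = 48, by = 0.2)
  discretization(dx_gel = 20, dx_epi = 10, dx_stroma = 20, dt = 0.05,
                 t_end = t_end, output_times = seq(0, t_end, by = by))

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# one coarse default-parameter run reused across files
quick_sim <- function() cached("quick_sim",
                               simulate_transport(transport_params(),
                                                  coarse_disc()))

erfc <- function(z) 2 * stats::pnorm(-sqrt(2) * z)

# minimal hand-built sim_result for metric-level tests
fake_sim <- function(times, gel, epi, stroma, dp_epi, dp_stroma, blood) {
  structure(list(times = times,
                 grids = list(gel = seq_len(ncol(gel)),
                              epithelium = seq_len(ncol(epi)),
                              stroma = seq_len(ncol(stroma))),
                 tfv_gel = gel, tfv_epi = epi, tfv_stroma = stroma,
                 dp_epi = dp_epi, dp_stroma = dp_stroma,
                 blood_tfv = blood,
                 loss_dilution = rep(0, length(times)),
                 loss_clearance = rep(0, length(times))),
            class = "sim_result")
}

# small synthetic "cohort-like" dataset with smooth metric relationships,
# for NN/CLI tests that must not pay for real simulations
synthetic_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  x <- matrix(runif(4 * n, -1, 1), n, 4)
  df <- data.frame(case = seq_len(n), he = 100 + 300 * (x[, 1] + 1) / 2,
                   kD = 0.4 + 0.8 * (x[, 2] + 1) / 2,
                   kB = 0.07 + 0.14 * (x[, 3] + 1) / 2)
  df$blood_Cmax <- 2 + x[, 1] + 0.3 * x[, 2]
  df$blood_tmax <- 4 + 0.5 * x[, 3]
  df$blood_AUC <- 20 + 5 * x[, 1] - 2 * x[, 2] + x[, 4]
  df$blood_C24 <- 0.2 + 0.05 * x[, 1] * x[, 3]
  df$stroma_Cmax <- 3 * df$blood_Cmax + 0.5 * df$blood_tmax
  df$stroma_tmax <- df$blood_tmax - 1
  df$stroma_AUC <- 2 * df$blood_AUC + df$blood_Cmax
  df$stroma_C24 <- 10 * df$blood_C24 + 0.1 * df$blood_Cmax
  df$t_lag <- 5 + tanh(df$blood_Cmax - 2) + 0.2 * df$blood_tmax
  df$PPmax <- 80 + 15 * tanh(df$blood_AUC / 10 - 2)
  df
}

write_config <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA)
  path
}
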