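#' Simulate tenofovir transport through gel, mucosa and blood
#'
#' Solves the coupled one-dimensional unsteady diffusion-reaction system for
#' TFV across the gel, epithelial and stromal layers, with a well-mixed blood
#' compartment and local first-order conversion of TFV to TFV-DP in tissue.
#'
#' The governing system (method of lines, cell-centred finite volumes,
#' Crank-Nicolson time stepping with a short backward-Euler startup):
#' \itemize{
#'   \item Gel, 0 <= x <= hg: dc/dt = Dg d2c/dx2 - kD c, zero flux at x = 0
#'     (luminal symmetry plane).
#'   \item Epithelium: dc/dt = De d2c/dx2.
#'   \item Stroma: dc/dt = Ds d2c/dx2 - kB c, zero flux at the deep face.
#'   \item Interfaces: flux continuity with a partition jump,
#'     c_downstream = phi * c_upstream (phi_ge, phi_es).
#'   \item Blood: VB dCB/dt = kB (W L area_factor) Int c_stroma dx - kL VB CB.
#'   \item TFV-DP (tissue-level, epithelium and stroma):
#'     dcDP/dt = k_on (vf n_eq c_TFV - cDP) - k_off cDP, where vf is the
#'     layer's cellular volume fraction.
#' }
#' At t = 0 the gel is at `C0` and every other field is zero.
#'
#' @param params a [transport_params()] object.
#' @param disc a [discretization()] object.
#' @return An object of class `sim_result`: list with `times` (hr), `grids`
#'   (cell-centre positions per layer, micrometres, measured from the luminal
#'   symmetry plane), concentration matrices `tfv_gel`, `tfv_epi`,
#'   `tfv_stroma`, `dp_epi`, `dp_stroma` (time x space, ng/mL), `blood_tfv`
#'   (ng/mL), cumulative `loss_dilution` and `loss_clearance` (ng), and the
#'   inputs `params`, `disc`.
#' @export
#' @examples
#' res <- simulate_transport(
#'   transport_params(),
#'   discretization(dx_gel = 20, dx_epi = 10, dx_stroma = 20, dt = 0.05,
#'                  t_end = 48, output_times = seq(0, 48, 0.5)))
#' max(res$blood_tfv)
simulate_transport <- function(params = transport_params(),
                               disc = discretization()) {
  validate_transport_params(params)
  validate_discretization(disc)

  ng <- layer_cells(params$hg, disc$dx_gel, "gel")
  ne <- layer_cells(params$he, disc$dx_epi, "epithelium")
  ns <- layer_cells(params$hs, disc$dx_stroma, "stroma")
  # actual spacings after rounding to whole cells (cm)
  dxg <- um_to_cm(params$hg) / ng
  dxe <- um_to_cm(params$he) / ne
  dxs <- um_to_cm(params$hs) / ns

  dt <- disc$dt
  steps <- disc$output_times / dt
  if (any(abs(steps - round(steps)) > 1e-6))
    stop("output_times must be integer multiples of dt", call. = FALSE)
  steps <- as.integer(round(steps))
  n_steps <- as.integer(round(disc$t_end / dt))
  if (max(steps) > n_steps) n_steps <- max(steps)

  out <- .cn_solver(
    ng, ne, ns, dxg, dxe, dxs,
    cm2s_to_cm2hr(params$Dg), cm2s_to_cm2hr(params$De),
    cm2s_to_cm2hr(params$Ds),
    params$phi_ge, params$phi_es,
    params$kD, params$kB, params$kL,
    params$C0, litre_to_ml(params$VB),
    params$W * params$L * params$area_factor,
    params$k_on, params$k_off,
    params$vf_e * params$n_eq, params$vf_s * params$n_eq,
    dt, n_steps, steps, rannacher_steps = 4L)

  xg <- (seq_len(ng) - 0.5) * dxg * 1e4
  xe <- params$hg + (seq_len(ne) - 0.5) * dxe * 1e4
  xs <- params$hg + params$he + (seq_len(ns) - 0.5) * dxs * 1e4

  structure(
    list(times = disc$output_times,
         grids = list(gel = xg, epithelium = xe, stroma = xs),
         tfv_gel = out$tfv_gel, tfv_epi = out$tfv_epi,
         tfv_stroma = out$tfv_stroma,
         dp_epi = out$dp_epi, dp_stroma = out$dp_stroma,
         blood_tfv = as.numeric(out$blood_tfv),
         loss_dilution = as.numeric(out$loss_dilution),
         loss_clearance = as.numeric(out$loss_clearance),
         params = params, disc = disc),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", length(x$times), " times over [",
      min(x$times), ", ", max(x$times), "] hr; cells: gel ",
      ncol(x$tfv_gel), ", epithelium ", ncol(x$tfv_epi), ", stroma ",
      ncol(x$tfv_stroma), "\n", sep = "")
  invisible(x)
}

#' Volume-averaged concentration time series for one compartment
#'
#' Within a layer the finite-volume cells have equal width, so the volume
#' average is the plain mean over cells at each output time. For blood the
#' stored (already volume-averaged) series is returned unchanged.
#'
#' @param result a `sim_result` from [simulate_transport()].
#' @param compartment one of `"gel"`, `"epithelium"`, `"stroma"`, `"blood"`.
#' @param species `"TFV"` or `"TFV-DP"`. TFV-DP is defined only in
#'   epithelium and stroma.
#' @return numeric vector (ng/mL), one value per output time.
#' @export
volume_average <- function(result, compartment, species = "TFV") {
  stopifnot(inherits(result, "sim_result"))
  compartment <- match.arg(compartment,
                           c("gel", "epithelium", "stroma", "blood"))
  species <- match.arg(species, c("TFV", "TFV-DP"))
  field <- switch(
    paste(compartment, species),
    "gel TFV" = result$tfv_gel,
    "epithelium TFV" = result$tfv_epi,
    "stroma TFV" = result$tfv_stroma,
    "epithelium TFV-DP" = result$dp_epi,
    "stroma TFV-DP" = result$dp_stroma,
    "blood TFV" = result$blood_tfv,
    stop("species '", species, "' is not defined in compartment '",
         compartment, "'", call. = FALSE))
  if (is.matrix(field)) rowMeans(field) else field
}

#' Compartmental mass ledger
#'
#' Converts the concentration fields to absolute drug mass per compartment
#' (over the coated area W x L x area_factor) and checks that, at every
#' output time, the initial gel mass equals the current gel + tissue + blood
#' mass plus the cumulative dilution and blood-clearance losses.
#'
#' @param result a `sim_result`.
#' @param params optional `transport_params`; defaults to those stored in
#'   `result`.
#' @return data.frame with columns `time`, `mass_gel`, `mass_epi`,
#'   `mass_stroma`, `mass_blood` (ng), cumulative `loss_dilution`,
#'   `loss_clearance` (ng), `total` and `rel_error` (relative to the initial
#'   gel mass; 0 when the initial mass is 0).
#' @export
mass_balance <- function(result, params = result$params) {
  stopifnot(inherits(result, "sim_result"))
  area <- params$W * params$L * params$area_factor # cm^2
  seg <- function(field, h_um) {
    dx_cm <- um_to_cm(h_um) / ncol(field)
    rowSums(field) * dx_cm * area
  }
  m_gel <- seg(result$tfv_gel, params$hg)
  m_epi <- seg(result$tfv_epi, params$he)
  m_str <- seg(result$tfv_stroma, params$hs)
  m_blood <- result$blood_tfv * litre_to_ml(params$VB)
  m0 <- params$C0 * um_to_cm(params$hg) * area
  total <- m_gel + m_epi + m_str + m_blood +
    result$loss_dilution + result$loss_clearance
  rel <- if (m0 > 0) (total - m0) / m0 else total * 0
  data.frame(time = result$times,
             mass_gel = m_gel, mass_epi = m_epi, mass_stroma = m_str,
             mass_blood = m_blood,
             loss_dilution = result$loss_dilution,
             loss_clearance = result$loss_clearance,
             total = total, rel_error = rel)
}

#' Export a simulation as tidy CSV
#'
#' One row per (time, compartment, species, position); blood rows have
#' `position = NA`.
#'
#' @param result a `sim_result`.
#' @param path output CSV path.
#' @param times optional subset of output times to export (defaults to all).
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path, times = result$times) {
  stopifnot(inherits(result, "sim_result"))
  idx <- match(times, result$times)
  if (anyNA(idx)) stop("requested times not in result$times", call. = FALSE)
  blocks <- list(
    list("gel", "TFV", result$tfv_gel, result$grids$gel),
    list("epithelium", "TFV", result$tfv_epi, result$grids$epithelium),
    list("stroma", "TFV", result$tfv_stroma, result$grids$stroma),
    list("epithelium", "TFV-DP", result$dp_epi, result$grids$epithelium),
    list("stroma", "TFV-DP", result$dp_stroma, result$grids$stroma))
  dfs <- lapply(blocks, function(b) {
    m <- b[[3]][idx, , drop = FALSE]
    data.frame(time = rep(times, times = ncol(m)),
               compartment = b[[1]], species = b[[2]],
               position_um = rep(b[[4]], each = length(times)),
               concentration = as.vector(m))
  })
  dfs[[length(dfs) + 1L]] <- data.frame(
    time = times, compartment = "blood", species = "TFV",
    position_um = NA_real_, concentration = result$blood_tfv[idx])
  out <- do.call(rbind, dfs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
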