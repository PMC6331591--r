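#' Summary pharmacokinetic metrics of a concentration time series
#'
#' Computes Cmax (peak), tmax (time of peak, first occurrence on ties), AUC
#' (trapezoidal rule over \[0, t_end\]) and C24 (exact sample at t = 24 hr)
#' for one compartment's volume-averaged concentration series.
#'
#' @param series numeric concentration series, ng/mL.
#' @param times sampling times, hr; strictly increasing, must contain 24 hr
#'   exactly (no silent interpolation).
#' @param t_end upper AUC limit, hr; defaults to the last sample time. Must
#'   be one of `times`.
#' @return list of class `pk_metrics` with `Cmax` (ng/mL), `tmax` (hr),
#'   `AUC` (ng hr/mL), `C24` (ng/mL).
#' @export
#' @examples
#' pk_metrics(c(0, 2, 1, 1), c(0, 8, 24, 48))
pk_metrics <- function(series, times, t_end = max(times)) {
  if (length(series) != length(times))
    stop("series and times must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  i24 <- which(abs(times - 24) < 1e-9)
  if (length(i24) != 1L)
    stop("times must contain a sample at exactly t = 24 hr", call. = FALSE)
  iend <- which(abs(times - t_end) < 1e-9)
  if (length(iend) != 1L)
    stop("t_end must coincide with a sample time", call. = FALSE)

  imax <- which.max(series) # first occurrence on ties
  keep <- seq_len(iend)
  auc <- trapz(times[keep], series[keep])
  structure(list(Cmax = series[imax], tmax = times[imax],
                 AUC = auc, C24 = series[i24]),
            class = "pk_metrics")
}

# trapezoidal quadrature
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Percent-protected time course
#'
#' At each output time, the percentage of stromal volume in which the
#' tissue-level TFV-DP concentration is at or above the prophylactic EC50.
#' Cells have equal width within the stroma, so the volume fraction is the
#' fraction of cells at/above threshold.
#'
#' @param dp_stroma TFV-DP concentration field, time x space matrix (ng/mL),
#'   or a `sim_result` from which the stromal field is taken.
#' @param EC50 prophylactic threshold, ng/mL; > 0.
#' @return numeric vector in \[0, 100\], one value per time.
#' @export
percent_protected <- function(dp_stroma, EC50) {
  if (inherits(dp_stroma, "sim_result")) {
    if (missing(EC50)) EC50 <- dp_stroma$params$EC50
    dp_stroma <- dp_stroma$dp_stroma
  }
  if (!is.matrix(dp_stroma) || nrow(dp_stroma) == 0L || ncol(dp_stroma) == 0L)
    stop("dp_stroma must be a non-empty time x space matrix", call. = FALSE)
  if (!is.numeric(EC50) || length(EC50) != 1L || !is.finite(EC50) || EC50 <= 0)
    stop("EC50 must be a single positive number", call. = FALSE)
  if (any(dp_stroma < 0))
    stop("dp_stroma must be non-negative", call. = FALSE)
  100 * rowMeans(dp_stroma >= EC50)
}

#' Pharmacodynamic summary metrics of the percent-protected course
#'
#' `PPmax` is the maximum of the series. Because TFV-DP decays very slowly
#' (k_off on the order of 1e-3/hr) the protection curve ends in a
#' near-plateau, so a strict argmax is numerically unstable; `t_lag` is
#' instead the earliest time at which the series comes within `tol`
#' percentage points of `PPmax`.
#'
#' @param pp_series percent-protected series in \[0, 100\].
#' @param times sampling times, hr.
#' @param tol plateau tolerance, percentage points (default 0.1).
#' @return list of class `pd_metrics` with `PPmax` (%) and `t_lag` (hr),
#'   plus the input series.
#' @export
pd_metrics <- function(pp_series, times, tol = 0.1) {
  if (length(pp_series) != length(times) || length(times) == 0L)
    stop("pp_series and times must be non-empty and of equal length",
         call. = FALSE)
  if (any(pp_series < -1e-9) || any(pp_series > 100 + 1e-9))
    stop("pp_series must lie in [0, 100]", call. = FALSE)
  ppmax <- max(pp_series)
  t_lag <- times[which(pp_series >= ppmax - tol)[1L]]
  structure(list(PPmax = ppmax, t_lag = t_lag,
                 pp_series = pp_series, times = times),
            class = "pd_metrics")
}

#' Convert an EC50 expressed per tissue mass to a tissue concentration
#'
#' fmol of drug per mg tissue times the molar mass gives mass of drug per
#' tissue mass (1 fmol/mg x 1 g/mol = 1e-3 ng/g); multiplying by the tissue
#' density converts to ng/mL. The canonical TFV-DP value of 500 fmol/mg at
#' molar mass 447.2 g/mol and density 1 g/mL gives 224 ng/mL (3 s.f.).
#'
#' @param value EC50 in fmol per mg tissue; >= 0.
#' @param molar_mass g/mol; > 0.
#' @param density tissue density, g/mL; > 0 (default 1).
#' @return EC50 in ng/mL.
#' @export
#' @examples
#' ec50_convert(500, 447.2) # ~224 ng/mL
ec50_convert <- function(value, molar_mass, density = 1) {
  if (!is.numeric(value) || any(value < 0))
    stop("value must be non-negative", call. = FALSE)
  if (!is.numeric(molar_mass) || any(molar_mass <= 0) ||
      !is.numeric(density) || any(density <= 0))
    stop("molar_mass and density must be positive", call. = FALSE)
  value * molar_mass * density / 1000
}

#' All PK/PD summary metrics of one simulation
#'
#' Convenience wrapper: blood/gel/epithelium/stroma TFV PK metrics, stromal
#' TFV-DP PK metrics, and the stromal percent-protected PD metrics.
#'
#' @param result a `sim_result`.
#' @param t_end AUC horizon, hr (default: last output time).
#' @return nested list: `pk[[compartment]]` of [pk_metrics()] results and
#'   `pd` of [pd_metrics()].
#' @export
summary_metrics <- function(result, t_end = max(result$times)) {
  stopifnot(inherits(result, "sim_result"))
  tt <- result$times
  pk <- list(
    blood = pk_metrics(volume_average(result, "blood"), tt, t_end),
    gel = pk_metrics(volume_average(result, "gel"), tt, t_end),
    epithelium = pk_metrics(volume_average(result, "epithelium"), tt, t_end),
    stroma = pk_metrics(volume_average(result, "stroma"), tt, t_end),
    stroma_dp = pk_metrics(volume_average(result, "stroma", "TFV-DP"),
                           tt, t_end))
  pd <- pd_metrics(percent_protected(result), tt)
  list(pk = pk, pd = pd)
}
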