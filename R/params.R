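#' Transport and physiological parameters of the gel-mucosa-blood model
#'
#' Constructs the full parameter set for the tenofovir (TFV) vaginal-gel
#' pharmacokinetic model: diffusion and partitioning of TFV through the gel,
#' epithelial and stromal layers, first-order loss terms (gel dilution by
#' ambient vaginal fluid, stroma-to-blood clearance, systemic clearance),
#' and the intracellular TFV to tenofovir-diphosphate (TFV-DP) conversion
#' kinetics.
#'
#' Defaults are the standard literature values for a 1% TFV gel; the three
#' host-variability parameters (`he`, `kD`, `kB`) default to the middle of
#' their canonical variation ranges (see [variation_grid()]).
#'
#' @param C0 initial TFV concentration in the gel layer, ng/mL.
#' @param Dg,De,Ds diffusion coefficients in gel, epithelium and stroma,
#'   cm^2/s.
#' @param phi_ge,phi_es partition coefficients (downstream/upstream
#'   equilibrium concentration ratio) at the gel/epithelium and
#'   epithelium/stroma interfaces, dimensionless.
#' @param hg,he,hs gel, epithelial and stromal layer thicknesses, micrometres.
#' @param W,L width and length of the coated vaginal canal, cm.
#' @param kD first-order dilution rate constant of drug in gel by ambient
#'   vaginal fluid, 1/hr.
#' @param kB first-order stroma-to-blood transport rate constant, 1/hr.
#' @param kL first-order clearance rate constant from blood, 1/hr.
#' @param VB blood volume of distribution, litres.
#' @param vf_e,vf_s volume fraction of cells in epithelium and stroma,
#'   dimensionless in \[0, 1\].
#' @param k_on rate of formation of TFV-DP in cells, 1/hr.
#' @param k_off rate of elimination of TFV-DP from cells, 1/hr.
#' @param n_eq equilibrium ratio of intracellular TFV-DP to TFV,
#'   dimensionless.
#' @param EC50 prophylactic (50% effective) tissue concentration of TFV-DP,
#'   ng/mL.
#' @param area_factor multiplier on the coated area W x L entering the blood
#'   uptake term; 1 models a single coated surface, 2 both apposed walls.
#'
#' @return An object of class `transport_params` (a validated named list).
#' @seealso [simulate_transport()], [variation_grid()]
#' @export
#' @examples
#' p <- transport_params()
#' p$EC50
transport_params <- function(C0 = 1e7,
                             Dg = 6e-6, De = 7e-8, Ds = 4e-7,
                             phi_ge = 0.75, phi_es = 1,
                             hg = 400, he = 250, hs = 2800,
                             W = 3.35, L = 13,
                             kD = 0.686, kB = 0.119, kL = 1.41,
                             VB = 75,
                             vf_e = 0.95, vf_s = 0.1,
                             k_on = 0.693, k_off = 0.00413,
                             n_eq = 0.1, EC50 = 224,
                             area_factor = 1) {
  p <- list(C0 = C0, Dg = Dg, De = De, Ds = Ds,
            phi_ge = phi_ge, phi_es = phi_es,
            hg = hg, he = he, hs = hs, W = W, L = L,
            kD = kD, kB = kB, kL = kL, VB = VB,
            vf_e = vf_e, vf_s = vf_s,
            k_on = k_on, k_off = k_off, n_eq = n_eq, EC50 = EC50,
            area_factor = area_factor)
  class(p) <- "transport_params"
  validate_transport_params(p)
  p
}

#' @rdname transport_params
#' @export
default_params <- function() transport_params()

#' Validate a transport_params object
#'
#' Checks positivity/range constraints on every field and fails with a
#' message naming each offending parameter.
#'
#' @param p a `transport_params` object or plain named list with its fields.
#' @return `p`, invisibly, if valid.
#' @export
validate_transport_params <- function(p) {
  bad <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(name, ok) if (!ok) bad <<- c(bad, name)

  for (f in c("Dg", "De", "Ds", "hg", "he", "hs", "W", "L", "VB",
              "phi_ge", "phi_es", "EC50", "area_factor"))
    chk(f, num1(p[[f]]) && p[[f]] > 0)
  for (f in c("kD", "kB", "kL", "k_on", "k_off", "n_eq", "C0"))
    chk(f, num1(p[[f]]) && p[[f]] >= 0)
  for (f in c("vf_e", "vf_s"))
    chk(f, num1(p[[f]]) && p[[f]] >= 0 && p[[f]] <= 1)

  if (length(bad))
    stop("invalid transport parameter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  invisible(p)
}

#' Spatial/temporal discretization settings for the transport solver
#'
#' @param dx_gel,dx_epi,dx_stroma cell widths in the gel, epithelial and
#'   stromal layers, micrometres. Each layer must resolve to at least 8
#'   cells.
#' @param dt time step, hr. Output times must be integer multiples of `dt`.
#' @param t_end simulation horizon, hr.
#' @param output_times monotone increasing sampling times, hr. Must include
#'   24 hr (required by the C24 pharmacokinetic metric) and be bounded by
#'   `t_end`.
#'
#' @return An object of class `discretization`.
#' @export
discretization <- function(dx_gel = 5, dx_epi = 5, dx_stroma = 5,
                           dt = 0.01, t_end = 96,
                           output_times = seq(0, t_end, by = 0.1)) {
  d <- list(dx_gel = dx_gel, dx_epi = dx_epi, dx_stroma = dx_stroma,
            dt = dt, t_end = t_end, output_times = output_times)
  class(d) <- "discretization"
  validate_discretization(d)
  d
}

#' @rdname discretization
#' @param d a `discretization` object.
#' @export
validate_discretization <- function(d) {
  bad <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(d$dt) || d$dt <= 0) bad <- c(bad, "dt")
  for (f in c("dx_gel", "dx_epi", "dx_stroma"))
    if (!num1(d[[f]]) || d[[f]] <= 0) bad <- c(bad, f)
  ot <- d$output_times
  if (!is.numeric(ot) || length(ot) < 1L || any(!is.finite(ot)) ||
      is.unsorted(ot, strictly = TRUE) || any(ot < 0))
    bad <- c(bad, "output_times")
  if (!num1(d$t_end) || d$t_end <= 0 ||
      (is.numeric(ot) && length(ot) && d$t_end < max(ot) - 1e-9))
    bad <- c(bad, "t_end")
  if (length(bad))
    stop("invalid discretization field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  invisible(d)
}

# number of finite-volume cells in a layer of thickness h_um with target
# spacing dx_um; enforces the minimum resolution contract
layer_cells <- function(h_um, dx_um, name) {
  n <- max(1L, as.integer(round(h_um / dx_um)))
  if (n < 8L)
    stop("layer '", name, "' resolves to ", n,
         " cells (< 8); decrease dx or increase thickness", call. = FALSE)
  n
}

# centralised unit conversions
um_to_cm <- function(x) x / 1e4
cm2s_to_cm2hr <- function(D) D * 3600
litre_to_ml <- function(v) v * 1000
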