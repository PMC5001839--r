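#' Absorbed photon flux at a given light intensity
#'
#' The vesicle-level absorbed photon rate is linear in intensity,
#' I = alpha * intensity, with alpha anchored to the calibration point of
#' 1860 photons/s absorbed at 50 W/m^2 (5% of full sunlight), i.e.
#' alpha = 37.2 photons s^-1 / (W m^-2).
#'
#' @param intensity incident light intensity, W/m^2 (vectorized, >= 0).
#' @param alpha photons s^-1 per W m^-2.
#' @return absorbed photons per second for the whole vesicle.
#' @export
#' @examples
#' photon_flux(50) # 1860
photon_flux <- function(intensity, alpha = 37.2) {
  if (any(intensity < 0)) stop("intensity must be non-negative")
  alpha * intensity
}

#' Total electron turnover capacity of the cytochrome bc1 complement
#'
#' B = 2 n_B / tau_B: each quinol turnover at a bc1 dimer passes two
#' electrons.
#'
#' @param n_B number of bc1 dimers.
#' @param tau_B quinol turnover time at one bc1 dimer, s.
#' @return capacity in electrons/s.
#' @export
#' @examples
#' bc1_electron_capacity(4, 0.025) # 320
bc1_electron_capacity <- function(n_B, tau_B) {
  stopifnot(n_B >= 0, tau_B > 0)
  2 * n_B / tau_B
}

#' High-light limit of the RC quinone cycling time
#'
#' When replacement quinones are limited by bc1 turnover, the total RC
#' turnover rate n_RC / tau_H matches the bc1 quinol turnover rate
#' n_B / tau_B, giving tau_H = (n_RC / n_B) tau_B.
#'
#' @param n_RC number of reaction centres.
#' @param n_B number of bc1 dimers (>= 1).
#' @param tau_B quinol turnover time at one bc1 dimer, s.
#' @return tau_H, s.
#' @export
tau_high <- function(n_RC, n_B, tau_B) {
  stopifnot(n_RC >= 0, tau_B > 0)
  if (n_B < 1) stop("tau_high undefined for n_B = 0 (no bc1-limited regime)")
  n_RC / n_B * tau_B
}

#' Light-dependent quinone cycling time at the RC
#'
#' Two-state interpolation between the diffusion-limited low-light cycling
#' time tau_L and the bc1-limited high-light value tau_H. The low-light
#' weight is the zero-event Poisson probability that no charge separation
#' falls within the characteristic bc1 electron turnover time,
#' c_L = exp(-f * I q / B) with B = 2 n_B / tau_B and f the Poisson factor
#' (1/2 in the printed two-state model):
#' tau_RC(I) = tau_L + (tau_H - tau_L)(1 - c_L).
#'
#' @param I absorbed photon flux, photons/s (vectorized).
#' @param q quantum yield.
#' @param tau_L,tau_H low-/high-light cycling times, s.
#' @param B bc1 electron turnover capacity, s^-1.
#' @param poisson_factor exponent prefactor f (default 1/2).
#' @return tau_RC in s, non-decreasing in I, within [tau_L, tau_H].
#' @export
cycling_time <- function(I, q, tau_L, tau_H, B, poisson_factor = 0.5) {
  stopifnot(all(I >= 0), tau_L > 0, tau_H >= tau_L, B > 0)
  cL <- exp(-poisson_factor * I * q / B)
  tau_L + (tau_H - tau_L) * (1 - cL)
}

#' Probability that a reaction centre is ready for charge separation
#'
#' Steady-state balance between quinol release (rate I q p_RC / 2) and
#' quinone rebinding (rate n_RC (1 - p_RC) / tau_RC) gives
#' p_RC = (1 + I q tau_RC / (2 n_RC))^-1.
#'
#' @param I absorbed photon flux, photons/s (vectorized).
#' @param q quantum yield.
#' @param tau_RC cycling time at this flux, s.
#' @param n_RC number of RCs.
#' @return probability in (0, 1].
#' @export
rc_availability <- function(I, q, tau_RC, n_RC) {
  stopifnot(all(I >= 0), n_RC > 0)
  1 / (1 + 0.5 * I * q * tau_RC / n_RC)
}

#' Steady-state ATP synthesis rate
#'
#' k_ATP(I) = (1/2) I q p_RC(I): every quinol needs two charge separations,
#' and under stationarity with matching proton stoichiometries (4 H+ per
#' quinol, 4 H+ per ATP with a 12-subunit c-ring) the quinol formation rate
#' equals the ATP synthesis rate. Saturates at n_RC / tau_H = n_B / tau_B *
#' ... = B/2 quinols/s as I grows.
#'
#' @param I absorbed photon flux, photons/s (vectorized).
#' @param params a [kinetic_params()] object (uses q, tau_L, tau_B, n_rc,
#'   n_bc1_dimers, poisson_factor, proton stoichiometries).
#' @param q optional quantum yield overriding `params$q`.
#' @return ATP molecules per second.
#' @export
#' @examples
#' atp_rate(photon_flux(1000), kinetic_params()) # ~158.5 at full sunlight
atp_rate <- function(I, params = kinetic_params(), q = NULL) {
  if (is.null(q)) q <- params$q
  if (params$n_rc <= 0) return(rep(0, length(I)))
  if (params$n_bc1_dimers <= 0) return(rep(0, length(I)))
  B <- bc1_electron_capacity(params$n_bc1_dimers, params$tau_B)
  tH <- tau_high(params$n_rc, params$n_bc1_dimers, params$tau_B)
  tRC <- cycling_time(I, q, params$tau_L, tH, B, params$poisson_factor)
  pRC <- rc_availability(I, q, tRC, params$n_rc)
  k_quinol <- 0.5 * I * q * pRC
  # identical to k_ATP when protons/quinol == protons/ATP; otherwise scale
  k_quinol * params$protons_per_quinol / params$protons_per_atp
}

#' Energy conversion efficiency of ATP synthesis
#'
#' eta_ATP(I) = E_ATP k_ATP(I) / (E_gamma I). At I = 0 the expression is
#' 0/0; the analytic low-light limit E_ATP q / (2 E_gamma) is returned
#' instead, flagged with attribute `"limit"`.
#'
#' @param I absorbed photon flux, photons/s (vectorized).
#' @param k_ATP matching ATP rates, s^-1.
#' @param E_ATP ATP hydrolysis energy, cm^-1.
#' @param E_gamma mean photon energy, cm^-1.
#' @param q quantum yield, needed only for the I = 0 limit.
#' @return dimensionless efficiency; attribute `"limit"` marks entries where
#'   the analytic limit replaced the undefined ratio.
#' @export
efficiency <- function(I, k_ATP, E_ATP = 4197, E_gamma = 11765, q = NULL) {
  stopifnot(all(I >= 0), length(k_ATP) == length(I))
  eta <- numeric(length(I))
  at0 <- I == 0
  eta[!at0] <- E_ATP * k_ATP[!at0] / (E_gamma * I[!at0])
  if (any(at0)) {
    if (is.null(q))
      stop("q is required to evaluate the I = 0 low-light limit")
    eta[at0] <- E_ATP * q / (2 * E_gamma)
  }
  attr(eta, "limit") <- at0
  eta
}

#' Full steady-state kinetics over an intensity grid
#'
#' Evaluates the whole Stage II/III chain for each intensity: photon flux,
#' bc1 capacity, two-state weights, cycling time, RC availability, quinol
#' and ATP rates, and efficiency.
#'
#' @param intensity light intensities, W/m^2.
#' @param params a [kinetic_params()] object.
#' @param q optional quantum yield overriding `params$q`.
#' @return data.frame of class `kinetics_result` with columns `intensity`
#'   (W/m^2), `I` (photons/s), `B` (1/s), `c_L`, `c_H`, `tau_RC` (s),
#'   `p_RC`, `k_Q_to_QH2` (1/s), `k_ATP` (1/s), `eta_ATP`.
#' @export
kinetics_profile <- function(intensity, params = kinetic_params(),
                             q = NULL) {
  if (is.null(q)) q <- params$q
  I <- photon_flux(intensity, params$alpha)
  B <- bc1_electron_capacity(params$n_bc1_dimers, params$tau_B)
  tH <- tau_high(params$n_rc, params$n_bc1_dimers, params$tau_B)
  cL <- exp(-params$poisson_factor * I * q / B)
  tRC <- cycling_time(I, q, params$tau_L, tH, B, params$poisson_factor)
  pRC <- rc_availability(I, q, tRC, params$n_rc)
  kq <- 0.5 * I * q * pRC
  katp <- kq * params$protons_per_quinol / params$protons_per_atp
  eta <- efficiency(I, katp, params$E_ATP, params$E_gamma, q = q)
  out <- data.frame(intensity = intensity, I = I, B = B,
                    c_L = cL, c_H = 1 - cL, tau_RC = tRC, p_RC = pRC,
                    k_Q_to_QH2 = kq, k_ATP = katp,
                    eta_ATP = as.numeric(eta))
  class(out) <- c("kinetics_result", "data.frame")
  out
}

#' Turnover-capacity comparison of the energy-conversion chain
#'
#' Tabulates the capacities that identify cytochrome bc1 as the rate
#' limiting component: RC quinol generation capacity (1/2) I q at the given
#' intensity, bc1 quinol / electron / proton capacities, ATP synthase proton
#' capacity, and the crossover intensity where the total RC electron
#' turnover I q equals the bc1 electron capacity B.
#'
#' @param params a [kinetic_params()] object.
#' @param intensity intensity at which the RC quinol capacity is quoted,
#'   W/m^2 (default 50, i.e. 5% of full sunlight).
#' @return data.frame with columns `quantity`, `value`, `units`.
#' @export
#' @examples
#' capacity_report(kinetic_params())
capacity_report <- function(params = kinetic_params(), intensity = 50) {
  I <- photon_flux(intensity, params$alpha)
  B <- bc1_electron_capacity(params$n_bc1_dimers, params$tau_B)
  crossover <- B / (params$q * params$alpha)
  data.frame(
    quantity = c("rc_quinol_capacity", "bc1_quinol_capacity",
                 "bc1_electron_capacity", "bc1_proton_capacity",
                 "atp_synthase_proton_capacity", "crossover_intensity"),
    value = c(0.5 * I * params$q,
              params$n_bc1_dimers / params$tau_B,
              B,
              params$protons_per_quinol * params$n_bc1_dimers /
                params$tau_B,
              params$protons_per_atp * params$n_atp_synthase *
                params$atp_synthase_capacity,
              crossover),
    units = c("quinol/s", "quinol/s", "electron/s", "H+/s", "H+/s",
              "W/m^2"),
    stringsAsFactors = FALSE)
}
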