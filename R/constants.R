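#' Constants registry for the exciton-transfer calculation
#'
#' Bundles every constant entering the effective-Hamiltonian / generalized
#' Foerster stage: bacteriochlorophyll (BChl) site energies, nearest-neighbour
#' couplings from quantum chemistry, the point-dipole coupling constant,
#' exciton linewidths, the fixed LH1<->RC transfer rates, and the loss and
#' charge-separation channels of the excitation-migration network. Energies
#' are in wavenumbers (cm^-1), times in seconds, distances in Angstrom.
#'
#' Site energies alternate around the LH2 B850 ring (alpha/beta BChls) and are
#' uniform on the LH1 B875 ring; the reaction centre (RC) carries a
#' low-energy special pair and two higher-energy accessory BChls. Couplings
#' between ring-adjacent BChls and within the RC special pair are short-range
#' and cannot be obtained from the point-dipole formula, so they are fixed
#' registry values; all other couplings are computed from geometry via
#' [dipole_coupling()].
#'
#' @param site_energies named list, cm^-1: `e1_lh2`, `e2_lh2` (alternating
#'   B850), `e_lh1` (B875), `e1_rc` (special pair), `e2_rc` (accessory).
#' @param nn_couplings named list, cm^-1: `v1_lh2`/`v2_lh2` (intra-/inter-
#'   alpha-beta-dimer B850), `v1_lh1`/`v2_lh1` (B875), `v_rc` (special pair).
#' @param dipole_constant_C point-dipole coupling constant, Angstrom^3 cm^-1.
#' @param sigma_lh2,sigma_lh1,sigma_rc exciton linewidths (Gaussian standard
#'   deviations), cm^-1. The RC linewidth is not tabulated independently and
#'   defaults to the LH1 value (nearest spectral region).
#' @param shift_S spectral shift between donor emission and acceptor
#'   absorption spectra, cm^-1. No published value; defaults to 0.
#' @param temperature temperature for Boltzmann exciton populations, K.
#' @param k_lh1_rc,k_rc_lh1 fixed intra-complex transfer rates, s^-1;
#'   defaults (35 ps)^-1 and (8 ps)^-1.
#' @param k_diss excitation loss rate through internal conversion, s^-1;
#'   default (1 ns)^-1.
#' @param k_cs charge-separation rate at an open RC, s^-1; default (3 ps)^-1.
#' @param neighbor_cutoff minimal Mg-Mg distance (Angstrom) below which two
#'   clusters are considered coupled neighbours; longer-range rates are
#'   negligible against the ~(10 ps)^-1 transfer scale and set to zero.
#' @param lineshape `"normalized"` uses unit-area Gaussians of standard
#'   deviation sigma; `"literal"` uses the narrower printed variant with
#'   exponent -((E-eps)/sigma)^2 (see the methods vignette).
#'
#' @return An object of class `exciton_params` (a validated list).
#' @export
#' @examples
#' p <- exciton_params()
#' p$nn_couplings$v_rc # 500 cm^-1
exciton_params <- function(site_energies = list(e1_lh2 = 12459, e2_lh2 = 12625,
                                                e_lh1 = 12344,
                                                e1_rc = 12092, e2_rc = 12581),
                           nn_couplings = list(v1_lh2 = 363, v2_lh2 = 320,
                                               v1_lh1 = 806, v2_lh1 = 377,
                                               v_rc = 500),
                           dipole_constant_C = 348000,
                           sigma_lh2 = 188, sigma_lh1 = 235,
                           sigma_rc = sigma_lh1,
                           shift_S = 0,
                           temperature = 300,
                           k_lh1_rc = 1 / 35e-12,
                           k_rc_lh1 = 1 / 8e-12,
                           k_diss = 1e9,
                           k_cs = 1 / 3e-12,
                           neighbor_cutoff = 70,
                           lineshape = c("normalized", "literal")) {
  lineshape <- match.arg(lineshape)
  p <- list(site_energies = site_energies, nn_couplings = nn_couplings,
            dipole_constant_C = dipole_constant_C,
            sigma_lh2 = sigma_lh2, sigma_lh1 = sigma_lh1, sigma_rc = sigma_rc,
            shift_S = shift_S, temperature = temperature,
            hbar = 5.3088e-12,           # cm^-1 s
            k_boltzmann = 0.69503480,    # cm^-1 / K
            k_lh1_rc = k_lh1_rc, k_rc_lh1 = k_rc_lh1,
            k_diss = k_diss, k_cs = k_cs,
            neighbor_cutoff = neighbor_cutoff,
            lineshape = lineshape)
  validate_exciton_params(p)
  structure(p, class = "exciton_params")
}

validate_exciton_params <- function(p) {
  need_e <- c("e1_lh2", "e2_lh2", "e_lh1", "e1_rc", "e2_rc")
  need_v <- c("v1_lh2", "v2_lh2", "v1_lh1", "v2_lh1", "v_rc")
  if (!all(need_e %in% names(p$site_energies)))
    stop("site_energies must contain: ", paste(need_e, collapse = ", "))
  if (!all(need_v %in% names(p$nn_couplings)))
    stop("nn_couplings must contain: ", paste(need_v, collapse = ", "))
  pos <- c(unlist(p$site_energies), unlist(p$nn_couplings),
           p$dipole_constant_C, p$sigma_lh2, p$sigma_lh1, p$sigma_rc,
           p$temperature, p$k_lh1_rc, p$k_rc_lh1, p$k_diss, p$k_cs,
           p$neighbor_cutoff)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all registry energies, couplings, linewidths, rates and the ",
         "temperature must be positive and finite")
  invisible(p)
}

#' Site energy for a pigment class
#'
#' Maps the pigment classification used in pigment tables to its registry
#' site energy. B800 BChls are not part of the exciton network and have no
#' registry energy; they are assigned `NA`.
#'
#' @param pigment_class character vector with values in `B850_alpha`,
#'   `B850_beta`, `B800`, `B875`, `RC_special`, `RC_accessory`.
#' @param params an [exciton_params()] registry.
#' @return numeric vector of site energies, cm^-1 (`NA` for B800).
#' @export
site_energy_for_class <- function(pigment_class, params = exciton_params()) {
  se <- params$site_energies
  lookup <- c(B850_alpha = se$e1_lh2, B850_beta = se$e2_lh2,
              B875 = se$e_lh1, RC_special = se$e1_rc,
              RC_accessory = se$e2_rc, B800 = NA_real_)
  unknown <- setdiff(unique(pigment_class), names(lookup))
  if (length(unknown) > 0)
    stop("unknown pigment_class: ", paste(unknown, collapse = ", "))
  unname(lookup[pigment_class])
}

#' Kinetic parameters for the steady-state energy-conversion model
#'
#' Stage II/III constants: quinone cycling times, photon-flux calibration,
#' proton stoichiometries and molecular energies, plus the vesicle
#' composition counts the rate equations depend on.
#'
#' The photon-flux conversion `alpha` is anchored to the one printed
#' calibration point: a vesicle absorbs 1860 photons/s at 50 W/m^2, hence
#' alpha = 37.2 photons s^-1 per W m^-2.
#'
#' @param tau_L low-light (diffusion-limited) quinone cycling time at the RC,
#'   s; default 3 ms for an LH2-rich low-light vesicle.
#' @param tau_B quinol turnover time at a cytochrome bc1 dimer, s; default
#'   25 ms.
#' @param q quantum yield of the light-harvesting stage; default 0.91 (the
#'   reference-vesicle value; supply the output of [quantum_yield()] or
#'   [interpolated_q()] to override).
#' @param alpha photon flux absorbed per unit intensity,
#'   photons s^-1 / (W m^-2).
#' @param E_ATP ATP hydrolysis energy, cm^-1.
#' @param E_gamma mean absorbed photon energy (850 nm), cm^-1.
#' @param protons_per_quinol protons released into the lumen per quinol
#'   turnover (Q-cycle at bc1 plus RC uptake).
#' @param protons_per_atp protons per ATP at the synthase (12-subunit c-ring
#'   gives 4).
#' @param atp_synthase_capacity single ATP synthase turnover capacity,
#'   ATP/s.
#' @param n_rc number of reaction centres.
#' @param n_bc1_dimers number of cytochrome bc1 dimers.
#' @param n_atp_synthase number of ATP synthases.
#' @param poisson_factor factor multiplying I q in the zero-event Poisson
#'   exponent of the low-light weight c_L = exp(-factor * I q / B). The
#'   printed two-state model uses 1/2; set 1 for the variant implied by the
#'   derivation text (see vignette).
#' @param strict_proton_stoichiometry if `TRUE` (default), require
#'   `protons_per_quinol == protons_per_atp`, the condition under which the
#'   steady-state identity k_ATP = k_Q->QH2 holds exactly.
#'
#' @return Object of class `kinetic_params`.
#' @export
#' @examples
#' kp <- kinetic_params()
#' bc1_electron_capacity(kp$n_bc1_dimers, kp$tau_B) # 320 s^-1
kinetic_params <- function(tau_L = 3e-3, tau_B = 25e-3, q = 0.91,
                           alpha = 37.2,
                           E_ATP = 4197, E_gamma = 11765,
                           protons_per_quinol = 4, protons_per_atp = 4,
                           atp_synthase_capacity = 270,
                           n_rc = 24, n_bc1_dimers = 4, n_atp_synthase = 2,
                           poisson_factor = 0.5,
                           strict_proton_stoichiometry = TRUE) {
  stopifnot(tau_L > 0, tau_B > 0, q > 0, q <= 1, alpha > 0,
            E_ATP > 0, E_gamma > 0, protons_per_quinol > 0,
            protons_per_atp > 0, atp_synthase_capacity > 0,
            n_rc >= 0, n_bc1_dimers >= 0, n_atp_synthase >= 0,
            poisson_factor > 0)
  if (strict_proton_stoichiometry &&
      protons_per_quinol != protons_per_atp)
    stop("protons_per_quinol must equal protons_per_atp for the ",
         "steady-state identity k_ATP = k_Q->QH2; set ",
         "strict_proton_stoichiometry = FALSE to relax")
  structure(list(tau_L = tau_L, tau_B = tau_B, q = q, alpha = alpha,
                 E_ATP = E_ATP, E_gamma = E_gamma,
                 protons_per_quinol = protons_per_quinol,
                 protons_per_atp = protons_per_atp,
                 atp_synthase_capacity = atp_synthase_capacity,
                 n_rc = n_rc, n_bc1_dimers = n_bc1_dimers,
                 n_atp_synthase = n_atp_synthase,
                 poisson_factor = poisson_factor),
            class = "kinetic_params")
}
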