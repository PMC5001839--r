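#' Membrane footprint areas of the protein complexes
#'
#' Areas used in the fixed-area composition sweep. The total protein area is
#' defined by the reference composition (4 bc1 dimers, 12 RC-LH1
#' dimer-equivalents, 63 LH2), so the reference point always maps back to
#' exactly 63 LH2 complexes. The individual areas are estimates from
#' approximate structural diameters; sweep conclusions are qualitative in
#' them (see the methods vignette).
#'
#' @param area_lh2 LH2 footprint, nm^2.
#' @param area_rclh1_dimer RC-LH1-PufX dimer footprint, nm^2.
#' @param area_bc1_dimer cytochrome bc1 dimer footprint, nm^2.
#' @param reference reference composition `c(n_B, n_L, n_lh2)` defining the
#'   total protein area.
#' @return Object of class `footprint_areas`.
#' @export
footprint_areas <- function(area_lh2 = 41, area_rclh1_dimer = 180,
                            area_bc1_dimer = 60,
                            reference = c(n_B = 4, n_L = 12, n_lh2 = 63)) {
  stopifnot(area_lh2 > 0, area_rclh1_dimer > 0, area_bc1_dimer > 0,
            length(reference) == 3, all(reference >= 0))
  total <- reference[[3]] * area_lh2 + reference[[2]] * area_rclh1_dimer +
    reference[[1]] * area_bc1_dimer
  structure(list(area_lh2 = area_lh2,
                 area_rclh1_dimer = area_rclh1_dimer,
                 area_bc1_dimer = area_bc1_dimer,
                 total_protein_area = total,
                 reference = reference),
            class = "footprint_areas")
}

#' LH2 count compensating a composition change at fixed membrane area
#'
#' The LH2 complement fills whatever protein area is left after placing
#' `n_B` bc1 dimers and `n_L` RC-LH1 dimers:
#' n_LH2 = round((A_total - n_B A_bc1 - n_L A_RCLH1) / A_LH2), floored at 0
#' (rounding half away from zero). A negative available area flags the
#' composition as infeasible.
#'
#' @param n_B,n_L bc1 dimer and RC-LH1 dimer counts (vectorized).
#' @param areas a [footprint_areas()] object.
#' @return integer LH2 counts with attribute `"feasible"` (logical).
#' @export
#' @examples
#' lh2_count(4, 12) # 63
lh2_count <- function(n_B, n_L, areas = footprint_areas()) {
  stopifnot(all(n_B >= 0), all(n_L >= 0))
  avail <- areas$total_protein_area - n_B * areas$area_bc1_dimer -
    n_L * areas$area_rclh1_dimer
  n <- floor(abs(avail) / areas$area_lh2 + 0.5) * sign(avail)
  n <- pmax(0L, as.integer(n))
  feasible <- avail >= 0
  n[!feasible] <- 0L
  attr(n, "feasible") <- feasible
  n
}

#' Composition sweep of the steady-state ATP rate at fixed membrane area
#'
#' Evaluates k_ATP over a grid of (n_B, n_L) compositions with the LH2 count
#' compensating footprint changes, the quantum yield interpolated from the
#' LH2:RC stoichiometry, and (optionally) the absorbed photon flux scaled
#' with the vesicle's BChl complement (27 BChls per LH2, 64 per RC-LH1
#' dimer) relative to the reference vesicle's 2469. Without that scaling a
#' composition with no antenna complexes would absorb as strongly as the
#' reference, and the sweep would degenerate to a grid-corner optimum.
#'
#' @param intensity light intensity, W/m^2.
#' @param nB_range,nL_range integer grids (defaults 1..16 and 1..33).
#' @param areas a [footprint_areas()] object.
#' @param params a [kinetic_params()] object; composition counts in it are
#'   overridden per grid point.
#' @param scale_absorption scale photon flux with pigment count (default
#'   TRUE).
#' @return Object of class `sweep_result`: `grid` (data.frame with n_B,
#'   n_L, n_lh2, s, q, I, k_ATP, feasible), `optimum` (row of the grid),
#'   `reference` (row matching the reference composition, if on the grid)
#'   and `intensity`.
#' @export
sweep_composition <- function(intensity,
                              nB_range = 1:16, nL_range = 1:33,
                              areas = footprint_areas(),
                              params = kinetic_params(),
                              scale_absorption = TRUE) {
  stopifnot(length(intensity) == 1, intensity >= 0,
            length(nB_range) > 0, length(nL_range) > 0)
  grid <- expand.grid(n_B = as.integer(nB_range),
                      n_L = as.integer(nL_range))
  nlh2 <- lh2_count(grid$n_B, grid$n_L, areas)
  grid$n_lh2 <- as.integer(nlh2)
  grid$feasible <- attr(nlh2, "feasible")
  grid$s <- grid$n_lh2 / (2 * grid$n_L)
  grid$q <- interpolated_q(grid$s)
  bchl <- 27 * grid$n_lh2 + 64 * grid$n_L
  ref_bchl <- 27 * areas$reference[[3]] + 64 * areas$reference[[2]]
  I0 <- photon_flux(intensity, params$alpha)
  grid$I <- if (scale_absorption) I0 * bchl / ref_bchl else rep(I0, nrow(grid))
  grid$k_ATP <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$n_rc <- 2 * grid$n_L[i]
    p$n_bc1_dimers <- grid$n_B[i]
    atp_rate(grid$I[i], p, q = grid$q[i])
  }, numeric(1))
  grid$k_ATP[!grid$feasible] <- NA_real_
  feas <- grid[grid$feasible, ]
  if (nrow(feas) == 0) stop("empty feasible region in composition sweep")
  # ties broken by smallest n_B, then smallest n_L
  ord <- order(-feas$k_ATP, feas$n_B, feas$n_L)
  optimum <- feas[ord[1], ]
  ref <- grid[grid$n_B == areas$reference[[1]] &
                grid$n_L == areas$reference[[2]], ]
  structure(list(grid = grid, optimum = optimum,
                 reference = if (nrow(ref) == 1) ref else NULL,
                 intensity = intensity),
            class = "sweep_result")
}

#' Reference-to-optimum ATP-rate fraction
#'
#' 100 * k_ATP(reference) / k_ATP(optimum) for a computed sweep; below 100
#' whenever the native composition is suboptimal on the swept grid.
#'
#' @param result a [sweep_composition()] result whose grid contains the
#'   reference composition.
#' @return percentage in (0, 100].
#' @export
reference_fraction <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  if (is.null(result$reference))
    stop("reference composition is not on the swept grid")
  100 * result$reference$k_ATP / result$optimum$k_ATP
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Composition sweep at %g W/m^2 (%d grid points, %d feasible)\n",
              x$intensity, nrow(x$grid), sum(x$grid$feasible)))
  cat(sprintf("  optimum: n_B = %d, n_L = %d, n_lh2 = %d, k_ATP = %.4g /s\n",
              x$optimum$n_B, x$optimum$n_L, x$optimum$n_lh2,
              x$optimum$k_ATP))
  if (!is.null(x$reference))
    cat(sprintf("  reference: k_ATP = %.4g /s (%.1f%% of optimum)\n",
                x$reference$k_ATP, reference_fraction(x)))
  invisible(x)
}
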