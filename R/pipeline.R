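#' Export a rate matrix as a (donor, acceptor, rate) TSV
#'
#' @param network a `transfer_network` with a `rates` element (as produced
#'   by [build_transfer_network()]), or a plain rate matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(network, path) {
  k <- if (inherits(network, "transfer_network")) network$rates else network
  idx <- which(k > 0, arr.ind = TRUE)
  tab <- data.frame(donor_cluster = rownames(k)[idx[, 1]],
                    acceptor_cluster = colnames(k)[idx[, 2]],
                    rate_per_s = sprintf("%.8e", k[idx]))
  tab <- tab[order(tab$donor_cluster, tab$acceptor_cluster), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration for the full pipeline
#'
#' Validated bundle of the per-stage configuration objects plus run-level
#' settings (intensity grid, sweep ranges, seed).
#'
#' @param geometry a [geometry_config()].
#' @param exciton an [exciton_params()] registry.
#' @param kinetics a [kinetic_params()] object.
#' @param areas a [footprint_areas()] object.
#' @param intensities intensity grid for the kinetics stage, W/m^2.
#' @param sweep_intensity intensity for the composition sweep, W/m^2.
#' @param nB_range,nL_range sweep grids.
#' @param seed placement seed (overrides `geometry$seed`).
#' @param q_source `"computed"` (from the built vesicle network),
#'   `"interpolated"` (from the LH2:RC stoichiometry) or `"fixed"`
#'   (`kinetics$q`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(geometry = geometry_config(),
                       exciton = exciton_params(),
                       kinetics = kinetic_params(),
                       areas = footprint_areas(),
                       intensities = c(0, 1, 3, 10, 30, 50, 100, 300, 1000),
                       sweep_intensity = 10,
                       nB_range = 1:16, nL_range = 1:33,
                       seed = NULL,
                       q_source = c("computed", "interpolated", "fixed")) {
  q_source <- match.arg(q_source)
  stopifnot(inherits(geometry, "geometry_config"),
            inherits(exciton, "exciton_params"),
            inherits(kinetics, "kinetic_params"),
            inherits(areas, "footprint_areas"),
            all(intensities >= 0), sweep_intensity >= 0)
  if (!is.null(seed)) geometry$seed <- as.integer(seed)
  structure(list(geometry = geometry, exciton = exciton,
                 kinetics = kinetics, areas = areas,
                 intensities = intensities,
                 sweep_intensity = sweep_intensity,
                 nB_range = nB_range, nL_range = nL_range,
                 q_source = q_source),
            class = "run_config")
}

#' Run the full build -> rates -> yield -> kinetics -> sweep pipeline
#'
#' Builds the reference vesicle, assembles the transfer network, computes
#' the quantum yield, evaluates the steady-state kinetics over the intensity
#' grid, runs the composition sweep, and writes every artifact (pigment TSV,
#' rate TSV, yield report, kinetics CSV, sweep CSV) plus a machine-readable
#' JSON manifest recording all inputs into `out_dir`. Deterministic for a
#' fixed seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list with the in-memory results (`vesicle`, `network`,
#'   `q`, `kinetics`, `sweep`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  vesicle <- build_reference_vesicle(config$geometry, config$exciton)
  write_pigment_table(vesicle, path("pigments.tsv"))

  network <- build_transfer_network(vesicle, config$exciton)
  write_rate_table(network, path("rates.tsv"))

  q_computed <- as.numeric(quantum_yield(network))
  q_used <- switch(config$q_source,
                   computed = q_computed,
                   interpolated = interpolated_q(vesicle$stoichiometry_s),
                   fixed = config$kinetics$q)
  yield_report <- list(q_computed = q_computed,
                       q_interpolated =
                         interpolated_q(vesicle$stoichiometry_s),
                       q_source = config$q_source, q_used = q_used,
                       oracle = as.numeric(quantum_yield_oracle(network)))
  jsonlite::write_json(yield_report, path("quantum_yield.json"),
                       auto_unbox = TRUE, digits = NA)

  kin <- kinetics_profile(config$intensities, config$kinetics, q = q_used)
  utils::write.csv(kin, path("kinetics.csv"), row.names = FALSE)

  sw <- sweep_composition(config$sweep_intensity, config$nB_range,
                          config$nL_range, config$areas, config$kinetics)
  utils::write.csv(sw$grid, path("sweep.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("chromatophore")),
    r_version = R.version.string,
    seed = config$geometry$seed,
    geometry = unclass(config$geometry),
    exciton = unclass(config$exciton),
    kinetics = unclass(config$kinetics),
    areas = unclass(config$areas)[1:4],
    intensities = config$intensities,
    sweep_intensity = config$sweep_intensity,
    nB_range = config$nB_range, nL_range = config$nL_range,
    q_source = config$q_source, q_used = q_used,
    outputs = c("pigments.tsv", "rates.tsv", "quantum_yield.json",
                "kinetics.csv", "sweep.csv"),
    sweep_optimum = as.list(sw$optimum),
    reference_fraction =
      if (!is.null(sw$reference)) reference_fraction(sw) else NULL)
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(vesicle = vesicle, network = network, q = q_used,
                 kinetics = kin, sweep = sw, manifest = manifest))
}

#' Generate small pigment-table fixtures with checkable yields
#'
#' `toy_two_cluster`: two single-BChl clusters (one non-RC donor, one RC
#' with the donor coupling dominating) whose yield follows the scalar
#' Foerster closed form. `toy_ring`: one LH2 plus one RC-LH1 monomer.
#' `mini_vesicle`: 6 LH2 and 2 RC-LH1 dimer-equivalents (as monomer pairs)
#' on a small sphere, suited to oracle cross-checks.
#'
#' @param kind fixture name.
#' @param dir output directory.
#' @param seed placement seed for the mini vesicle.
#' @return path of the written TSV, invisibly.
#' @export
make_fixtures <- function(kind = c("toy_two_cluster", "toy_ring",
                                   "mini_vesicle"),
                          dir, seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(kind, ".tsv"))
  v <- switch(kind,
    toy_two_cluster = toy_two_cluster_model(),
    toy_ring = build_vesicle(
      composition_spec(0, 1, 1, n_l_monomers = 2, n_atp_synthase = 0),
      geometry_config(placement_radius = 150, seed = seed)),
    mini_vesicle = build_vesicle(
      composition_spec(0, 2, 6, n_atp_synthase = 0),
      geometry_config(placement_radius = 200, seed = seed)))
  write_pigment_table(v, path)
  invisible(path)
}

# Two single-pigment clusters 20 A apart, parallel dipoles perpendicular to
# the separation. Both are typed LH1 (a 1-BChl RC would violate the 4-BChl
# invariant); tests mark the acceptor as the charge-separating sink when
# assembling the rate matrix, so the scalar-Foerster closed form applies.
toy_two_cluster_model <- function() {
  pig <- data.frame(
    cluster_id = c("DONOR_1", "ACCEPTOR_1"),
    cluster_type = c("LH1", "LH1"),
    pigment_class = c("B875", "B875"),
    ring_index = c(1L, 1L),
    mg_x = c(0, 20), mg_y = c(0, 0), mg_z = c(0, 0),
    nb_x = c(0, 20), nb_y = c(-1.45, -1.45), nb_z = c(0, 0),
    nd_x = c(0, 20), nd_y = c(1.45, 1.45), nd_z = c(0, 0),
    stringsAsFactors = FALSE)
  vesicle_from_pigments(pig)
}
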