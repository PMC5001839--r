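#' Transition dipole direction from NB/ND atom positions
#'
#' The Qy transition dipole of a BChl points from its NB to its ND nitrogen;
#' the unit vector is (r_D - r_B)/|r_D - r_B|, centred at the Mg atom.
#'
#' @param nb_position,nd_position numeric 3-vectors, or n x 3 matrices for a
#'   vectorized call, Angstrom.
#' @return unit 3-vector (or n x 3 matrix of unit rows).
#' @export
#' @examples
#' transition_dipole(c(0, 0, 0), c(3, 4, 0)) # c(0.6, 0.8, 0)
transition_dipole <- function(nb_position, nd_position) {
  if (is.null(dim(nb_position))) {
    nb_position <- matrix(nb_position, nrow = 1)
    nd_position <- matrix(nd_position, nrow = 1)
    scalar <- TRUE
  } else scalar <- FALSE
  d <- nd_position - nb_position
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9))
    stop("coincident NB and ND atoms: cannot define a transition dipole")
  d <- d / len
  if (scalar) drop(d) else d
}

#' Vesicle composition specification
#'
#' Counts of the protein complexes making up a vesicle. RC-LH1-PufX content
#' is given in dimer-equivalents (`n_l_dimers`); a pair of monomeric
#' complexes counts as one dimer-equivalent, so `n_l_monomers` must be even
#' and at most `2 * n_l_dimers`. The number of RCs is `2 * n_l_dimers`.
#'
#' @param n_bc1_dimers cytochrome bc1 dimers.
#' @param n_l_dimers RC-LH1-PufX dimer-equivalents.
#' @param n_lh2 LH2 complexes.
#' @param n_l_monomers how many of the RC-LH1 complexes are monomeric
#'   (counted two-per-dimer-equivalent).
#' @param n_atp_synthase ATP synthases.
#' @return Object of class `composition_spec`.
#' @export
composition_spec <- function(n_bc1_dimers, n_l_dimers, n_lh2,
                             n_l_monomers = 0, n_atp_synthase = 2) {
  stopifnot(n_bc1_dimers >= 0, n_l_dimers >= 0, n_lh2 >= 0,
            n_l_monomers >= 0, n_atp_synthase >= 0)
  if (n_l_monomers %% 2 != 0)
    stop("n_l_monomers must be even (two monomers count as one dimer)")
  if (n_l_monomers / 2 > n_l_dimers)
    stop("n_l_monomers/2 cannot exceed n_l_dimers")
  structure(list(n_bc1_dimers = as.integer(n_bc1_dimers),
                 n_l_dimers = as.integer(n_l_dimers),
                 n_lh2 = as.integer(n_lh2),
                 n_l_monomers = as.integer(n_l_monomers),
                 n_atp_synthase = as.integer(n_atp_synthase)),
            class = "composition_spec")
}

# Place hard discs on the placement sphere. `contact` mode anchors every
# new complex at touching distance from a randomly chosen placed complex
# (plus a small jitter), growing the dense, connected antenna arrangement
# the exciton network presumes; `rsa` mode is plain random sequential
# adsorption. Dimers occupy two discs tied to one complex group.
place_complexes <- function(composition, config) {
  R <- config$placement_radius
  centres <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  groups <- character(0)
  contact <- identical(config$placement, "contact")

  clash <- function(dirs, r, group) {
    if (nrow(centres) == 0) return(FALSE)
    for (k in seq_len(nrow(dirs))) {
      d2 <- colSums((t(centres) - R * dirs[k, ])^2)
      lim <- (0.999 * (radii + r))^2
      bad <- d2 < lim & groups != group
      if (any(bad)) return(TRUE)
    }
    FALSE
  }

  # direction at angular distance `arc` from `anchor`, random bearing
  offset_direction <- function(anchor, arc) {
    M <- local_frame(anchor, stats::runif(1, 0, 2 * pi))
    d <- cos(arc) * anchor + sin(arc) * M[, 1]
    d / sqrt(sum(d^2))
  }

  candidate_direction <- function(r_new) {
    if (!contact || nrow(centres) == 0) return(random_direction())
    i <- sample.int(nrow(centres), 1)
    anchor <- centres[i, ] / sqrt(sum(centres[i, ]^2))
    gap <- abs(stats::rnorm(1, 0, config$contact_jitter))
    # arc giving a chord of (r_i + r_new + gap)
    chord <- radii[i] + r_new + gap
    arc <- 2 * asin(pmin(1, chord / (2 * R)))
    offset_direction(anchor, arc)
  }

  add_unit <- function(type, r, n_discs, group) {
    r_eff <- if (n_discs == 2) r + config$dimer_offset else r
    for (attempt in seq_len(config$max_attempts)) {
      n <- candidate_direction(r_eff)
      az <- stats::runif(1, 0, 2 * pi)
      if (n_discs == 2) {
        a <- config$dimer_offset / R
        M <- local_frame(n, az)
        t1 <- M[, 1]
        d1 <- cos(a) * n + sin(a) * t1
        d2 <- cos(a) * n - sin(a) * t1
        dirs <- rbind(d1 / sqrt(sum(d1^2)), d2 / sqrt(sum(d2^2)))
      } else {
        dirs <- matrix(n, nrow = 1)
      }
      if (!clash(dirs, r, group)) {
        centres <<- rbind(centres, R * dirs)
        radii <<- c(radii, rep(r, nrow(dirs)))
        groups <<- c(groups, rep(group, nrow(dirs)))
        return(list(dirs = dirs, azimuth = az))
      }
    }
    stop("placement failure: could not fit all complexes on the sphere ",
         "(radius ", R, " A) for composition with ",
         composition$n_lh2, " LH2, ", composition$n_l_dimers,
         " RC-LH1 dimer-equivalents, ", composition$n_bc1_dimers,
         " bc1 dimers; reduce counts or enlarge the sphere")
  }

  units <- list()
  n_phys_dimers <- composition$n_l_dimers - composition$n_l_monomers / 2
  i_mono <- 0L
  for (d in seq_len(n_phys_dimers)) {
    group <- sprintf("DIM_%02d", d)
    u <- add_unit("RCLH1_dimer", config$hardcore_rclh1, 2, group)
    units[[length(units) + 1]] <- list(type = "RCLH1", group = group, u = u)
  }
  for (m in seq_len(composition$n_l_monomers)) {
    group <- sprintf("MON_%02d", m)
    u <- add_unit("RCLH1_monomer", config$hardcore_rclh1, 1, group)
    units[[length(units) + 1]] <- list(type = "RCLH1", group = group, u = u)
  }
  for (b in seq_len(composition$n_bc1_dimers)) {
    group <- sprintf("BC1_%02d", b)
    u <- add_unit("bc1", config$hardcore_bc1, 1, group)
    units[[length(units) + 1]] <- list(type = "bc1", group = group, u = u)
  }
  for (a in seq_len(composition$n_atp_synthase)) {
    group <- sprintf("ATP_%02d", a)
    u <- add_unit("atp", config$hardcore_atp, 1, group)
    units[[length(units) + 1]] <- list(type = "atp", group = group, u = u)
  }
  for (l in seq_len(composition$n_lh2)) {
    group <- sprintf("LH2_%03d", l)
    u <- add_unit("lh2", config$hardcore_lh2, 1, group)
    units[[length(units) + 1]] <- list(type = "lh2", group = group, u = u)
  }
  units
}

# Build the pigment table for one RC-LH1 monomer at direction n.
monomer_pigments <- function(id, n, azimuth, config) {
  lh1 <- ring_pigments(config$n_b875, config$b875_radius, z = 0,
                       tilt_deg = config$dipole_tilt_deg,
                       classes = "B875", nbnd_half = config$nbnd_half)
  lh1 <- place_pigments(lh1, n, config$placement_radius, azimuth)
  lh1$cluster_id <- sprintf("%s_LH1", id)
  lh1$cluster_type <- "LH1"
  rc <- rc_pigments(config)
  rc <- place_pigments(rc, n, config$placement_radius, azimuth)
  rc$cluster_id <- sprintf("%s_RC", id)
  rc$cluster_type <- "RC"
  rbind(lh1, rc)
}

lh2_pigments <- function(id, n, azimuth, config) {
  b850 <- ring_pigments(config$n_b850, config$b850_radius, z = 0,
                        tilt_deg = config$dipole_tilt_deg,
                        classes = c("B850_alpha", "B850_beta"),
                        nbnd_half = config$nbnd_half)
  out <- b850
  if (config$n_b800 > 0) {
    b800 <- ring_pigments(config$n_b800, config$b800_radius,
                          z = config$b800_z, tilt_deg = 0,
                          classes = "B800", nbnd_half = config$nbnd_half)
    out <- rbind(b850, b800)
  }
  out <- place_pigments(out, n, config$placement_radius, azimuth)
  out$cluster_id <- id
  out$cluster_type <- "LH2"
  out
}

# Derive dipoles, site energies and the cluster table; attach counts.
finalize_vesicle <- function(pigments, composition, config,
                             proteins = NULL,
                             params = exciton_params()) {
  dip <- transition_dipole(
    as.matrix(pigments[, c("nb_x", "nb_y", "nb_z")]),
    as.matrix(pigments[, c("nd_x", "nd_y", "nd_z")]))
  pigments$dip_x <- dip[, 1]; pigments$dip_y <- dip[, 2]
  pigments$dip_z <- dip[, 3]
  pigments$site_energy <- site_energy_for_class(pigments$pigment_class,
                                                params)
  pigments$network <- pigments$pigment_class != "B800"

  net <- pigments[pigments$network, ]
  ids <- unique(net$cluster_id)
  clusters <- do.call(rbind, lapply(ids, function(cid) {
    rows <- net[net$cluster_id == cid, ]
    data.frame(cluster_id = cid,
               cluster_type = rows$cluster_type[1],
               complex_id = complex_of(cid, rows$cluster_type[1]),
               n_pigments = nrow(rows),
               center_x = mean(rows$mg_x), center_y = mean(rows$mg_y),
               center_z = mean(rows$mg_z),
               stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL

  check_cluster_sizes(clusters)

  n_rc <- sum(clusters$cluster_type == "RC")
  model <- structure(list(
    pigments = pigments,
    clusters = clusters,
    proteins = proteins,
    n_lh2 = composition$n_lh2,
    n_l_dimers = composition$n_l_dimers,
    n_l_monomers = composition$n_l_monomers,
    n_rc = n_rc,
    n_bc1_dimers = composition$n_bc1_dimers,
    n_atp_synthase = composition$n_atp_synthase,
    inner_diameter_nm = config$inner_diameter_nm,
    total_bchl = nrow(pigments),
    stoichiometry_s = if (n_rc > 0) composition$n_lh2 / n_rc else NA_real_,
    config = config), class = "vesicle_model")
  model
}

complex_of <- function(cluster_id, cluster_type) {
  if (cluster_type %in% c("LH1", "RC"))
    sub("_(LH1|RC)$", "", cluster_id)
  else
    cluster_id
}

check_cluster_sizes <- function(clusters) {
  want <- c(LH2 = 18L, LH1 = 28L, RC = 4L)
  # LH2/LH1 ring sizes are configurable but must be even; RC is fixed at 4
  bad <- clusters$cluster_type == "RC" & clusters$n_pigments != 4L
  if (any(bad))
    stop("RC cluster(s) with wrong pigment count (need 4): ",
         paste(clusters$cluster_id[bad], collapse = ", "))
  invisible(want)
}

#' Build a synthetic vesicle with a given composition
#'
#' Generates pigment coordinates and transition dipoles for all LH2 and
#' RC-LH1-PufX complexes of a vesicle, placing complexes on the mid-membrane
#' sphere by random sequential adsorption with hard-core exclusion
#' (deterministic for a fixed `config$seed`). Cytochrome bc1 dimers and ATP
#' synthases carry no pigments but occupy membrane area and are placed too.
#'
#' @param composition a [composition_spec()].
#' @param config a [geometry_config()].
#' @param params an [exciton_params()] registry used to assign site energies.
#' @return Object of class `vesicle_model`: pigment table (`pigments`),
#'   network cluster table (`clusters`), complex placements (`proteins`) and
#'   composition bookkeeping (`n_lh2`, `n_rc`, `total_bchl`,
#'   `stoichiometry_s`, ...).
#' @seealso [build_reference_vesicle()], [read_pigment_table()]
#' @export
build_vesicle <- function(composition, config = geometry_config(),
                          params = exciton_params()) {
  stopifnot(inherits(composition, "composition_spec"),
            inherits(config, "geometry_config"))
  units <- with_placement_seed(config$seed,
                               place_complexes(composition, config))

  pieces <- list()
  proteins <- list()
  i_mono <- 0L; i_dim <- 0L; i_lh2 <- 0L; i_unit <- 0L
  for (u in units) {
    i_unit <- i_unit + 1L
    dirs <- u$u$dirs
    if (u$type == "RCLH1") {
      for (k in seq_len(nrow(dirs))) {
        i_mono <- i_mono + 1L
        id <- sprintf("RCLH1_%02d", i_mono)
        pieces[[length(pieces) + 1]] <-
          monomer_pigments(id, dirs[k, ], u$u$azimuth, config)
        proteins[[length(proteins) + 1]] <-
          data.frame(type = "RCLH1", id = id, group = u$group,
                     x = dirs[k, 1], y = dirs[k, 2], z = dirs[k, 3])
      }
    } else if (u$type == "lh2") {
      i_lh2 <- i_lh2 + 1L
      id <- sprintf("LH2_%03d", i_lh2)
      pieces[[length(pieces) + 1]] <-
        lh2_pigments(id, dirs[1, ], u$u$azimuth, config)
      proteins[[length(proteins) + 1]] <-
        data.frame(type = "LH2", id = id, group = u$group,
                   x = dirs[1, 1], y = dirs[1, 2], z = dirs[1, 3])
    } else {
      proteins[[length(proteins) + 1]] <-
        data.frame(type = u$type, id = u$group, group = u$group,
                   x = dirs[1, 1], y = dirs[1, 2], z = dirs[1, 3])
    }
  }
  pigments <- do.call(rbind, pieces)
  # canonical column order (TSV dialect) plus derived columns
  pigments <- pigments[, c("cluster_id", "cluster_type", "pigment_class",
                           "ring_index",
                           "mg_x", "mg_y", "mg_z",
                           "nb_x", "nb_y", "nb_z",
                           "nd_x", "nd_y", "nd_z")]
  rownames(pigments) <- NULL
  finalize_vesicle(pigments, composition, config,
                   proteins = do.call(rbind, proteins), params = params)
}

#' Build the low-light-adapted reference vesicle
#'
#' The reference composition: 63 LH2 complexes, 11 dimeric plus 2 monomeric
#' RC-LH1-PufX complexes (12 dimer-equivalents, 24 RCs), 4 cytochrome bc1
#' dimers and 2 ATP synthases on a 50 nm inner-diameter sphere, carrying
#' 2469 BChls in total (27 per LH2 including the 9 non-network B800s, 28
#' B875 per RC-LH1 monomer half, 4 per RC).
#'
#' @inheritParams build_vesicle
#' @return A `vesicle_model`; see [build_vesicle()].
#' @export
#' @examples
#' \donttest{
#' v <- build_reference_vesicle()
#' v$total_bchl        # 2469
#' v$stoichiometry_s   # 2.625
#' }
build_reference_vesicle <- function(config = geometry_config(),
                                    params = exciton_params()) {
  build_vesicle(composition_spec(n_bc1_dimers = 4, n_l_dimers = 12,
                                 n_lh2 = 63, n_l_monomers = 2,
                                 n_atp_synthase = 2),
                config = config, params = params)
}

#' @export
print.vesicle_model <- function(x, ...) {
  cat("Chromatophore vesicle model\n")
  cat(sprintf("  LH2: %d   RC-LH1 dimer-equivalents: %d (monomers: %d)\n",
              x$n_lh2, x$n_l_dimers, x$n_l_monomers))
  cat(sprintf("  RCs: %d   cytbc1 dimers: %d   ATP synthases: %d\n",
              x$n_rc, x$n_bc1_dimers, x$n_atp_synthase))
  cat(sprintf("  BChls: %d (network clusters: %d)   LH2:RC s = %.4g\n",
              x$total_bchl, nrow(x$clusters), x$stoichiometry_s))
  cat(sprintf("  inner diameter: %g nm\n", x$inner_diameter_nm))
  invisible(x)
}
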