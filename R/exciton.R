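#' Point-dipole coupling between two pigments
#'
#' Coupling of two Qy transition dipoles in the point-dipole approximation,
#' V = C (d_i.d_j / r^3 - 3 (d_i.r)(d_j.r) / r^5), valid for pigment
#' separations beyond ~1 nm. `C` carries the dipole strengths and dielectric
#' screening; with C in Angstrom^3 cm^-1 and r in Angstrom, V is in cm^-1.
#'
#' @param pigment_i,pigment_j one-row pigment data.frames (as in
#'   `vesicle_model$pigments`) carrying `mg_x..mg_z` and `dip_x..dip_z`.
#' @param C coupling constant, Angstrom^3 cm^-1.
#' @return coupling in cm^-1 (symmetric in i, j).
#' @export
dipole_coupling <- function(pigment_i, pigment_j, C = 348000) {
  di <- c(pigment_i$dip_x, pigment_i$dip_y, pigment_i$dip_z)
  dj <- c(pigment_j$dip_x, pigment_j$dip_y, pigment_j$dip_z)
  r <- c(pigment_j$mg_x - pigment_i$mg_x,
         pigment_j$mg_y - pigment_i$mg_y,
         pigment_j$mg_z - pigment_i$mg_z)
  r2 <- sum(r^2)
  if (r2 < 1e-12) stop("zero separation between pigments")
  rlen <- sqrt(r2)
  C * (sum(di * dj) / rlen^3 - 3 * sum(di * r) * sum(dj * r) / rlen^5)
}

# Vectorized all-pairs dipole couplings between two pigment sets (n x m).
coupling_matrix <- function(p1, p2, C) {
  n <- nrow(p1); m <- nrow(p2)
  Rx <- matrix(p2$mg_x, n, m, byrow = TRUE) - p1$mg_x
  Ry <- matrix(p2$mg_y, n, m, byrow = TRUE) - p1$mg_y
  Rz <- matrix(p2$mg_z, n, m, byrow = TRUE) - p1$mg_z
  r2 <- Rx^2 + Ry^2 + Rz^2
  if (any(r2 < 1e-12 & row(r2) != col(r2) | (n != m) & r2 < 1e-12))
    stop("zero separation between pigments")
  dd <- p1$dip_x %o% p2$dip_x + p1$dip_y %o% p2$dip_y +
    p1$dip_z %o% p2$dip_z
  d1r <- p1$dip_x * Rx + p1$dip_y * Ry + p1$dip_z * Rz
  d2r <- Rx * matrix(p2$dip_x, n, m, byrow = TRUE) +
    Ry * matrix(p2$dip_y, n, m, byrow = TRUE) +
    Rz * matrix(p2$dip_z, n, m, byrow = TRUE)
  r <- sqrt(r2)
  V <- C * (dd / r^3 - 3 * d1r * d2r / r^5)
  V[!is.finite(V)] <- 0  # self-pairs (diagonal when p1 == p2)
  V
}

#' Extract the network pigments of one cluster
#'
#' @param vesicle a `vesicle_model`.
#' @param cluster_id cluster identifier from `vesicle$clusters`.
#' @return list with `cluster_id`, `cluster_type`, `complex_id` and the
#'   ring-ordered network `pigments` data.frame.
#' @export
cluster_pigments <- function(vesicle, cluster_id) {
  meta <- vesicle$clusters[vesicle$clusters$cluster_id == cluster_id, ]
  if (nrow(meta) != 1) stop("unknown cluster_id: ", cluster_id)
  p <- vesicle$pigments
  rows <- p[p$cluster_id == cluster_id & p$pigment_class != "B800", ]
  rows <- rows[order(rows$ring_index), ]
  list(cluster_id = cluster_id, cluster_type = meta$cluster_type,
       complex_id = meta$complex_id, pigments = rows)
}

#' Effective exciton Hamiltonian of one BChl cluster
#'
#' Diagonal entries are the registry site energies (alternating
#' alpha/beta around B850 rings, uniform on B875, special-pair and accessory
#' energies in the RC). Cyclic nearest-neighbour couplings of the rings
#' alternate between the intra- and inter-alpha-beta-dimer registry values,
#' and the RC special pair coupling is fixed; every other off-diagonal
#' element comes from the point-dipole formula.
#'
#' @param cluster a cluster as returned by [cluster_pigments()], or any list
#'   with `cluster_type` and a ring-ordered `pigments` data.frame.
#' @param params an [exciton_params()] registry.
#' @return symmetric `N_I` x `N_I` matrix, cm^-1.
#' @export
site_hamiltonian <- function(cluster, params = exciton_params()) {
  p <- cluster$pigments
  n <- nrow(p)
  if (n < 1) stop("empty cluster")
  H <- if (n > 1) coupling_matrix(p, p, params$dipole_constant_C)
       else matrix(0, 1, 1)
  diag(H) <- p$site_energy
  nc <- params$nn_couplings
  if (cluster$cluster_type %in% c("LH2", "LH1") && n > 1) {
    if (n %% 2 != 0)
      stop("ring cluster with odd pigment count (", n,
           "): cannot alternate intra/inter-dimer couplings")
    v1 <- if (cluster$cluster_type == "LH2") nc$v1_lh2 else nc$v1_lh1
    v2 <- if (cluster$cluster_type == "LH2") nc$v2_lh2 else nc$v2_lh1
    for (i in seq_len(n)) {
      j <- if (i < n) i + 1L else 1L
      v <- if (i %% 2 == 1) v1 else v2
      H[i, j] <- v; H[j, i] <- v
    }
  } else if (cluster$cluster_type %in% c("LH2", "LH1")) {
    # single-pigment toy cluster: no neighbour pairs to override
  } else if (cluster$cluster_type == "RC") {
    sp <- which(p$pigment_class == "RC_special")
    if (length(sp) != 2)
      stop("RC cluster must have exactly 2 special-pair pigments")
    H[sp[1], sp[2]] <- nc$v_rc; H[sp[2], sp[1]] <- nc$v_rc
  } else stop("unknown cluster_type: ", cluster$cluster_type)
  H
}

#' Exciton states and thermal populations of a cluster
#'
#' Eigendecomposition of the effective Hamiltonian, with energies in
#' ascending order, orthonormal coefficient columns, and Boltzmann weights
#' over the exciton energies at the registry temperature (excitation
#' thermalizes within a cluster faster than it transfers between clusters).
#'
#' @param H symmetric site Hamiltonian, cm^-1.
#' @param linewidth Gaussian exciton linewidth of this cluster, cm^-1.
#' @param params an [exciton_params()] registry (temperature, Boltzmann
#'   constant).
#' @return Object of class `exciton_basis`: `energies`, `coefficients`
#'   (columns are states), `boltzmann_weights`, `linewidth`.
#' @export
exciton_states <- function(H, linewidth = NULL,
                           params = exciton_params()) {
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("Hamiltonian must be symmetric")
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  energies <- e$values[ord]
  coeff <- e$vectors[, ord, drop = FALSE]
  beta <- 1 / (params$k_boltzmann * params$temperature)
  w <- exp(-beta * (energies - energies[1]))
  w <- w / sum(w)
  structure(list(energies = energies, coefficients = coeff,
                 boltzmann_weights = w, linewidth = linewidth),
            class = "exciton_basis")
}

#' Gaussian spectral overlap of donor emission and acceptor absorption
#'
#' Lineshapes are Gaussians centred on the exciton energies; the donor
#' emission spectrum is the absorption lineshape red-shifted by `shift_S`.
#' With unit-area Gaussians of standard deviations `sigma_donor` and
#' `sigma_acceptor`, the overlap integral has the closed form
#' `exp(-(de - S)^2 / (2 s2)) / sqrt(2 pi s2)` with
#' `s2 = sigma_donor^2 + sigma_acceptor^2` and `de = eps_donor -
#' eps_acceptor`. The `"literal"` convention instead uses lineshapes with
#' exponent `-((E - eps)/sigma)^2` and prefactor `1/(sqrt(2 pi) sigma)`
#' (which do not integrate to one); see the methods vignette.
#'
#' @param eps_donor,eps_acceptor exciton energies, cm^-1 (vectorized).
#' @param sigma_donor,sigma_acceptor linewidths, cm^-1.
#' @param shift_S donor emission red-shift, cm^-1.
#' @param lineshape `"normalized"` or `"literal"`.
#' @return overlap in (cm^-1)^-1.
#' @export
#' @examples
#' spectral_overlap(12500, 12500, 188, 188) # 1/(2*188*sqrt(pi))
spectral_overlap <- function(eps_donor, eps_acceptor,
                             sigma_donor, sigma_acceptor,
                             shift_S = 0,
                             lineshape = c("normalized", "literal")) {
  lineshape <- match.arg(lineshape)
  stopifnot(all(sigma_donor > 0), all(sigma_acceptor > 0))
  de <- (eps_donor - shift_S) - eps_acceptor
  if (lineshape == "normalized") {
    s2 <- sigma_donor^2 + sigma_acceptor^2
    exp(-de^2 / (2 * s2)) / sqrt(2 * pi * s2)
  } else {
    s2 <- sigma_donor^2 + sigma_acceptor^2
    0.5 * exp(-de^2 / s2) / sqrt(pi * s2)
  }
}

sigma_for_type <- function(cluster_type, params) {
  switch(cluster_type,
         LH2 = params$sigma_lh2,
         LH1 = params$sigma_lh1,
         RC = params$sigma_rc,
         stop("unknown cluster_type: ", cluster_type))
}

#' Generalized Foerster transfer rate between two clusters
#'
#' Rotates the inter-cluster point-dipole coupling matrix into the exciton
#' bases of donor and acceptor and sums Boltzmann-weighted squared couplings
#' times spectral overlaps over all donor/acceptor exciton pairs:
#' k = (2 pi / hbar) sum_mu,nu p_mu |(mu|H_IJ|nu)|^2 J_mu,nu. LH1<->RC
#' transfer inside one RC-LH1 complex bypasses the computed value and uses
#' the fixed registry rates ((35 ps)^-1 forward, (8 ps)^-1 back), which were
#' calibrated against the observed excitation lifetime.
#'
#' @param donor,acceptor clusters from [cluster_pigments()].
#' @param donor_basis,acceptor_basis matching [exciton_states()] objects
#'   (computed from [site_hamiltonian()] if omitted).
#' @param params an [exciton_params()] registry.
#' @return rate in s^-1.
#' @export
transfer_rate <- function(donor, acceptor,
                          donor_basis = NULL, acceptor_basis = NULL,
                          params = exciton_params()) {
  if (identical(donor$cluster_id, acceptor$cluster_id))
    stop("donor and acceptor must be distinct clusters")
  same_complex <- !is.na(donor$complex_id) &&
    identical(donor$complex_id, acceptor$complex_id)
  if (same_complex && donor$cluster_type == "LH1" &&
      acceptor$cluster_type == "RC")
    return(params$k_lh1_rc)
  if (same_complex && donor$cluster_type == "RC" &&
      acceptor$cluster_type == "LH1")
    return(params$k_rc_lh1)

  if (is.null(donor_basis))
    donor_basis <- exciton_states(site_hamiltonian(donor, params),
                                  sigma_for_type(donor$cluster_type, params),
                                  params)
  if (is.null(acceptor_basis))
    acceptor_basis <- exciton_states(
      site_hamiltonian(acceptor, params),
      sigma_for_type(acceptor$cluster_type, params), params)

  V <- coupling_matrix(donor$pigments, acceptor$pigments,
                       params$dipole_constant_C)
  M <- t(donor_basis$coefficients) %*% V %*% acceptor_basis$coefficients
  sd <- donor_basis$linewidth
  if (is.null(sd)) sd <- sigma_for_type(donor$cluster_type, params)
  sa <- acceptor_basis$linewidth
  if (is.null(sa)) sa <- sigma_for_type(acceptor$cluster_type, params)
  J <- spectral_overlap(outer(donor_basis$energies,
                              rep(1, length(acceptor_basis$energies))),
                        outer(rep(1, length(donor_basis$energies)),
                              acceptor_basis$energies),
                        sd, sa, params$shift_S, params$lineshape)
  w <- donor_basis$boltzmann_weights
  2 * pi / params$hbar * sum(w * (M^2 * J))
}

#' Neighbour adjacency of a vesicle's pigment clusters
#'
#' Two clusters are neighbours when their minimal Mg-Mg distance does not
#' exceed `cutoff`; the r^-3 decay of the dipole coupling makes longer-range
#' rates negligible against the (10 ps)^-1 transfer scale. LH1-RC pairs of
#' the same RC-LH1 complex are always neighbours.
#'
#' @param vesicle a `vesicle_model`.
#' @param cutoff minimal Mg-Mg distance, Angstrom.
#' @return symmetric logical adjacency matrix with cluster_id dimnames.
#' @export
neighbor_graph <- function(vesicle, cutoff = 70) {
  stopifnot(cutoff > 0)
  cl <- vesicle$clusters
  nC <- nrow(cl)
  p <- vesicle$pigments[vesicle$pigments$pigment_class != "B800", ]
  coords <- lapply(cl$cluster_id, function(cid) {
    as.matrix(p[p$cluster_id == cid, c("mg_x", "mg_y", "mg_z")])
  })
  reach <- vapply(seq_len(nC), function(i) {
    ctr <- c(cl$center_x[i], cl$center_y[i], cl$center_z[i])
    max(sqrt(colSums((t(coords[[i]]) - ctr)^2)))
  }, numeric(1))
  A <- matrix(FALSE, nC, nC,
              dimnames = list(cl$cluster_id, cl$cluster_id))
  ctrs <- as.matrix(cl[, c("center_x", "center_y", "center_z")])
  for (i in seq_len(nC - 1)) {
    for (j in (i + 1):nC) {
      cd <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
      if (cd > cutoff + reach[i] + reach[j]) next
      xi <- coords[[i]]; xj <- coords[[j]]
      d2min <- min(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                     2 * xi %*% t(xj))
      if (d2min <= cutoff^2) A[i, j] <- A[j, i] <- TRUE
    }
  }
  # intra-complex LH1-RC edges always present
  lhrc <- cl$cluster_type %in% c("LH1", "RC")
  for (cx in unique(cl$complex_id[lhrc])) {
    idx <- which(cl$complex_id == cx & lhrc)
    if (length(idx) == 2) A[idx[1], idx[2]] <- A[idx[2], idx[1]] <- TRUE
  }
  A
}

#' Assemble the excitation-migration network of a vesicle
#'
#' Computes exciton bases for every cluster, the neighbour graph, all
#' pairwise generalized Foerster rates over neighbour edges (fixed rates for
#' intra-complex LH1<->RC), and assembles the rate matrix, loss channels and
#' initial state into a `transfer_network` ready for [quantum_yield()].
#'
#' @param vesicle a `vesicle_model`.
#' @param params an [exciton_params()] registry.
#' @return A `transfer_network` (see [rate_matrix()]) with an additional
#'   `rates` element: the dense donor-by-acceptor rate matrix, s^-1.
#' @export
build_transfer_network <- function(vesicle, params = exciton_params()) {
  cl <- vesicle$clusters
  nC <- nrow(cl)
  clusters <- lapply(cl$cluster_id, cluster_pigments, vesicle = vesicle)
  names(clusters) <- cl$cluster_id
  bases <- lapply(clusters, function(cc) {
    exciton_states(site_hamiltonian(cc, params),
                   sigma_for_type(cc$cluster_type, params), params)
  })
  A <- neighbor_graph(vesicle, params$neighbor_cutoff)
  k <- matrix(0, nC, nC, dimnames = dimnames(A))
  for (i in seq_len(nC)) {
    for (j in seq_len(nC)) {
      if (i == j || !A[i, j]) next
      k[i, j] <- transfer_rate(clusters[[i]], clusters[[j]],
                               bases[[i]], bases[[j]], params)
    }
  }
  rc <- as.integer(cl$cluster_type == "RC")
  P0 <- cl$n_pigments / sum(cl$n_pigments)
  net <- rate_matrix(k, params$k_diss, params$k_cs, rc,
                     cluster_ids = cl$cluster_id, initial_state = P0)
  net$rates <- k
  net
}
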