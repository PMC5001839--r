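# Shared fixtures, built in code. The reference vesicle and its transfer
# network are expensive (~3 s); build them once per test run.

.fixture_env <- new.env(parent = emptyenv())

ref_vesicle <- function() {
  if (is.null(.fixture_env$vesicle))
    .fixture_env$vesicle <- build_reference_vesicle()
  .fixture_env$vesicle
}

ref_network <- function() {
  if (is.null(.fixture_env$network))
    .fixture_env$network <- build_transfer_network(ref_vesicle())
  .fixture_env$network
}

mini_vesicle <- function(n_lh2 = 6, n_l_dimers = 2, seed = 7L) {
  build_vesicle(
    composition_spec(0, n_l_dimers, n_lh2, n_atp_synthase = 0),
    geometry_config(placement_radius = 200, seed = seed))
}

# A hand-built single ring cluster with explicit dipoles (bypasses the
# builder) for Hamiltonian-level tests.
toy_ring_cluster <- function(n = 18, radius = 26, ctype = "LH2",
                             centre = c(0, 0, 0)) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  classes <- if (ctype == "LH2") rep_len(c("B850_alpha", "B850_beta"), n)
             else rep("B875", n)
  sgn <- rep_len(c(1, -1), n)
  pig <- data.frame(
    cluster_id = "TOY", cluster_type = ctype,
    pigment_class = classes, ring_index = seq_len(n),
    mg_x = radius * cos(theta) + centre[1],
    mg_y = radius * sin(theta) + centre[2],
    mg_z = rep(centre[3], n),
    dip_x = -sgn * sin(theta), dip_y = sgn * cos(theta),
    dip_z = rep(0, n))
  pig$site_energy <- site_energy_for_class(pig$pigment_class)
  list(cluster_id = "TOY", cluster_type = ctype, complex_id = "TOY",
       pigments = pig)
}

# Single-pigment cluster helper for scalar-rate tests.
point_cluster <- function(id, pos, dip, energy_class = "B875",
                          ctype = "LH1") {
  pig <- data.frame(
    cluster_id = id, cluster_type = ctype, pigment_class = energy_class,
    ring_index = 1L,
    mg_x = pos[1], mg_y = pos[2], mg_z = pos[3],
    dip_x = dip[1], dip_y = dip[2], dip_z = dip[3])
  pig$site_energy <- site_energy_for_class(energy_class)
  list(cluster_id = id, cluster_type = ctype, complex_id = id,
       pigments = pig)
}

# Random sparse excitation-transfer network for property tests.
random_network <- function(n, seed, density = 0.5) {
  set.seed(seed)
  k <- matrix(stats::runif(n * n, 1e9, 5e10), n, n)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  k[!mask] <- 0
  diag(k) <- 0
  rc <- rep(0, n)
  rc[sample.int(n, max(1, floor(n / 3)))] <- 1
  p0 <- stats::runif(n)
  p0 <- p0 / sum(p0)
  rate_matrix(k, k_diss = 1e9, k_cs = 1 / 3e-12, rc_indicator = rc,
              initial_state = p0)
}
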