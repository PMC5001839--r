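test_that("point-dipole coupling matches hand-evaluated cases", {
  pig <- function(pos, dip) data.frame(
    mg_x = pos[1], mg_y = pos[2], mg_z = pos[3],
    dip_x = dip[1], dip_y = dip[2], dip_z = dip[3])
  # parallel dipoles perpendicular to the separation: C / r^3
  expect_equal(dipole_coupling(pig(c(0, 0, 0), c(0, 0, 1)),
                               pig(c(10, 0, 0), c(0, 0, 1))), 348)
  # head-to-tail collinear: C (1 - 3) / r^3
  expect_equal(dipole_coupling(pig(c(0, 0, 0), c(1, 0, 0)),
                               pig(c(10, 0, 0), c(1, 0, 0))), -696)
  # mutually and separation-orthogonal: both terms vanish
  expect_equal(dipole_coupling(pig(c(0, 0, 0), c(1, 0, 0)),
                               pig(c(0, 0, 10), c(0, 1, 0))), 0)
  # symmetry and exact r^-3 scaling
  set.seed(42)
  for (rep in 1:5) {
    d1 <- transition_dipole(c(0, 0, 0), rnorm(3))
    d2 <- transition_dipole(c(0, 0, 0), rnorm(3))
    p1 <- pig(c(0, 0, 0), d1)
    expect_equal(dipole_coupling(p1, pig(c(12, 3, 4), d2)),
                 dipole_coupling(pig(c(12, 3, 4), d2), p1))
    expect_equal(dipole_coupling(p1, pig(c(24, 6, 8), d2)),
                 dipole_coupling(p1, pig(c(12, 3, 4), d2)) / 8)
  }
  expect_error(dipole_coupling(pig(c(0, 0, 0), c(1, 0, 0)),
                               pig(c(0, 0, 0), c(0, 1, 0))),
               "zero separation")
})

test_that("site Hamiltonian lays out registry energies and couplings", {
  ring <- toy_ring_cluster()
  H <- site_hamiltonian(ring)
  expect_equal(dim(H), c(18L, 18L))
  expect_equal(sum(diag(H)), 9 * (12459 + 12625))
  expect_equal(H, t(H))
  # cyclic alternating nearest-neighbour overrides
  expect_equal(H[1, 2], 363); expect_equal(H[2, 3], 320)
  expect_equal(H[17, 18], 363); expect_equal(H[18, 1], 320)
  # RC: fixed special-pair coupling on the diagonal block
  v <- mini_vesicle(n_lh2 = 1, n_l_dimers = 1)
  rc_id <- v$clusters$cluster_id[v$clusters$cluster_type == "RC"][1]
  Hrc <- site_hamiltonian(cluster_pigments(v, rc_id))
  expect_equal(dim(Hrc), c(4L, 4L))
  expect_equal(Hrc[1, 2], 500)
  expect_equal(diag(Hrc), c(12092, 12092, 12581, 12581))
  # odd ring cannot alternate
  odd <- toy_ring_cluster(n = 17)
  odd$pigments$pigment_class <- "B875"
  odd$pigments$site_energy <- 12344
  odd$cluster_type <- "LH1"
  expect_error(site_hamiltonian(odd), "odd")
})

test_that("exciton states: two-level closed form and basis invariants", {
  # E +/- V for a symmetric dimer
  H2 <- matrix(c(12500, 300, 300, 12500), 2, 2)
  b <- exciton_states(H2, 188)
  expect_equal(b$energies, c(12200, 12800))
  # diagonal H: coefficients are (signed) unit vectors
  Hd <- diag(c(12344, 12600, 12100))
  bd <- exciton_states(Hd, 235)
  expect_equal(abs(bd$coefficients),
               diag(3)[, order(diag(Hd))], tolerance = 1e-12)
  # equal energies: uniform Boltzmann weights
  bu <- exciton_states(diag(rep(12344, 4)), 235)
  expect_equal(bu$boltzmann_weights, rep(0.25, 4))
  # orthonormality + weights sorted along energy
  H <- site_hamiltonian(toy_ring_cluster())
  bb <- exciton_states(H, 188)
  expect_lt(max(abs(crossprod(bb$coefficients) - diag(18))), 1e-10)
  expect_true(all(diff(bb$energies) > -1e-9))
  expect_true(all(diff(bb$boltzmann_weights) <= 1e-15))
  expect_equal(sum(bb$boltzmann_weights), 1)
  # ring delocalization pushes the band bottom below every site energy
  expect_lt(bb$energies[1], 12459)
  expect_error(exciton_states(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("eigensolver agrees with a characteristic-polynomial oracle", {
  # reduced 4-ring with alternating energies/couplings
  H <- matrix(0, 4, 4)
  diag(H) <- c(12459, 12625, 12459, 12625)
  for (i in 1:4) {
    j <- if (i < 4) i + 1 else 1
    v <- if (i %% 2 == 1) 363 else 320
    H[i, j] <- H[j, i] <- v
  }
  # char-poly coefficients from sums of principal minors (independent route)
  n <- 4
  coefs <- sapply(1:n, function(k) {
    sum(apply(utils::combn(n, k), 2, function(idx)
      det(H[idx, idx, drop = FALSE])))
  })
  poly <- c(1, -coefs[1], coefs[2], -coefs[3], coefs[4]) # lambda^4 ... const
  roots <- sort(Re(polyroot(rev(poly))))
  b <- exciton_states(H, 188)
  # polyroot works from O(1e16) characteristic coefficients; a few parts
  # in 1e7 is the attainable agreement
  expect_equal(b$energies, roots, tolerance = 2e-6)
})

test_that("spectral overlap matches its closed form and quadrature", {
  # resonant, equal widths: 1 / (2 sigma sqrt(pi))
  expect_equal(spectral_overlap(12500, 12500, 188, 188),
               1 / (2 * 188 * sqrt(pi)))
  expect_equal(spectral_overlap(12500, 12500, 188, 188), 1.5006e-3,
               tolerance = 1e-4)
  # distant lines overlap not at all
  expect_lt(spectral_overlap(20000, 12000, 188, 235), 1e-40)
  # donor/acceptor exchange symmetry at S = 0, equal sigma
  expect_equal(spectral_overlap(12400, 12700, 188, 188),
               spectral_overlap(12700, 12400, 188, 188))
  # against numerical quadrature, both lineshape conventions
  gauss_n <- function(E, mu, s) exp(-(E - mu)^2 / (2 * s^2)) /
    (sqrt(2 * pi) * s)
  gauss_l <- function(E, mu, s) exp(-((E - mu) / s)^2) /
    (sqrt(2 * pi) * s)
  for (de in c(0, 150, 400, 900)) for (s in c(120, 188, 235)) {
    for (S in c(0, 100)) {
      num <- stats::integrate(function(E)
        gauss_n(E, 12500 - S, s) * gauss_n(E, 12500 - de, 235),
        lower = 8000, upper = 17000, rel.tol = 1e-12)$value
      expect_equal(spectral_overlap(12500, 12500 - de, s, 235, shift_S = S),
                   num, tolerance = 1e-10)
      numl <- stats::integrate(function(E)
        gauss_l(E, 12500 - S, s) * gauss_l(E, 12500 - de, 235),
        lower = 8000, upper = 17000, rel.tol = 1e-12)$value
      expect_equal(spectral_overlap(12500, 12500 - de, s, 235, shift_S = S,
                                    lineshape = "literal"),
                   numl, tolerance = 1e-10)
    }
  }
})

test_that("transfer rates: fixed LH1<->RC values and the scalar limit", {
  v <- mini_vesicle(n_lh2 = 1, n_l_dimers = 1)
  cl <- v$clusters
  lh1_id <- cl$cluster_id[cl$cluster_type == "LH1"][1]
  rc_id <- paste0(cl$complex_id[cl$cluster_id == lh1_id], "_RC")
  lh1 <- cluster_pigments(v, lh1_id)
  rc <- cluster_pigments(v, rc_id)
  expect_equal(transfer_rate(lh1, rc), 1 / 35e-12)
  expect_equal(transfer_rate(rc, lh1), 1 / 8e-12)

  # scalar case: k = (2 pi / hbar) V^2 J, hand-evaluated
  p <- exciton_params()
  c1 <- point_cluster("A", c(0, 0, 0), c(0, 0, 1))
  c2 <- point_cluster("B", c(20, 0, 0), c(0, 0, 1))
  V <- 348000 / 20^3
  J <- 1 / (2 * p$sigma_lh1 * sqrt(pi))
  k_hand <- 2 * pi / 5.3088e-12 * V^2 * J
  expect_equal(transfer_rate(c1, c2, params = p), k_hand, tolerance = 1e-12)
  # equal site energies: forward and backward rates coincide
  expect_equal(transfer_rate(c1, c2, params = p),
               transfer_rate(c2, c1, params = p))
  expect_error(transfer_rate(c1, c1, params = p), "distinct")
})

test_that("rates are invariant under rigid rotation and translation", {
  v <- mini_vesicle(n_lh2 = 2, n_l_dimers = 1, seed = 3L)
  net <- build_transfer_network(v)
  # random rigid motion of every coordinate column
  set.seed(99)
  ax <- transition_dipole(c(0, 0, 0), rnorm(3))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  shift <- c(120, -40, 75)
  v2 <- v
  for (pre in c("mg", "nb", "nd")) {
    cols <- paste0(pre, c("_x", "_y", "_z"))
    v2$pigments[, cols] <-
      sweep(as.matrix(v$pigments[, cols]) %*% t(R), 2, shift, `+`)
  }
  v2 <- chromatophore:::vesicle_from_pigments(
    v2$pigments[, c("cluster_id", "cluster_type", "pigment_class",
                    "ring_index", "mg_x", "mg_y", "mg_z",
                    "nb_x", "nb_y", "nb_z", "nd_x", "nd_y", "nd_z")])
  net2 <- build_transfer_network(v2)
  expect_equal(net2$rates[net$cluster_ids, net$cluster_ids], net$rates,
               tolerance = 1e-8)
})

test_that("neighbour graph is symmetric, cutoff-driven, and RC-complete", {
  # two LH2 rings 300 A apart: no edge at a 70 A cutoff
  far <- rbind(toy_ring_cluster(centre = c(0, 0, 0))$pigments,
               within(toy_ring_cluster(centre = c(300, 0, 0))$pigments,
                      cluster_id <- "TOY2"))
  far$nb_x <- far$mg_x - 1.45 * far$dip_x
  far$nb_y <- far$mg_y - 1.45 * far$dip_y
  far$nb_z <- far$mg_z - 1.45 * far$dip_z
  far$nd_x <- far$mg_x + 1.45 * far$dip_x
  far$nd_y <- far$mg_y + 1.45 * far$dip_y
  far$nd_z <- far$mg_z + 1.45 * far$dip_z
  vfar <- chromatophore:::vesicle_from_pigments(
    far[, c("cluster_id", "cluster_type", "pigment_class", "ring_index",
            "mg_x", "mg_y", "mg_z", "nb_x", "nb_y", "nb_z",
            "nd_x", "nd_y", "nd_z")])
  A <- neighbor_graph(vfar, 70)
  expect_false(any(A))

  v <- ref_vesicle()
  Av <- neighbor_graph(v, 70)
  expect_identical(Av, t(Av))
  expect_false(any(diag(Av)))
  cl <- v$clusters
  # every RC is wired to the LH1 of its own complex
  for (rc in which(cl$cluster_type == "RC")) {
    partner <- which(cl$complex_id == cl$complex_id[rc] &
                       cl$cluster_type == "LH1")
    expect_length(partner, 1)
    expect_true(Av[rc, partner])
  }
})
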