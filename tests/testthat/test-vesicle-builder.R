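test_that("transition dipole is the ND-NB unit vector", {
  expect_equal(transition_dipole(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_equal(transition_dipole(c(1, 1, 1), c(1, 1, 4)), c(0, 0, 1))
  expect_equal(transition_dipole(c(0, 0, 0), c(3, 4, 0)), c(0.6, 0.8, 0))
  expect_error(transition_dipole(c(1, 2, 3), c(1, 2, 3)), "coincident")
})

test_that("reference vesicle reproduces the published composition", {
  v <- ref_vesicle()
  expect_identical(v$total_bchl, 2469L)
  expect_identical(nrow(v$clusters), 111L)           # 63 + 24 + 24
  expect_identical(v$n_lh2, 63L)
  expect_identical(v$n_rc, 24L)
  expect_identical(v$n_l_dimers, 12L)
  expect_identical(v$n_bc1_dimers, 4L)
  expect_identical(v$n_atp_synthase, 2L)
  expect_equal(v$stoichiometry_s, 2.625)
  counts <- table(v$clusters$cluster_type)
  expect_equal(as.integer(counts[c("LH2", "LH1", "RC")]), c(63L, 24L, 24L))
  expect_true(all(v$clusters$n_pigments[v$clusters$cluster_type == "LH2"]
                  == 18))
  expect_true(all(v$clusters$n_pigments[v$clusters$cluster_type == "LH1"]
                  == 28))
  expect_true(all(v$clusters$n_pigments[v$clusters$cluster_type == "RC"]
                  == 4))
})

test_that("general compositions honour the counting identity", {
  # identity case equals the reference composition
  v <- build_vesicle(composition_spec(4, 12, 63, n_l_monomers = 2))
  expect_identical(v$total_bchl, 2469L)
  expect_equal(v$stoichiometry_s, 2.625)
  # bc1 carries no pigments
  v1 <- build_vesicle(composition_spec(1, 12, 63, n_l_monomers = 2))
  expect_identical(v1$total_bchl, 2469L)
  # n_rc = 2 n_L
  v2 <- build_vesicle(composition_spec(4, 1, 10),
                      geometry_config(placement_radius = 200))
  expect_identical(v2$n_rc, 2L)
  # total_bchl = 27 n_lh2 + 64 n_L for several compositions
  for (cmp in list(c(0, 1, 3), c(2, 3, 10), c(1, 2, 0))) {
    v <- build_vesicle(composition_spec(cmp[1], cmp[2], cmp[3]),
                       geometry_config(placement_radius = 220))
    expect_identical(v$total_bchl, as.integer(27 * cmp[3] + 64 * cmp[2]))
  }
})

test_that("site energies follow the class registry", {
  v <- ref_vesicle()
  p <- v$pigments
  expect_equal(unique(p$site_energy[p$pigment_class == "B850_alpha"]), 12459)
  expect_equal(unique(p$site_energy[p$pigment_class == "B850_beta"]), 12625)
  expect_equal(unique(p$site_energy[p$pigment_class == "B875"]), 12344)
  expect_equal(unique(p$site_energy[p$pigment_class == "RC_special"]), 12092)
  expect_equal(unique(p$site_energy[p$pigment_class == "RC_accessory"]),
               12581)
  expect_true(all(is.na(p$site_energy[p$pigment_class == "B800"])))
  # dipoles are unit vectors
  norms <- sqrt(p$dip_x^2 + p$dip_y^2 + p$dip_z^2)
  expect_true(all(abs(norms - 1) < 1e-12))
})

test_that("ring geometry is ideal: equal consecutive Mg-Mg spacings", {
  v <- mini_vesicle(n_lh2 = 2, n_l_dimers = 1)
  p <- v$pigments
  for (cid in unique(p$cluster_id[p$cluster_type %in% c("LH2", "LH1")])) {
    ring <- p[p$cluster_id == cid & p$pigment_class != "B800", ]
    ring <- ring[order(ring$ring_index), ]
    xyz <- as.matrix(ring[, c("mg_x", "mg_y", "mg_z")])
    nxt <- rbind(xyz[-1, ], xyz[1, ])
    d <- sqrt(rowSums((nxt - xyz)^2))
    expect_lt(max(d) - min(d), 1e-6)
    # published ~9 A nearest-neighbour spacing
    expect_gt(mean(d), 8); expect_lt(mean(d), 10)
  }
})

test_that("placement is deterministic in the seed and non-overlapping", {
  cfg <- geometry_config(placement_radius = 220, seed = 11L)
  v1 <- build_vesicle(composition_spec(1, 2, 8), cfg)
  v2 <- build_vesicle(composition_spec(1, 2, 8), cfg)
  expect_identical(v1$pigments, v2$pigments)
  v3 <- build_vesicle(composition_spec(1, 2, 8),
                      geometry_config(placement_radius = 220, seed = 12L))
  expect_false(identical(v1$pigments, v3$pigments))

  # hard-core exclusion between complexes of different groups
  pr <- v1$proteins
  hard <- c(LH2 = 36, RCLH1 = 52, bc1 = 44, atp = 36)
  ctr <- 220 * as.matrix(pr[, c("x", "y", "z")])
  for (i in seq_len(nrow(pr) - 1)) {
    for (j in (i + 1):nrow(pr)) {
      if (pr$group[i] == pr$group[j]) next
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      expect_gte(d, 0.998 * (hard[[pr$type[i]]] + hard[[pr$type[j]]]))
    }
  }
})

test_that("placement failure on an overcrowded sphere is explicit", {
  expect_error(
    build_vesicle(composition_spec(0, 2, 40),
                  geometry_config(placement_radius = 80,
                                  max_attempts = 50)),
    "placement failure")
})

test_that("pigment tables round-trip through TSV", {
  v <- mini_vesicle(n_lh2 = 3, n_l_dimers = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pigment_table(v, path)
  v2 <- read_pigment_table(path)
  expect_identical(v2$total_bchl, v$total_bchl)
  expect_identical(nrow(v2$clusters), nrow(v$clusters))
  expect_equal(v2$pigments$mg_x, v$pigments$mg_x, tolerance = 1e-5)
  expect_equal(v2$pigments$dip_x, v$pigments$dip_x, tolerance = 1e-4)
  expect_identical(v2$pigments$pigment_class, v$pigments$pigment_class)
  # an 18-row single-ring table forms one 18-pigment cluster
  one <- v$pigments[v$pigments$cluster_id == v$clusters$cluster_id[
    v$clusters$cluster_type == "LH2"][1], ]
  one <- one[one$pigment_class != "B800", ]
  path1 <- withr::local_tempfile(fileext = ".tsv")
  write_pigment_table(list(pigments = one), path1)
  v3 <- read_pigment_table(path1)
  expect_identical(nrow(v3$clusters), 1L)
  expect_identical(v3$clusters$n_pigments, 18L)
})

test_that("malformed pigment tables fail with line information", {
  v <- mini_vesicle(n_lh2 = 1, n_l_dimers = 1)
  p <- v$pigments

  # RC cluster with 3 pigments violates the 4-BChl invariant
  rc_id <- v$clusters$cluster_id[v$clusters$cluster_type == "RC"][1]
  drop1 <- p[!(p$cluster_id == rc_id & p$ring_index == 4 &
                 p$cluster_type == "RC"), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pigment_table(list(pigments = drop1), path)
  expect_error(read_pigment_table(path), "RC .* 4|requires 4")

  # unknown pigment class, with the offending line number
  bad <- p
  bad$pigment_class[5] <- "B999"
  write_pigment_table(list(pigments = bad), path)
  expect_error(read_pigment_table(path), "line 6.*B999")

  # duplicate (cluster_id, ring_index)
  dup <- rbind(p, p[1, ])
  write_pigment_table(list(pigments = dup), path)
  expect_error(read_pigment_table(path), "duplicate")
})

test_that("PDB-style input with MG/NB/ND atoms parses to the same model", {
  v <- mini_vesicle(n_lh2 = 1, n_l_dimers = 1)
  p <- v$pigments
  # write a minimal PDB: one chain per cluster (B800 as its own chain)
  chains <- c(LETTERS, letters)
  key <- paste(p$cluster_id, p$pigment_class == "B800")
  chain <- chains[match(key, unique(key))]
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(p))) {
    for (at in c("MG", "NB", "ND")) {
      serial <- serial + 1
      xyz <- unlist(p[i, paste0(tolower(at), c("_x", "_y", "_z"))])
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f",
        serial, at, "BCL", chain[i], p$ring_index[i],
        xyz[1], xyz[2], xyz[3]))
    }
  }
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  v2 <- read_pigment_table(path)
  expect_identical(v2$total_bchl, v$total_bchl)
  expect_setequal(v2$clusters$n_pigments, v$clusters$n_pigments)
  expect_equal(sort(table(v2$pigments$pigment_class)),
               sort(table(p$pigment_class)))
})
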