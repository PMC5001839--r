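#' Geometry configuration for synthetic vesicle construction
#'
#' Parameters of the idealized complex geometries and of the sphere-placement
#' algorithm. Distances are in Angstrom unless noted. Ring radii and the
#' alternating dipole tilt are chosen so that consecutive Mg-Mg spacings in
#' the B850 ring come out near the published ~9 Angstrom; nearest-neighbour
#' couplings are overridden by registry constants anyway, so only the
#' >1 nm inter-complex geometry influences computed transfer rates.
#'
#' The `placement_radius` is the mid-membrane sphere on which complex centres
#' sit; it exceeds the 25 nm inner (lumenal) radius by roughly half a
#' membrane thickness.
#'
#' @param inner_diameter_nm inner vesicle diameter, nm.
#' @param placement_radius radius of the sphere carrying complex centres.
#' @param b850_radius,b800_radius,b875_radius Mg ring radii.
#' @param b800_z axial offset of the B800 ring from the B850 plane.
#' @param n_b850,n_b800,n_b875 pigments per ring.
#' @param dipole_tilt_deg magnitude of the alternating out-of-plane tilt of
#'   ring dipoles (alpha +, beta -), degrees.
#' @param nbnd_half half the NB-ND atom separation used to synthesize NB/ND
#'   coordinates on either side of the Mg along the dipole.
#' @param rc_special_half half-separation of the RC special-pair Mg atoms.
#' @param rc_accessory_dist distance of accessory RC BChls from the RC
#'   centre.
#' @param hardcore_lh2,hardcore_rclh1,hardcore_bc1,hardcore_atp hard-core
#'   (half minimal centre-centre) radii used during placement; they exceed
#'   the pigment ring radii by roughly a protein shell, keeping
#'   inter-complex pigment separations above the ~1 nm point-dipole
#'   validity limit.
#' @param dimer_offset half the centre separation of the two monomers in an
#'   RC-LH1-PufX dimer.
#' @param placement `"contact"` grows a contact-packed arrangement (each
#'   complex anchored touching an earlier one, emulating the densely packed
#'   antenna domains seen in AFM); `"rsa"` is plain random sequential
#'   adsorption, which leaves wide lipid gaps and a sparser network.
#' @param contact_jitter standard deviation of the extra centre-centre slack
#'   added on top of contact distance, Angstrom.
#' @param max_attempts placement attempts per complex before giving up.
#' @param seed integer seed for the (only) stochastic stage, placement.
#' @return Object of class `geometry_config`.
#' @export
geometry_config <- function(inner_diameter_nm = 50,
                            placement_radius = 280,
                            b850_radius = 26, b800_radius = 31,
                            b875_radius = 40,
                            b800_z = -16.5,
                            n_b850 = 18, n_b800 = 9, n_b875 = 28,
                            dipole_tilt_deg = 10,
                            nbnd_half = 1.45,
                            rc_special_half = 3.9,
                            rc_accessory_dist = 13,
                            hardcore_lh2 = 36, hardcore_rclh1 = 52,
                            hardcore_bc1 = 44, hardcore_atp = 36,
                            dimer_offset = 52,
                            placement = c("contact", "rsa"),
                            contact_jitter = 2,
                            max_attempts = 20000,
                            seed = 1L) {
  placement <- match.arg(placement)
  seed <- as.integer(seed)
  stopifnot(inner_diameter_nm > 0, placement_radius > 0,
            b850_radius > 0, b800_radius > 0, b875_radius > 0,
            n_b850 >= 2, n_b850 %% 2 == 0,
            n_b875 >= 2, n_b875 %% 2 == 0,
            n_b800 >= 0, nbnd_half > 0,
            hardcore_lh2 > 0, hardcore_rclh1 > 0, hardcore_bc1 > 0,
            hardcore_atp > 0, dimer_offset > 0, max_attempts >= 1)
  structure(as.list(environment()), class = "geometry_config")
}

# Evaluate code with a deterministic RNG state, restoring the caller's.
with_placement_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rotation matrix taking the local +z axis onto unit vector n, composed with
# a rotation by `azimuth` about local z first.
local_frame <- function(n, azimuth = 0) {
  n <- n / sqrt(sum(n^2))
  # pick a reference not parallel to n
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  R <- cbind(e1, e2, n)
  ca <- cos(azimuth); sa <- sin(azimuth)
  Az <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
  R %*% Az
}

# Uniform random unit vector.
random_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    s <- sqrt(sum(v^2))
    if (s > 1e-8) return(v / s)
  }
}

# Local pigment layout for one complex type. Returns a data.frame with local
# coordinates (Angstrom) in the ring frame: z along the outward normal.
# Ring dipoles are tangential with an alternating out-of-plane tilt and,
# when `alternate_sign`, alternating tangential direction: consecutive
# alpha/beta Qy dipoles in B850/B875 rings point nearly antiparallel, which
# carries the oscillator strength into the thermally populated low excitons
# and sets the picosecond inter-complex transfer scale.
ring_pigments <- function(n, radius, z = 0, tilt_deg = 0, classes,
                          nbnd_half = 1.45, alternate_sign = TRUE) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  mg <- cbind(radius * cos(theta), radius * sin(theta), rep(z, n))
  tang <- cbind(-sin(theta), cos(theta), rep(0, n))
  sgn <- if (alternate_sign) rep_len(c(1, -1), n) else rep(1, n)
  tilt <- rep_len(c(tilt_deg, -tilt_deg), n) * pi / 180
  dip <- sgn * (cos(tilt) * tang) + sin(tilt) %o% c(0, 0, 1)
  dip <- dip / sqrt(rowSums(dip^2))
  data.frame(pigment_class = rep_len(classes, n),
             ring_index = seq_len(n),
             mg_x = mg[, 1], mg_y = mg[, 2], mg_z = mg[, 3],
             nb_x = mg[, 1] - nbnd_half * dip[, 1],
             nb_y = mg[, 2] - nbnd_half * dip[, 2],
             nb_z = mg[, 3] - nbnd_half * dip[, 3],
             nd_x = mg[, 1] + nbnd_half * dip[, 1],
             nd_y = mg[, 2] + nbnd_half * dip[, 2],
             nd_z = mg[, 3] + nbnd_half * dip[, 3],
             stringsAsFactors = FALSE)
}

rc_pigments <- function(config) {
  a <- config$rc_special_half
  b <- config$rc_accessory_dist
  h <- config$nbnd_half
  mg <- rbind(c(-a, 0, 0), c(a, 0, 0), c(0, -b, 0), c(0, b, 0))
  dip <- rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0), c(-1, 0, 0))
  data.frame(pigment_class = c("RC_special", "RC_special",
                               "RC_accessory", "RC_accessory"),
             ring_index = 1:4,
             mg_x = mg[, 1], mg_y = mg[, 2], mg_z = mg[, 3],
             nb_x = mg[, 1] - h * dip[, 1],
             nb_y = mg[, 2] - h * dip[, 2],
             nb_z = mg[, 3] - h * dip[, 3],
             nd_x = mg[, 1] + h * dip[, 1],
             nd_y = mg[, 2] + h * dip[, 2],
             nd_z = mg[, 3] + h * dip[, 3],
             stringsAsFactors = FALSE)
}

# Map local pigment coordinates into the vesicle frame: centre direction n
# (unit), placement radius R, in-plane rotation `azimuth`.
place_pigments <- function(local, n, R, azimuth) {
  M <- local_frame(n, azimuth)
  centre <- R * n
  xf <- function(prefix) {
    xyz <- as.matrix(local[, paste0(prefix, c("_x", "_y", "_z"))])
    sweep(xyz %*% t(M), 2, centre, `+`)
  }
  mg <- xf("mg"); nb <- xf("nb"); nd <- xf("nd")
  local$mg_x <- mg[, 1]; local$mg_y <- mg[, 2]; local$mg_z <- mg[, 3]
  local$nb_x <- nb[, 1]; local$nb_y <- nb[, 2]; local$nb_z <- nb[, 3]
  local$nd_x <- nd[, 1]; local$nd_y <- nd[, 2]; local$nd_z <- nd[, 3]
  local
}
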