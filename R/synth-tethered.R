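#' Specify a tethered hydration site
#'
#' @param center Length-3 site centre, Angstrom.
#' @param translational_sigma Isotropic Gaussian spread of the water oxygen,
#'   Angstrom (> 0).
#' @param orientational_concentration Concentration parameter of the
#'   orientation distribution about the reference orientation; 0 means
#'   uniform orientations.
#' @param occupancy_prob Per-frame probability that the site holds a water.
#' @export
tethered_site <- function(center, translational_sigma = 0.3,
                          orientational_concentration = 0,
                          occupancy_prob = 1) {
  if (translational_sigma <= 0) abort("translational_sigma must be > 0")
  if (occupancy_prob < 0 || occupancy_prob > 1) {
    abort("occupancy_prob must lie in [0, 1]")
  }
  structure(list(center = as.numeric(center),
                 translational_sigma = translational_sigma,
                 orientational_concentration = orientational_concentration,
                 occupancy_prob = occupancy_prob),
            class = "tethered_site")
}

#' Generate tethered-water ensembles with known thermodynamics
#'
#' Places one water per site per frame (with the site's occupancy
#' probability): the oxygen is drawn from an isotropic Gaussian about the
#' site centre and the orientation either uniformly (concentration 0) or
#' from a concentrated rotation distribution about the reference frame with
#' density proportional to `exp(kappa * cos omega)` in the rotation angle
#' `omega`. Unoccupied frames park the water far from every site, so
#' occupancy can be measured downstream exactly as for real trajectories.
#'
#' Alongside the ensemble, the generator returns closed-form (translational)
#' and numerically integrated (orientational) first-order excess entropies,
#' expressed as `-T dS` in kcal/mol at `temperature`, for use as estimator
#' ground truth.
#'
#' @param sites List of [tethered_site()] objects; centres must be at least
#'   6 Angstrom apart.
#' @param n_frames Number of frames.
#' @param bulk_density Bulk water number density, per Angstrom^3.
#' @param temperature Temperature for the entropy scale, K.
#' @param seed Optional RNG seed.
#' @return List with `system`, `trajectory`, `truth` (a tibble with one row
#'   per site: occupancy_prob, analytic `minus_TdS_trans`,
#'   `minus_TdS_orient`), and `orientations` (list of per-site quaternion
#'   matrices with `NA` rows for unoccupied frames).
#' @export
gen_tethered_waters <- function(sites, n_frames, bulk_density = 0.0334,
                                temperature = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(sites, "tethered_site")) sites <- list(sites)
  centers <- do.call(rbind, lapply(sites, `[[`, "center"))
  if (length(sites) > 1) {
    dmin <- min(stats::dist(centers))
    if (dmin < 6) abort("overlapping sites: centres must be >= 6 A apart")
  }
  ns <- length(sites)
  geom <- water_geometry()
  kT <- KB_KCAL * temperature

  coords <- array(0, dim = c(3 * ns, 3, n_frames))
  orientations <- vector("list", ns)
  truth <- vector("list", ns)
  for (s in seq_len(ns)) {
    sp <- sites[[s]]
    occ <- runif(n_frames) < sp$occupancy_prob
    q <- matrix(NA_real_, n_frames, 4)
    nocc <- sum(occ)
    if (nocc > 0) {
      q[occ, ] <- sample_concentrated_quat(nocc,
                                           sp$orientational_concentration)
      opos <- matrix(rnorm(3 * nocc, sd = sp$translational_sigma),
                     ncol = 3, byrow = TRUE)
      opos <- sweep(opos, 2, sp$center, "+")
    }
    park <- c(1e4 + 100 * s, 1e4, 1e4)
    io <- 0
    for (f in seq_len(n_frames)) {
      rows <- (3 * s - 2):(3 * s)
      if (occ[f]) {
        io <- io + 1
        rot <- quat_to_matrix(q[f, ])
        w <- geom %*% t(rot)
        coords[rows, , f] <- sweep(w, 2, opos[io, ], "+")
      } else {
        coords[rows, , f] <- sweep(geom, 2, park, "+")
      }
    }
    orientations[[s]] <- q
    sg <- sp$translational_sigma
    mtds_tr <- kT * (-1.5 * log(2 * pi * sg^2) - 1.5 - log(bulk_density))
    mtds_or <- orientational_truth(sp$orientational_concentration, kT)
    truth[[s]] <- tibble(site = s,
                         cx = sp$center[1], cy = sp$center[2],
                         cz = sp$center[3],
                         sigma = sg,
                         kappa = sp$orientational_concentration,
                         occupancy_prob = sp$occupancy_prob,
                         minus_TdS_trans = mtds_tr,
                         minus_TdS_orient = mtds_or)
  }
  atoms <- tibble(
    name = rep(c("OH2", "H1", "H2"), ns),
    element = rep(c("O", "H", "H"), ns),
    resname = "TIP3",
    resid = rep(seq_len(ns), each = 3),
    chain = "W"
  )
  system <- new_system(atoms, coords = coords[, , 1])
  system <- assign_parameters(system, tip3p_parameters())
  system <- set_roles(system)
  traj <- new_trajectory(coords, frame_interval = 10,
                         source = "gen_tethered_waters")
  list(system = system, trajectory = traj,
       truth = dplyr::bind_rows(truth), orientations = orientations)
}

# Rotations about a uniform random axis with angle density
# p(omega) ~ (1 - cos omega) exp(kappa cos omega), omega in [0, pi];
# kappa = 0 reduces to the uniform (Haar) distribution on rotations.
sample_concentrated_quat <- function(n, kappa) {
  if (kappa == 0) return(rand_quaternion(n))
  out <- matrix(0, n, 4)
  got <- 0
  # rejection from the Haar angle density with envelope exp(kappa cos omega)
  while (got < n) {
    todo <- (n - got) * 2 + 10
    w <- sample_haar_angle(todo)
    u <- runif(todo)
    keep <- u < exp(kappa * (cos(w) - 1))
    w <- w[keep]
    take <- min(length(w), n - got)
    if (take > 0) {
      ww <- w[seq_len(take)]
      ax <- matrix(rnorm(3 * take), ncol = 3)
      ax <- ax / sqrt(rowSums(ax^2))
      out[got + seq_len(take), ] <- cbind(cos(ww / 2), sin(ww / 2) * ax)
      got <- got + take
    }
  }
  out
}

# Haar rotation-angle density (1 - cos omega)/pi via inverse-CDF bisection
sample_haar_angle <- function(n) {
  u <- runif(n)
  lo <- rep(0, n); hi <- rep(pi, n)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    cdf <- (mid - sin(mid)) / pi
    less <- cdf < u
    lo[less] <- mid[less]
    hi[!less] <- mid[!less]
  }
  (lo + hi) / 2
}

# Deterministic 2D quadrature of the orientational excess entropy of the
# concentrated distribution, folded by the water C2 symmetry:
#   -T dS = kT * E_p[ ln( (g(x) + g(x C2)) / 2 ) ]
# with g(x) = (pi / Z) exp(kappa cos omega(x)) relative to Haar.
orientational_truth <- function(kappa, kT, n_omega = 600, n_theta = 300) {
  if (kappa == 0) return(0)
  om <- seq(0, pi, length.out = n_omega)
  th <- seq(0, pi, length.out = n_theta)
  dom <- om[2] - om[1]; dth <- th[2] - th[1]
  z <- sum((1 - cos(om)) * exp(kappa * cos(om)) * dom)
  lgp <- log(pi) - log(z)
  # cos of the rotation angle of x * C2 given omega(x) and axis polar angle
  acc <- 0
  for (i in seq_along(om)) {
    w <- om[i]
    g1 <- exp(lgp + kappa * cos(w))
    cw2 <- 2 * sin(w / 2)^2 * cos(th)^2 - 1
    g2 <- exp(lgp + kappa * cw2)
    h <- log((g1 + g2) / 2)
    # weights: Haar angle density x axis area x sample density g1
    wgt <- (1 - cos(w)) / pi * (sin(th) / 2) * g1
    acc <- acc + sum(h * wgt) * dom * dth
  }
  kT * acc
}
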