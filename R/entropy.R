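#' Quasiharmonic conformational entropy
#'
#' Frames are superposed onto their mean structure by a mass-weighted rigid
#' fit (projecting out overall translation and rotation), the mass-weighted
#' covariance of the fluctuations is diagonalized, and each retained mode
#' contributes the quantum harmonic-oscillator entropy at the analysis
#' temperature, with mode frequencies `omega_i = sqrt(kB T / lambda_i)`.
#' The six smallest-eigenvalue modes (the residual rigid-body null space)
#' are discarded by rank.
#'
#' @param trajectory An `mm_trajectory`.
#' @param system Parameterized `mm_system` (masses).
#' @param selection Atom indices to analyse; default all heavy atoms with
#'   masses. Fewer than `3 * n_atoms` frames triggers a warning.
#' @param temperature Analysis temperature, K (default 298).
#' @return Object of class `quasiharmonic`: `frequencies` (cm^-1,
#'   increasing), `TS` (kcal/mol), `n_modes`, `temperature`.
#' @export
quasiharmonic_entropy <- function(trajectory, system, selection = NULL,
                                  temperature = 298) {
  a <- system$atoms
  selection <- selection %||% which(a$element != "H" & !is.na(a$mass))
  masses <- a$mass[selection]
  if (anyNA(masses)) abort("masses not assigned on the selection")
  nf <- n_frames(trajectory)
  n <- length(selection)
  if (nf < 3 * n) {
    warning(sprintf("only %d frames for %d atoms; >= 3N frames recommended",
                    nf, n))
  }
  arr <- trajectory$coords[selection, , , drop = FALSE]
  arr <- superpose_frames(arr, masses)
  # frames x 3N matrix, atom-major columns (x1,y1,z1,x2,...)
  x <- matrix(0, nf, 3 * n)
  for (f in seq_len(nf)) x[f, ] <- as.vector(t(arr[, , f]))
  mw <- rep(sqrt(masses), each = 3)
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, mw, "*")
  cv <- crossprod(x) / (nf - 1)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  keep <- head(ev, max(0, length(ev) - 6))
  null_like <- sum(keep <= 1e-10)
  if (null_like > 0) {
    warning(sprintf("rank-deficient covariance: %d near-null modes beyond the 6 expected",
                    null_like))
  }
  kbt_j <- KB_J * temperature
  lam_si <- keep * AMU_KG * 1e-20           # kg m^2
  omega <- ifelse(keep > 1e-10, sqrt(kbt_j / lam_si), Inf)
  nu_cm <- omega / (2 * pi * SPEED_OF_LIGHT_CM)
  xq <- PLANCK_HBAR * omega / kbt_j
  s_mode <- ifelse(is.finite(xq),
                   xq / (exp(xq) - 1) - log1p(-exp(-xq)), 0)
  ts <- temperature * KB_KCAL * sum(s_mode)
  structure(list(frequencies = sort(nu_cm[is.finite(nu_cm)]),
                 TS = ts, n_modes = length(keep),
                 temperature = temperature),
            class = "quasiharmonic")
}

#' @export
print.quasiharmonic <- function(x, ...) {
  cat(sprintf("<quasiharmonic> %d modes at %g K, TS = %.2f kcal/mol\n",
              x$n_modes, x$temperature, x$TS))
  invisible(x)
}

#' Translational excess entropy of a hydration site
#'
#' First-order translational term of the inhomogeneous-solvation expansion,
#' `S_tr = -kB < ln(rho_site / rho_bulk) >`, with the local density
#' estimated by a k-nearest-neighbour (Kozachenko-Leonenko) estimator.
#' Returned as `-T dS` in kcal/mol: positive for localized sites, near zero
#' for bulk-like distributions.
#'
#' @param positions `n x 3` matrix of site-assigned water-oxygen positions.
#' @param bulk_density Bulk number density, per Angstrom^3.
#' @param temperature K.
#' @param k Nearest-neighbour order (default 1).
#' @export
site_translational_entropy <- function(positions, bulk_density = 0.0334,
                                       temperature = 300, k = 1) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < k + 1) abort("need at least k + 1 samples")
  if (n < 50) warning("fewer than 50 samples; entropy estimate will be noisy")
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  rk <- apply(d, 1, function(r) sort(r, partial = k)[k])
  rk <- pmax(rk, 1e-12)
  # Kozachenko-Leonenko: <ln rho> ~ mean(psi(k) - psi(n) - ln V_ball)
  ln_rho <- digamma(k) - digamma(n) - log(4 / 3 * pi * rk^3)
  kT <- KB_KCAL * temperature
  kT * (mean(ln_rho) - log(bulk_density))
}

#' Orientational excess entropy of a hydration site
#'
#' First-order orientational term, `S_or = -kB < ln g_or >`, with the
#' orientation density estimated by a nearest-neighbour estimator on the
#' rotation manifold (geodesic rotation-angle metric) and normalized to the
#' uniform distribution reduced by the molecular symmetry number (2 for
#' water). Returned as `-T dS` (kcal/mol), non-negative within estimator
#' noise.
#'
#' When samples coincide (fully frozen orientations) the estimator
#' saturates: the geodesic radius is floored and a saturation warning is
#' emitted.
#'
#' @param quaternions `n x 4` matrix of unit quaternions.
#' @param water_symmetry Molecular symmetry number (2 for C2v water).
#' @param temperature K.
#' @param k Nearest-neighbour order.
#' @export
site_orientational_entropy <- function(quaternions, water_symmetry = 2,
                                       temperature = 300, k = 1) {
  q <- as.matrix(quaternions)
  n <- nrow(q)
  if (n < k + 1) abort("need at least k + 1 samples")
  if (n < 50) warning("fewer than 50 samples; entropy estimate will be noisy")
  norms <- sqrt(rowSums(q^2))
  if (any(abs(norms - 1) > 1e-6)) abort("quaternions must be unit-normalized")
  # geodesic distance folded by the C2 symmetry (rotation by pi about the
  # molecular z axis): d = 2 acos(max |q_i . q_j|, |q_i . (q_j * C2)|)
  dot1 <- abs(q %*% t(q))
  qc2 <- cbind(-q[, 4], q[, 3], -q[, 2], q[, 1]) # q * (0,0,0,1)
  dot2 <- abs(q %*% t(qc2))
  dmax <- pmin(pmax(dot1, dot2), 1)
  theta <- 2 * acos(dmax)
  diag(theta) <- Inf
  rk <- apply(theta, 1, function(r) sort(r, partial = k)[k])
  floor_r <- 1e-4
  saturated <- rk < floor_r
  if (any(saturated)) {
    warning(sprintf("orientational estimator saturated for %d samples (coincident orientations); value capped",
                    sum(saturated)))
    rk[saturated] <- floor_r
  }
  # Haar-measure fraction of a geodesic ball of radius r on rotations
  frac <- (rk - sin(rk)) / pi
  ln_g <- digamma(k) - digamma(n) - log(water_symmetry * frac)
  kT <- KB_KCAL * temperature
  kT * mean(ln_g)
}
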