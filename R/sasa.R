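#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA from the fraction of quasi-uniform (Fibonacci lattice)
#' points on each probe-inflated atomic sphere that no neighbouring sphere
#' buries, times the sphere area. Atoms with zero or missing SASA radius are
#' excluded with a warning.
#'
#' @param system Parameterized `mm_system` (uses `radius_sasa`).
#' @param frame Coordinate matrix.
#' @param atoms Atom indices (default: all non-water atoms).
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom.
#' @return List with `total` (Angstrom^2) and `per_atom` (named by atom
#'   index; excluded atoms get 0).
#' @export
sasa <- function(system, frame, atoms = NULL, probe = 1.4, n_points = 960) {
  a <- system$atoms
  atoms <- atoms %||% which(!a$is_water)
  rad <- a$radius_sasa[atoms]
  bad <- is.na(rad) | rad <= 0
  if (any(bad)) {
    warning(sprintf("%d atoms with zero/missing SASA radius excluded",
                    sum(bad)))
    atoms <- atoms[!bad]; rad <- rad[!bad]
  }
  co <- frame[atoms, , drop = FALSE]
  m <- length(atoms)
  pts <- fibonacci_sphere(n_points)
  per <- numeric(m)
  rext <- rad + probe
  for (i in seq_len(m)) {
    sphere <- sweep(pts * rext[i], 2, co[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(m)) {
      if (j == i) next
      dij <- sqrt(sum((co[i, ] - co[j, ])^2))
      if (dij >= rext[i] + rext[j]) next
      d2 <- (sphere[, 1] - co[j, 1])^2 + (sphere[, 2] - co[j, 2])^2 +
        (sphere[, 3] - co[j, 3])^2
      exposed <- exposed & d2 > rext[j]^2
    }
    per[i] <- sum(exposed) / n_points * 4 * pi * rext[i]^2
  }
  names(per) <- atoms
  list(total = sum(per), per_atom = per)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Nonpolar (surface-area) solvation term
#'
#' `dG_SA = 0.00542 * dSASA + 0.92` kcal/mol with the constant, or the pure
#' linear term without it (the per-residue mode).
#'
#' @param delta_sasa Change in SASA upon binding, Angstrom^2.
#' @param include_constant Include the 0.92 kcal/mol intercept.
#' @return kcal/mol.
#' @export
delta_g_sa <- function(delta_sasa, include_constant = TRUE) {
  0.00542 * delta_sasa + if (include_constant) 0.92 else 0
}
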