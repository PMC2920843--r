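#' Assign force-field parameters from tables
#'
#' Joins a parameter table onto the atom table by residue and atom name.
#' Rows with `resname = "*"` act as wildcards matched by atom name alone.
#' Two charge sets coexist on every atom: `mm_charge` feeds the
#' molecular-mechanics terms and `parse_charge` feeds the continuum
#' (Poisson-Boltzmann) terms. Assignment is idempotent.
#'
#' @param system An `mm_system`.
#' @param tables A tibble with columns `resname`, `name`, `mass`,
#'   `mm_charge`, `parse_charge`, `lj_epsilon`, `lj_rmin_half`, `radius_pb`,
#'   `radius_sasa`.
#' @param strict When `TRUE` (default) atoms missing from the table raise an
#'   error listing them as `residue:atom`; otherwise they keep `NA`
#'   parameters.
#' @return The system with parameters filled in.
#' @export
assign_parameters <- function(system, tables, strict = TRUE) {
  tables <- as_tibble(tables)
  a <- system$atoms
  param_cols <- c("mass", "mm_charge", "parse_charge", "lj_epsilon",
                  "lj_rmin_half", "radius_pb", "radius_sasa")
  key_sys <- paste(a$resname, a$name)
  key_tab <- paste(tables$resname, tables$name)
  hit <- match(key_sys, key_tab)
  wild <- match(a$name, tables$name[tables$resname == "*"])
  wild_rows <- which(tables$resname == "*")[wild]
  use_wild <- is.na(hit) & !is.na(wild_rows)
  hit[use_wild] <- wild_rows[use_wild]
  missing <- which(is.na(hit))
  if (length(missing) > 0 && strict) {
    abort(paste0("missing parameters for atoms: ",
                 paste(unique(paste0(a$resname[missing], ":",
                                     a$name[missing])), collapse = ", ")))
  }
  ok <- !is.na(hit)
  for (col in param_cols) {
    if (!is.null(tables[[col]])) a[[col]][ok] <- tables[[col]][hit[ok]]
  }
  system$atoms <- a
  system
}

#' TIP3P-style 3-site water parameters
#'
#' Rigid 3-site water with the CHARMM-flavoured TIP3P charges and
#' Lennard-Jones terms (hydrogens carry a small LJ well). Atom names cover
#' the common PDB/CHARMM dialects. PARSE-style continuum radii are attached
#' for the PB path; `parse_charge` mirrors the MM charges for water.
#'
#' @return A parameter tibble accepted by [assign_parameters()].
#' @export
tip3p_parameters <- function() {
  o_names <- c("OH2", "OW", "O")
  h_names <- c("H1", "H2", "HW1", "HW2")
  water_res <- c("TIP3", "HOH", "WAT", "SOL", "SPC")
  rows <- list()
  for (res in water_res) {
    for (nm in o_names) {
      rows[[length(rows) + 1]] <- tibble(
        resname = res, name = nm, mass = 15.9994,
        mm_charge = -0.834, parse_charge = -0.834,
        lj_epsilon = 0.1521, lj_rmin_half = 1.7682,
        radius_pb = 1.40, radius_sasa = 1.52)
    }
    for (nm in h_names) {
      rows[[length(rows) + 1]] <- tibble(
        resname = res, name = nm, mass = 1.008,
        mm_charge = 0.417, parse_charge = 0.417,
        lj_epsilon = 0.046, lj_rmin_half = 0.2245,
        radius_pb = 1.00, radius_sasa = 1.20)
    }
  }
  dplyr::bind_rows(rows)
}

#' Rigid TIP3P water geometry
#'
#' Returns O/H1/H2 coordinates (Angstrom) of one water in a canonical frame:
#' oxygen at the origin, the H-O-H bisector along +z, hydrogens in the xz
#' plane. O-H 0.9572 Angstrom, H-O-H 104.52 degrees.
#' @export
water_geometry <- function() {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(
    O  = c(0, 0, 0),
    H1 = c(r_oh * sin(half), 0, r_oh * cos(half)),
    H2 = c(-r_oh * sin(half), 0, r_oh * cos(half))
  )
}

#' Check per-molecule water neutrality
#'
#' @param system A parameterized `mm_system`.
#' @param tol Allowed absolute deviation from zero net charge (e).
#' @return `TRUE` invisibly; errors if any water molecule is non-neutral.
#' @export
check_water_neutrality <- function(system, tol = 1e-6) {
  a <- system$atoms
  w <- a[a$is_water, ]
  if (nrow(w) == 0) return(invisible(TRUE))
  sums <- tapply(w$mm_charge, paste(w$chain, w$resid, w$icode), sum)
  if (any(abs(sums) > tol)) {
    abort("water molecule with non-zero net MM charge found")
  }
  invisible(TRUE)
}
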