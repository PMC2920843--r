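MAINCHAIN_HEAVY <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
MAINCHAIN_H <- c("H", "HN", "HA", "HA1", "HA2", "HT1", "HT2", "HT3",
                 "1H", "2H", "3H", "HXT")

#' Select atoms by role, residue and backbone partition
#'
#' The mainchain of a residue comprises the peptide backbone heavy atoms
#' (`N`, `CA`, `C`, `O`), terminal capping atoms (`OXT`/`OT1`/`OT2`), and
#' hydrogens bonded to these (by the bond table when present, by naming
#' convention otherwise). The sidechain is the residue complement, so the two
#' parts partition every residue.
#'
#' @param system An `mm_system`.
#' @param role Optional role name (`"receptor"`, `"ligand"`, `"water"`) to
#'   restrict to; must exist in `system$selections`.
#' @param resid Optional residue numbers (within the role restriction if one
#'   is given).
#' @param resname Optional residue-name filter.
#' @param part `"all"`, `"mainchain"` or `"sidechain"`.
#' @param heavy_only Drop hydrogens from the result.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(system, role = NULL, resid = NULL, resname = NULL,
                         part = c("all", "mainchain", "sidechain"),
                         heavy_only = FALSE) {
  part <- match.arg(part)
  a <- system$atoms
  idx <- seq_len(nrow(a))
  if (!is.null(role)) {
    if (is.null(system$selections[[role]])) {
      abort(sprintf("role '%s' is not defined on this system", role))
    }
    idx <- intersect(idx, system$selections[[role]])
  }
  if (!is.null(resid)) {
    avail <- unique(a$resid[idx])
    bad <- setdiff(resid, avail)
    if (length(bad) > 0) {
      abort(sprintf("selection error: residue(s) %s do not exist in scope",
                    paste(bad, collapse = ", ")))
    }
    idx <- idx[a$resid[idx] %in% resid]
  }
  if (!is.null(resname)) idx <- idx[a$resname[idx] %in% resname]
  if (part != "all") {
    mc <- mainchain_mask(system)
    idx <- if (part == "mainchain") idx[mc[idx]] else idx[!mc[idx]]
  }
  if (heavy_only) idx <- idx[a$element[idx] != "H"]
  sort(idx)
}

mainchain_mask <- function(system) {
  a <- system$atoms
  mc <- a$name %in% MAINCHAIN_HEAVY & !a$is_water
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    b <- system$bonds
    is_h <- a$element == "H"
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1]; j <- b[r, 2]
      if (is_h[i] && mc[j]) mc[i] <- TRUE
      if (is_h[j] && mc[i]) mc[j] <- TRUE
    }
  } else {
    mc <- mc | (a$name %in% MAINCHAIN_H & !a$is_water)
  }
  mc
}
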