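#' Detect hydrogen bonds in one frame
#'
#' Donors are N/O atoms with at least one attached hydrogen (bond table when
#' present, otherwise any hydrogen within 1.2 Angstrom); acceptors are N/O
#' atoms. A bond requires donor-acceptor distance `<= d_max` and
#' donor-hydrogen-acceptor angle `>= angle_min`. In `heavy_only` mode (for
#' structures without hydrogens) the angle test is skipped and each polar
#' pair within `d_max` counts once; the returned tibble records the mode.
#' Pairs separated by 1 or 2 bonds are never counted.
#'
#' @param system An `mm_system`.
#' @param frame Coordinate matrix (default: the system coordinates).
#' @param d_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min D-H-A angle cutoff, degrees.
#' @param heavy_only Skip the angle test (no hydrogens required).
#' @return Tibble `donor`, `hydrogen`, `acceptor`, `distance`, `angle`
#'   sorted by (donor, acceptor); attribute `heavy_only` records the mode.
#' @export
detect_hbonds <- function(system, frame = system$coords, d_max = 3.5,
                          angle_min = 120, heavy_only = FALSE) {
  a <- system$atoms
  polar <- which(a$element %in% c("N", "O"))
  empty <- tibble(donor = integer(), hydrogen = integer(),
                  acceptor = integer(), distance = numeric(),
                  angle = numeric())
  if (length(polar) < 2) return(structure(empty, heavy_only = heavy_only))
  hyd <- attached_hydrogens(system, frame)
  excl <- bonded_within2(system)
  rows <- list()
  if (heavy_only) {
    for (ii in seq_along(polar)) {
      for (jj in seq_along(polar)) {
        if (jj <= ii) next
        i <- polar[ii]; j <- polar[jj]
        if (paste(i, j) %in% excl) next
        d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
        if (d <= d_max) {
          rows[[length(rows) + 1]] <- tibble(donor = i,
                                             hydrogen = NA_integer_,
                                             acceptor = j, distance = d,
                                             angle = NA_real_)
        }
      }
    }
  } else {
    for (i in polar) {
      hs <- hyd[[i]]
      if (length(hs) == 0) next
      for (j in polar) {
        if (j == i) next
        if (paste(min(i, j), max(i, j)) %in% excl) next
        d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
        if (d > d_max) next
        for (h in hs) {
          v1 <- frame[i, ] - frame[h, ]
          v2 <- frame[j, ] - frame[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          if (ang >= angle_min) {
            rows[[length(rows) + 1]] <- tibble(donor = i, hydrogen = h,
                                               acceptor = j, distance = d,
                                               angle = ang)
            break
          }
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty
  out <- out[order(out$donor, out$acceptor), ]
  structure(out, heavy_only = heavy_only)
}

attached_hydrogens <- function(system, frame) {
  a <- system$atoms
  out <- vector("list", nrow(a))
  hs <- which(a$element == "H")
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    for (r in seq_len(nrow(system$bonds))) {
      i <- system$bonds[r, 1]; j <- system$bonds[r, 2]
      if (a$element[i] == "H" && a$element[j] %in% c("N", "O")) {
        out[[j]] <- c(out[[j]], i)
      }
      if (a$element[j] == "H" && a$element[i] %in% c("N", "O")) {
        out[[i]] <- c(out[[i]], j)
      }
    }
  } else if (length(hs) > 0) {
    heavies <- which(a$element %in% c("N", "O"))
    for (i in heavies) {
      d2 <- rowSums(sweep(frame[hs, , drop = FALSE], 2, frame[i, ])^2)
      out[[i]] <- hs[d2 <= 1.2^2]
    }
  }
  out
}

bonded_within2 <- function(system) {
  if (is.null(system$bonds) || nrow(system$bonds) == 0) return(character())
  b <- system$bonds
  adj <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
  keys <- c(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  for (i in names(adj)) {
    nb <- adj[[i]]
    if (length(nb) > 1) {
      pr <- t(utils::combn(sort(nb), 2))
      keys <- c(keys, paste(pr[, 1], pr[, 2]))
    }
  }
  unique(keys)
}

count_water_hbonds <- function(system, frame, watoms, d_max = 3.5,
                               angle_min = 120) {
  hb <- detect_hbonds(system, frame, d_max, angle_min)
  sum(hb$donor %in% watoms | hb$acceptor %in% watoms)
}

#' Direct versus water-bridged hydrogen-bond census at an interface
#'
#' `direct` counts hydrogen bonds with one partner atom in the receptor and
#' one in the ligand. `bridged` counts waters hydrogen-bonded simultaneously
#' to at least one receptor atom and at least one ligand atom; each such
#' water counts once regardless of how many partners it has on either side.
#' The total interaction count is `direct + bridged`.
#'
#' @param system An `mm_system` with roles (or explicit selections below).
#' @param frame Coordinate matrix (default: system coordinates).
#' @param receptor,ligand,waters Atom index vectors; default to the role
#'   selections.
#' @param d_max,angle_min,heavy_only Criteria passed to [detect_hbonds()].
#' @return List with `direct`, `bridged` and `total`.
#' @export
interface_hbond_census <- function(system, frame = system$coords,
                                   receptor = NULL, ligand = NULL,
                                   waters = NULL, d_max = 3.5,
                                   angle_min = 120, heavy_only = FALSE) {
  receptor <- receptor %||% system$selections$receptor
  ligand <- ligand %||% system$selections$ligand
  waters <- waters %||% system$selections$water %||%
    which(system$atoms$is_water)
  hb <- detect_hbonds(system, frame, d_max, angle_min, heavy_only)
  in_r <- function(x) x %in% receptor
  in_l <- function(x) x %in% ligand
  direct <- sum((in_r(hb$donor) & in_l(hb$acceptor)) |
                  (in_l(hb$donor) & in_r(hb$acceptor)))
  a <- system$atoms
  wkeys <- unique(residue_key(a)[waters])
  bridged <- 0L
  for (wk in wkeys) {
    watoms <- intersect(waters, which(residue_key(a) == wk))
    partners <- c(hb$acceptor[hb$donor %in% watoms],
                  hb$donor[hb$acceptor %in% watoms])
    if (any(in_r(partners)) && any(in_l(partners))) bridged <- bridged + 1L
  }
  list(direct = as.integer(direct), bridged = bridged,
       total = as.integer(direct) + bridged)
}

#' Root mean square fluctuation per atom
#'
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` over frames. Optional mass-weighted
#' superposition onto the mean structure first (water RMSF is conventionally
#' computed without superposition). An optional rolling `window` (frames)
#' returns a time series of the mean RMSF per window.
#'
#' @param trajectory An `mm_trajectory` with at least 2 frames.
#' @param selection Atom indices (default all).
#' @param superpose Mass-weighted rigid superposition before the
#'   fluctuation analysis.
#' @param system Required when `superpose = TRUE` (masses).
#' @param window Optional window length in frames for the time series.
#' @return List with `rmsf` (per-atom, Angstrom) and, when `window` is
#'   given, `series` (tibble `window_start`, `mean_rmsf`).
#' @export
rmsf <- function(trajectory, selection = NULL, superpose = FALSE,
                 system = NULL, window = NULL) {
  if (n_frames(trajectory) < 2) abort("RMSF needs at least 2 frames")
  selection <- selection %||% seq_len(dim(trajectory$coords)[1])
  arr <- trajectory$coords[selection, , , drop = FALSE]
  if (superpose) {
    if (is.null(system)) abort("superposition needs the system (masses)")
    w <- system$atoms$mass[selection]
    if (anyNA(w)) w <- rep(1, length(selection))
    arr <- superpose_frames(arr, w)
  }
  per_atom_rmsf <- function(a) {
    mu <- apply(a, c(1, 2), mean)
    sqrt(apply((a - array(mu, dim = dim(a)))^2, 1, sum) / dim(a)[3])
  }
  out <- list(rmsf = per_atom_rmsf(arr))
  if (!is.null(window)) {
    starts <- seq(1, dim(arr)[3] - window + 1, by = window)
    out$series <- tibble(
      window_start = starts,
      mean_rmsf = vapply(starts, function(s) {
        mean(per_atom_rmsf(arr[, , s:(s + window - 1), drop = FALSE]))
      }, numeric(1)))
  }
  out
}
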