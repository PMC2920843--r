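#' Block standard error of the mean
#'
#' Splits the series into `n_blocks` equal contiguous blocks (the remainder
#' is truncated) and returns `sd(block means) / sqrt(n_blocks)`.
#'
#' @param x Per-snapshot numeric series.
#' @param n_blocks Number of blocks (default 20; must be at least 2 and no
#'   longer than the series).
#' @export
block_sem <- function(x, n_blocks = 20) {
  if (n_blocks < 2) abort("n_blocks must be at least 2")
  if (length(x) < n_blocks) {
    abort(sprintf("series of length %d is shorter than %d blocks",
                  length(x), n_blocks))
  }
  bs <- floor(length(x) / n_blocks)
  m <- matrix(x[seq_len(bs * n_blocks)], nrow = bs)
  stats::sd(colMeans(m)) / sqrt(n_blocks)
}

stride_frames <- function(trajectory, stride) {
  if (is.null(stride)) return(seq_len(n_frames(trajectory)))
  duration <- n_frames(trajectory) * trajectory$frame_interval
  if (stride > duration) abort("stride exceeds the trajectory duration")
  step <- stride / trajectory$frame_interval
  if (abs(step - round(step)) > 1e-9) {
    abort("stride must be a multiple of the frame interval")
  }
  seq(round(step), n_frames(trajectory), by = round(step))
}

#' MM-PBSA binding free-energy pipeline
#'
#' Assembles the binding enthalpy over trajectory snapshots:
#' receptor-ligand van der Waals and electrostatic interaction energies, the
#' ligand deformation penalty (bound-minus-unbound intra-ligand internal
#' energy; the receptor internal energy is never differenced), and
#' optionally the PB desolvation and SASA nonpolar terms. Waters are
#' stripped before every term. Standard errors come from the 20-block rule.
#'
#' @param system Parameterized `mm_system` with receptor/ligand roles.
#' @param complex_traj Bound-state trajectory.
#' @param unbound_traj Unbound-ligand trajectory (same atom order).
#' @param receptor,ligand Atom selections (default roles).
#' @param stride Snapshot stride in ps (default: every frame). The snapshot
#'   count is `floor(duration / stride)`.
#' @param dielectric Solute-solute dielectric (default 2).
#' @param scale14 1-4 scale factor for internal energies.
#' @param pb `FALSE`, or a list of [pb_solvation()] arguments to enable the
#'   desolvation term.
#' @param sasa_term Include the surface-area term.
#' @param probe SASA probe radius.
#' @param n_blocks Blocks for standard errors.
#' @return An object of class `mmpbsa_result`: list with `per_frame`
#'   (tibble), `internal_bound`, `internal_unbound`, `deformation`, and
#'   `table` (term/value/sem tibble containing dH).
#' @export
run_mmpbsa <- function(system, complex_traj, unbound_traj, receptor = NULL,
                       ligand = NULL, stride = NULL, dielectric = 2,
                       scale14 = 1, pb = FALSE, sasa_term = TRUE,
                       probe = 1.4, n_blocks = 20) {
  receptor <- receptor %||% system$selections$receptor
  ligand <- ligand %||% system$selections$ligand
  w <- which(system$atoms$is_water)
  receptor <- setdiff(receptor, w)
  ligand <- setdiff(ligand, w)
  fb <- stride_frames(complex_traj, stride)
  fu <- stride_frames(unbound_traj, stride)
  sub_b <- new_trajectory(complex_traj$coords[, , fb, drop = FALSE],
                          complex_traj$frame_interval, source = "stride")
  sub_u <- new_trajectory(unbound_traj$coords[, , fu, drop = FALSE],
                          unbound_traj$frame_interval, source = "stride")
  inter <- interaction_energy(system, sub_b, receptor, ligand, dielectric)
  int_b <- internal_energy(system, sub_b, ligand, dielectric, scale14)
  int_u <- internal_energy(system, sub_u, ligand, dielectric, scale14)
  nb <- min(n_blocks, length(fb), length(fu))
  defo <- deformation_penalty(int_b, int_u,
                              n_blocks = max(2, nb))
  per_frame <- inter
  rows <- list(
    tibble(term = "vdw", value = mean(inter$vdw),
           sem = safe_sem(inter$vdw, n_blocks)),
    tibble(term = "elec", value = mean(inter$elec),
           sem = safe_sem(inter$elec, n_blocks))
  )
  if (!isFALSE(pb)) {
    pb_args <- if (isTRUE(pb)) list() else pb
    dpb <- do.call(delta_g_pb, c(list(system = system, trajectory = sub_b,
                                      receptor = receptor, ligand = ligand),
                                 pb_args))
    per_frame$dg_pb <- dpb$delta
    rows[[length(rows) + 1]] <- tibble(term = "desolvation",
                                       value = mean(dpb$delta),
                                       sem = safe_sem(dpb$delta, n_blocks))
  }
  if (sasa_term) {
    dsa <- numeric(length(fb))
    for (k in seq_along(fb)) {
      co <- frame_coords(sub_b, k)
      s_c <- sasa(system, co, c(receptor, ligand), probe = probe)$total
      s_r <- sasa(system, co, receptor, probe = probe)$total
      s_l <- sasa(system, co, ligand, probe = probe)$total
      dsa[k] <- s_c - s_r - s_l
    }
    dgsa <- delta_g_sa(dsa, include_constant = TRUE)
    per_frame$dg_sa <- dgsa
    rows[[length(rows) + 1]] <- tibble(term = "sasa", value = mean(dgsa),
                                       sem = safe_sem(dgsa, n_blocks))
  }
  rows[[length(rows) + 1]] <- tibble(term = "deformation",
                                     value = defo$value, sem = defo$sem)
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::bind_rows(tab, tibble(term = "dH", value = sum(tab$value),
                                      sem = sqrt(sum(tab$sem^2,
                                                     na.rm = TRUE))))
  structure(list(per_frame = per_frame, internal_bound = int_b,
                 internal_unbound = int_u, deformation = defo,
                 table = tab, n_snapshots = length(fb)),
            class = "mmpbsa_result")
}

safe_sem <- function(x, n_blocks) {
  if (length(x) >= n_blocks) block_sem(x, n_blocks) else NA_real_
}

#' @export
print.mmpbsa_result <- function(x, ...) {
  cat(sprintf("<mmpbsa_result> %d snapshots\n", x$n_snapshots))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Single-point (static) MM-PBSA
#'
#' The same terms as [run_mmpbsa()] evaluated on one pre-minimized frame
#' pair: deformation is the internal energy of the bound frame minus the
#' relaxed frame.
#'
#' @param system Parameterized `mm_system`.
#' @param complex_frame Coordinate matrix of the (minimized) complex.
#' @param relaxed_frame Coordinate matrix with the ligand relaxed.
#' @param ... Passed to [run_mmpbsa()].
#' @return An `mmpbsa_result` (no standard errors).
#' @export
static_mmpbsa <- function(system, complex_frame, relaxed_frame, ...) {
  tb <- new_trajectory(array(complex_frame,
                             dim = c(nrow(complex_frame), 3, 1)),
                       frame_interval = 1, source = "static")
  tu <- new_trajectory(array(relaxed_frame,
                             dim = c(nrow(relaxed_frame), 3, 1)),
                       frame_interval = 1, source = "static")
  run_mmpbsa(system, tb, tu, ...)
}

#' Assemble the binding free energy from its components
#'
#' `dG = dH + (-T dS)`, with `dH` either supplied directly or summed from
#' the five enthalpy components (vdw, elec, deformation, desolvation,
#' sasa). Missing components raise an error listing them. When `reference`
#' (another assembled table) is given, `ddG`-style differences are computed
#' from the unrounded values.
#'
#' @param components Named numeric vector/list: either the five enthalpy
#'   terms, or a single `dH`.
#' @param minus_T_delta_S Conformational entropy term `-T dS`, kcal/mol.
#' @param reference Optional `binding_free_energy` table to difference
#'   against.
#' @return A `binding_free_energy` tibble of `term`, `value` rows.
#' @export
assemble_binding_free_energy <- function(components, minus_T_delta_S,
                                         reference = NULL) {
  comp <- as.list(components)
  if (!is.null(comp$dH)) {
    dh <- unname(comp$dH)
    rows <- tibble(term = "dH", value = dh)
  } else {
    need <- c("vdw", "elec", "deformation", "desolvation", "sasa")
    missing <- setdiff(need, names(comp))
    if (length(missing) > 0) {
      abort(paste0("missing components: ", paste(missing, collapse = ", ")))
    }
    vals <- unname(unlist(comp[need]))
    dh <- sum(vals)
    rows <- dplyr::bind_rows(tibble(term = need, value = vals),
                             tibble(term = "dH", value = dh))
  }
  dg <- dh + minus_T_delta_S
  out <- dplyr::bind_rows(rows,
                          tibble(term = "minus_TdS",
                                 value = minus_T_delta_S),
                          tibble(term = "dG", value = dg))
  if (!is.null(reference)) {
    ref <- setNames(reference$value, reference$term)
    out$delta_vs_reference <- unname(out$value - ref[out$term])
  }
  class(out) <- c("binding_free_energy", class(out))
  out
}

#' Per-residue contribution table from component columns
#'
#' Pure arithmetic on per-residue enthalpy components: `total` is the row
#' sum of the component columns and `percent` is each row's share of the
#' grand total. Used both by the trajectory decomposition and to aggregate
#' externally supplied per-residue tables.
#'
#' @param df Tibble with a `residue` column and numeric component columns
#'   (any of vdw, elec, deformation, desolvation, sasa).
#' @return The table with `total` and `percent` columns appended.
#' @export
residue_contribution_table <- function(df) {
  comp <- intersect(c("vdw", "elec", "deformation", "desolvation", "sasa"),
                    names(df))
  df$total <- rowSums(as.matrix(df[, comp, drop = FALSE]))
  df$percent <- df$total / sum(df$total) * 100
  class(df) <- c("residue_contribution", class(df))
  df
}

#' Per-residue decomposition of the MM-PBSA binding enthalpy
#'
#' Attributes every term to ligand sidechain groups plus one pooled
#' mainchain group. Interaction terms are attributed by the ligand atom's
#' group. Intra-ligand (deformation) pair energies crossing two groups are
#' split half-and-half between the partners; torsions follow their central
#' bond. Per-group PB desolvation deletes all other ligand atoms (so the
#' sum over groups need not equal the whole-ligand PB term); the per-residue
#' SASA term omits the 0.92 constant.
#'
#' @inheritParams run_mmpbsa
#' @return A `residue_contribution` tibble (one row per sidechain group plus
#'   a pooled `mainchain` row) with component columns, block-SEM columns for
#'   the interaction terms, `total` and `percent`.
#' @export
per_residue_decomposition <- function(system, complex_traj, unbound_traj,
                                      receptor = NULL, ligand = NULL,
                                      stride = NULL, dielectric = 2,
                                      scale14 = 1, pb = FALSE,
                                      sasa_term = TRUE, probe = 1.4,
                                      n_blocks = 20) {
  receptor <- receptor %||% system$selections$receptor
  ligand <- ligand %||% system$selections$ligand
  a <- system$atoms
  if (length(setdiff(ligand, which(!a$is_water))) > 0) {
    abort("ligand selection contains water atoms")
  }
  mc <- mainchain_mask(system)
  resids <- sort(unique(a$resid[ligand]))
  groups <- setNames(rep(NA_integer_, n_atoms(system)), NULL)
  labels <- c(sprintf("%s %d", a$resname[match(resids, a$resid)], resids),
              "mainchain")
  ng <- length(resids) + 1L
  for (r in seq_along(resids)) {
    idx <- ligand[a$resid[ligand] == resids[r] & !mc[ligand]]
    groups[idx] <- r
  }
  groups[ligand[mc[ligand]]] <- ng
  if (anyNA(groups[ligand])) abort("residue partition does not cover ligand")

  fb <- stride_frames(complex_traj, stride)
  fu <- stride_frames(unbound_traj, stride)
  nf <- length(fb)
  inter_v <- inter_e <- matrix(0, nf, ng)
  intra_b <- intra_u <- matrix(0, max(nf, length(fu)), ng)
  pl <- nonbonded_pairlist(system, ligand, scale14)
  for (k in seq_len(nf)) {
    co <- frame_coords(complex_traj, fb[k])
    res <- cpp_group_energy(co, as.integer(receptor), as.integer(ligand),
                            a$mm_charge, a$lj_epsilon, a$lj_rmin_half,
                            dielectric, NULL,
                            rep(1L, length(receptor)),
                            as.integer(groups[ligand]), 1L, ng)
    inter_v[k, ] <- res$vdw_by_group[1, ]
    inter_e[k, ] <- res$elec_by_group[1, ]
    intra_b[k, ] <- intra_group_energy(system, co, ligand, groups, pl,
                                       dielectric)
  }
  for (k in seq_along(fu)) {
    co <- frame_coords(unbound_traj, fu[k])
    intra_u[k, ] <- intra_group_energy(system, co, ligand, groups, pl,
                                       dielectric)
  }
  intra_b <- intra_b[seq_len(nf), , drop = FALSE]
  intra_u <- intra_u[seq_along(fu), , drop = FALSE]

  out <- tibble(residue = labels,
                vdw = colMeans(inter_v),
                vdw_sem = apply(inter_v, 2, safe_sem, n_blocks),
                elec = colMeans(inter_e),
                elec_sem = apply(inter_e, 2, safe_sem, n_blocks),
                deformation = colMeans(intra_b) - colMeans(intra_u))

  if (!isFALSE(pb)) {
    pb_args <- if (isTRUE(pb)) list() else pb
    dpb <- numeric(ng)
    co <- frame_coords(complex_traj, fb[1])
    both <- c(receptor, ligand)
    rad <- a$radius_pb[both]
    lo <- apply(co[both, , drop = FALSE] - rad, 2, min)
    hi <- apply(co[both, , drop = FALSE] + rad, 2, max)
    center <- (lo + hi) / 2; extent <- max(hi - lo)
    pbv <- matrix(0, nf, ng)
    for (k in seq_len(nf)) {
      cok <- frame_coords(complex_traj, fb[k])
      g_rec <- do.call(pb_solvation,
                       c(list(system = system, frame = cok, atoms = receptor,
                              center = center, extent = extent), pb_args))$energy
      for (g in seq_len(ng)) {
        gi <- ligand[groups[ligand] == g]
        g_cplx <- do.call(pb_solvation,
                          c(list(system = system, frame = cok,
                                 atoms = c(receptor, gi), center = center,
                                 extent = extent), pb_args))$energy
        g_lig <- do.call(pb_solvation,
                         c(list(system = system, frame = cok, atoms = gi,
                                center = center, extent = extent),
                           pb_args))$energy
        pbv[k, g] <- g_cplx - g_rec - g_lig
      }
    }
    out$desolvation <- colMeans(pbv)
  }
  if (sasa_term) {
    dsa <- matrix(0, nf, ng)
    for (k in seq_len(nf)) {
      co <- frame_coords(complex_traj, fb[k])
      s_c <- sasa(system, co, c(receptor, ligand), probe = probe)$per_atom
      s_l <- sasa(system, co, ligand, probe = probe)$per_atom
      for (g in seq_len(ng)) {
        gi <- as.character(ligand[groups[ligand] == g])
        dsa[k, g] <- sum(s_c[gi]) - sum(s_l[gi])
      }
    }
    out$sasa <- delta_g_sa(colMeans(dsa), include_constant = FALSE)
  }
  residue_contribution_table(out)
}

# Intra-ligand nonbonded + torsion energy attributed to groups, with
# cross-group pairs halved between the two partners.
intra_group_energy <- function(system, frame, ligand, groups, pl,
                               dielectric) {
  a <- system$atoms
  ng <- max(groups, na.rm = TRUE)
  e <- numeric(ng)
  kq <- COULOMB_K / dielectric
  for (p in seq_along(pl$i)) {
    s <- pl$scale[p]
    if (s == 0) next
    i <- pl$i[p]; j <- pl$j[p]
    d <- frame[j, ] - frame[i, ]
    r2 <- sum(d * d)
    r <- sqrt(r2)
    ee <- s * kq * a$mm_charge[i] * a$mm_charge[j] / r
    epsij <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    vv <- 0
    if (epsij > 0) {
      s2 <- (a$lj_rmin_half[i] + a$lj_rmin_half[j])^2 / r2
      s6 <- s2^3
      vv <- s * epsij * (s6 * s6 - 2 * s6)
    }
    gi <- groups[i]; gj <- groups[j]
    if (gi == gj) e[gi] <- e[gi] + ee + vv else {
      e[gi] <- e[gi] + (ee + vv) / 2
      e[gj] <- e[gj] + (ee + vv) / 2
    }
  }
  d <- system$dihedrals
  if (!is.null(d) && nrow(d) > 0) {
    inside <- d$i %in% ligand & d$j %in% ligand & d$k %in% ligand &
      d$l %in% ligand
    d <- d[inside, , drop = FALSE]
    for (r in seq_len(nrow(d))) {
      phi <- dihedral_angle(frame, d$i[r], d$j[r], d$k[r], d$l[r])
      et <- d$k_dih[r] * (1 + cos(d$n[r] * phi - d$delta[r] * pi / 180))
      gj <- groups[d$j[r]]; gk <- groups[d$k[r]]
      if (gj == gk) e[gj] <- e[gj] + et else {
        e[gj] <- e[gj] + et / 2; e[gk] <- e[gk] + et / 2
      }
    }
  }
  e
}
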