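#' Cluster water-oxygen density into hydration sites
#'
#' Greedy density clustering of pooled water-oxygen positions: the sample
#' with the most neighbours within `site_radius` becomes a site centre, all
#' samples within `exclusion_radius` of it are removed, and the procedure
#' repeats until the best remaining count drops below
#' `min_occupancy * n_frames`. Ties are broken by lexicographically smallest
#' position, so the result is invariant to the input order of the samples.
#'
#' @param positions `n x 3` matrix of water-oxygen positions pooled over
#'   frames (e.g. restricted to a binding-site region).
#' @param n_frames Number of frames the samples came from (sets the
#'   occupancy threshold). Fewer than 100 triggers a warning.
#' @param site_radius Neighbour radius defining site density, Angstrom.
#' @param exclusion_radius Minimum distance between site centres, Angstrom.
#' @param min_occupancy Minimum site occupancy (fraction of frames).
#' @return Tibble with `site`, `x`, `y`, `z`, `n_samples` (neighbour count
#'   at selection); zero rows when no region is dense enough.
#' @export
cluster_hydration_sites <- function(positions, n_frames, site_radius = 1.0,
                                    exclusion_radius = 2.4,
                                    min_occupancy = 0.25) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) {
    return(tibble(site = integer(), x = numeric(), y = numeric(),
                  z = numeric(), n_samples = integer()))
  }
  if (n_frames < 100) warning("fewer than 100 frames; occupancies are noisy")
  threshold <- min_occupancy * n_frames
  active <- rep(TRUE, nrow(positions))
  out <- list()
  repeat {
    idx <- which(active)
    if (length(idx) == 0) break
    p <- positions[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(p))^2
    counts <- rowSums(d2 <= site_radius^2)  # includes self
    best <- max(counts)
    if (best < threshold) break
    cand <- which(counts == best)
    if (length(cand) > 1) {
      ord <- order(p[cand, 1], p[cand, 2], p[cand, 3])
      cand <- cand[ord[1]]
    }
    center <- p[cand, ]
    out[[length(out) + 1]] <- tibble(x = center[1], y = center[2],
                                     z = center[3],
                                     n_samples = as.integer(best))
    drop <- sqrt(rowSums(sweep(positions[idx, , drop = FALSE], 2,
                               center)^2)) <= exclusion_radius
    active[idx[drop]] <- FALSE
  }
  if (length(out) == 0) {
    return(tibble(site = integer(), x = numeric(), y = numeric(),
                  z = numeric(), n_samples = integer()))
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(site = dplyr::row_number(), .before = 1)
}

water_oxygen_indices <- function(system) {
  which(system$atoms$is_water & system$atoms$element == "O")
}

# For one frame, the indices (into the oxygen list) of oxygens within
# `radius` of `center`, nearest first.
site_occupants <- function(ox_coords, center, radius) {
  d2 <- rowSums(sweep(ox_coords, 2, center)^2)
  ord <- order(d2)
  ord[d2[ord] <= radius^2]
}

#' Thermodynamic characterization of one hydration site
#'
#' For every frame with at least one water oxygen inside the site sphere
#' (the nearest is taken when several qualify): the water's interaction
#' energy with the rest of the system gives the enthalpy relative to
#' `bulk_ref`; hydrogen bonds of the occupying water are counted; and the
#' occupying positions/orientations feed the first-order translational and
#' orientational entropy estimators. `dG = dH + (-T dS)` exactly, and the
#' occupancy-weighted columns are `occupancy` times the raw ones.
#'
#' @param center Length-3 site centre, Angstrom.
#' @param trajectory An `mm_trajectory`.
#' @param system Parameterized `mm_system` (waters flagged).
#' @param bulk_ref Bulk-water reference enthalpy, kcal/mol (see
#'   [bulk_reference()]).
#' @param site_radius Site sphere radius, Angstrom.
#' @param bulk_density Bulk number density for the translational term.
#' @param temperature K.
#' @param d_max,angle_min Hydrogen-bond criteria.
#' @param k Nearest-neighbour order for the entropy estimators.
#' @param dielectric Dielectric for the water environment energy.
#' @return One-row tibble: centre, radius, `occupancy`, `mean_hbonds`,
#'   `dH`, `mTdS`, `dG`, and `weighted_*` columns.
#' @export
characterize_site <- function(center, trajectory, system, bulk_ref,
                              site_radius = 1.0, bulk_density = 0.0334,
                              temperature = 300, d_max = 3.5,
                              angle_min = 120, k = 1, dielectric = 1) {
  ox <- water_oxygen_indices(system)
  if (length(ox) == 0) abort("system contains no water oxygens")
  nf <- n_frames(trajectory)
  energies <- hb <- numeric(0)
  opos <- matrix(0, 0, 3)
  quats <- matrix(0, 0, 4)
  occ_frames <- 0L
  for (f in seq_len(nf)) {
    co <- frame_coords(trajectory, f)
    hits <- site_occupants(co[ox, , drop = FALSE], center, site_radius)
    if (length(hits) == 0) next
    occ_frames <- occ_frames + 1L
    oi <- ox[hits[1]]
    watoms <- which(system$atoms$is_water &
                      system$atoms$resid == system$atoms$resid[oi] &
                      system$atoms$chain == system$atoms$chain[oi])
    energies <- c(energies,
                  water_environment_energy(system, co, watoms,
                                           dielectric = dielectric,
                                           box = frame_box(trajectory, f) %||%
                                             system$box))
    hb <- c(hb, count_water_hbonds(system, co, watoms, d_max, angle_min))
    opos <- rbind(opos, co[oi, ])
    hyd <- setdiff(watoms, oi)
    quats <- rbind(quats, water_orientation(co[oi, ], co[hyd[1], ],
                                            co[hyd[2], ]))
  }
  if (occ_frames == 0) {
    abort("zero occupancy: site thermodynamics are undefined")
  }
  occupancy <- occ_frames / nf
  dh <- mean(energies) - bulk_ref
  mtds_tr <- site_translational_entropy(opos, bulk_density, temperature, k)
  mtds_or <- site_orientational_entropy(quats, 2, temperature, k)
  mtds <- mtds_tr + mtds_or
  tibble(x = center[1], y = center[2], z = center[3],
         radius = site_radius, occupancy = occupancy,
         mean_hbonds = mean(hb), dH = dh,
         mTdS = mtds, mTdS_trans = mtds_tr, mTdS_orient = mtds_or,
         dG = dh + mtds,
         weighted_dH = occupancy * dh,
         weighted_mTdS = occupancy * mtds,
         weighted_dG = occupancy * (dh + mtds))
}

#' Enthalpy of waters visiting a fixed probe site
#'
#' Every water whose oxygen lies within `probe_radius` of the probe point
#' contributes its full environment interaction energy; the occupancy is the
#' fraction of frames with at least one such water, and the enthalpy is
#' reported relative to `bulk_ref` with a 20-block standard error over the
#' occupied-frame means.
#'
#' @param point Length-3 probe position, Angstrom. May also be given as a
#'   function(frame_coords) returning the point, for per-frame placements
#'   such as "3 Angstrom along an amide N-H vector".
#' @param trajectory,system,bulk_ref As in [characterize_site()].
#' @param probe_radius Probe sphere radius, Angstrom (default 1.4).
#' @param dielectric Dielectric for the environment energy.
#' @param n_blocks Blocks for the standard error.
#' @return List with `occupancy`, `enthalpy` (vs bulk; `NA` when never
#'   occupied), `sem`, `n_frames_occupied`.
#' @export
probe_site_analysis <- function(point, trajectory, system, bulk_ref,
                                probe_radius = 1.4, dielectric = 1,
                                n_blocks = 20) {
  ox <- water_oxygen_indices(system)
  nf <- n_frames(trajectory)
  frame_mean <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(trajectory, f)
    pt <- if (is.function(point)) point(co) else point
    hits <- site_occupants(co[ox, , drop = FALSE], pt, probe_radius)
    if (length(hits) == 0) next
    es <- vapply(hits, function(h) {
      oi <- ox[h]
      watoms <- which(system$atoms$is_water &
                        system$atoms$resid == system$atoms$resid[oi] &
                        system$atoms$chain == system$atoms$chain[oi])
      water_environment_energy(system, co, watoms, dielectric = dielectric,
                               box = frame_box(trajectory, f) %||% system$box)
    }, numeric(1))
    frame_mean[f] <- mean(es)
  }
  occupied <- !is.na(frame_mean)
  occupancy <- mean(occupied)
  if (!any(occupied)) {
    return(list(occupancy = 0, enthalpy = NA_real_, sem = NA_real_,
                n_frames_occupied = 0L))
  }
  vals <- frame_mean[occupied]
  list(occupancy = occupancy,
       enthalpy = mean(vals) - bulk_ref,
       sem = safe_sem(vals, n_blocks),
       n_frames_occupied = sum(occupied))
}

#' Bulk-water reference enthalpy
#'
#' Mean interaction energy of a bulk water molecule with its full
#' environment, averaged over waters and snapshots, with a 20-block
#' standard error over snapshot means. An inner-region rule restricts to
#' waters within `inner_radius` of `center` (for droplet-style input);
#' by default all waters of a periodic box contribute.
#'
#' @param system Parameterized `mm_system` of waters.
#' @param trajectory An `mm_trajectory` (box used for minimum image).
#' @param inner_radius Optional inclusion radius, Angstrom.
#' @param center Centre for the inclusion rule (default: box centre).
#' @param n_snapshots Use only the first `n_snapshots` frames.
#' @param dielectric Dielectric (default 1, explicit solvent).
#' @return List with `value` (kcal/mol), `sem`, `n_frames`, `n_waters`.
#' @export
bulk_reference <- function(system, trajectory, inner_radius = NULL,
                           center = NULL, n_snapshots = NULL,
                           dielectric = 1) {
  ox <- water_oxygen_indices(system)
  if (length(ox) == 0) abort("no waters selected for the bulk reference")
  nf <- n_frames(trajectory)
  if (!is.null(n_snapshots)) nf <- min(nf, n_snapshots)
  a <- system$atoms
  frame_means <- numeric(nf)
  n_included <- 0L
  for (f in seq_len(nf)) {
    co <- frame_coords(trajectory, f)
    box <- frame_box(trajectory, f) %||% system$box
    keep <- ox
    if (!is.null(inner_radius)) {
      ctr <- center %||% (if (!is.null(box)) box / 2 else
        colMeans(co[ox, , drop = FALSE]))
      d2 <- rowSums(sweep(co[ox, , drop = FALSE], 2, ctr)^2)
      keep <- ox[d2 <= inner_radius^2]
    }
    if (length(keep) == 0) abort("no waters inside the inclusion region")
    es <- vapply(keep, function(oi) {
      watoms <- which(a$is_water & a$resid == a$resid[oi] &
                        a$chain == a$chain[oi])
      water_environment_energy(system, co, watoms, dielectric = dielectric,
                               box = box)
    }, numeric(1))
    frame_means[f] <- mean(es)
    n_included <- length(keep)
  }
  list(value = mean(frame_means),
       sem = safe_sem(frame_means, min(20, nf)),
       n_frames = nf, n_waters = n_included)
}

#' Compare apo and bound hydration sites
#'
#' Classifies every apo site: `displaced` when a ligand heavy atom sits
#' within `overlap_radius` and no bound site matches within `match_radius`
#' (the water returns to bulk, so the binding contribution is minus the apo
#' excess values); `stabilized` when a bound site matches (contribution is
#' bound minus apo); `unchanged` otherwise (zero contribution). Ambiguous
#' multi-matches resolve to the nearest bound site with a message. A totals
#' row (`classification = "sum"`) is appended.
#'
#' @param apo_sites,bound_sites Site tibbles with `x`, `y`, `z` and value
#'   columns `dH`, `mTdS`, `dG` (pass the occupancy-weighted columns under
#'   these names to reproduce occupancy-weighted bookkeeping).
#' @param ligand_heavy_coords Matrix of bound-ligand heavy-atom positions.
#' @param match_radius Apo-bound site matching radius, Angstrom.
#' @param overlap_radius Ligand-overlap radius for displacement, Angstrom.
#' @return Tibble with `apo_site`, `bound_site`, `classification`, `ddH`,
#'   `dTdS`, `ddG` (with `ddG = ddH + dTdS` exactly) plus the sum row.
#' @export
compare_states <- function(apo_sites, bound_sites, ligand_heavy_coords,
                           match_radius = 1.5, overlap_radius = 2.0) {
  lig <- as.matrix(ligand_heavy_coords)
  rows <- list()
  for (i in seq_len(nrow(apo_sites))) {
    ap <- apo_sites[i, ]
    ctr <- c(ap$x, ap$y, ap$z)
    match_j <- NA_integer_
    if (nrow(bound_sites) > 0) {
      db <- sqrt((bound_sites$x - ctr[1])^2 + (bound_sites$y - ctr[2])^2 +
                   (bound_sites$z - ctr[3])^2)
      near <- which(db <= match_radius)
      if (length(near) > 1) {
        message(sprintf("apo site %d matches %d bound sites; taking nearest",
                        i, length(near)))
      }
      if (length(near) >= 1) match_j <- near[which.min(db[near])]
    }
    overlaps <- nrow(lig) > 0 &&
      min(sqrt(rowSums(sweep(lig, 2, ctr)^2))) <= overlap_radius
    if (!is.na(match_j)) {
      bs <- bound_sites[match_j, ]
      rows[[i]] <- tibble(apo_site = i, bound_site = match_j,
                          classification = "stabilized",
                          ddH = bs$dH - ap$dH,
                          dTdS = bs$mTdS - ap$mTdS,
                          ddG = bs$dG - ap$dG)
    } else if (overlaps) {
      rows[[i]] <- tibble(apo_site = i, bound_site = NA_integer_,
                          classification = "displaced",
                          ddH = -ap$dH, dTdS = -ap$mTdS, ddG = -ap$dG)
    } else {
      rows[[i]] <- tibble(apo_site = i, bound_site = NA_integer_,
                          classification = "unchanged",
                          ddH = 0, dTdS = 0, ddG = 0)
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, tibble(apo_site = NA_integer_,
                               bound_site = NA_integer_,
                               classification = "sum",
                               ddH = sum(out$ddH), dTdS = sum(out$dTdS),
                               ddG = sum(out$ddG)))
}

#' Aggregate site rows into group subtotals and a grand total
#'
#' Pure arithmetic over characterized (or compared) site tables: sums the
#' value columns within each group and appends a `Total` row.
#'
#' @param rows Tibble of site rows.
#' @param group Name of the grouping column (e.g. the ligand residue a site
#'   is assigned to); `NULL` sums everything.
#' @param values Character vector of value columns to sum (defaults to the
#'   occupancy-weighted columns when present, else `dH`, `mTdS`, `dG`).
#' @return Tibble of per-group sums plus the `Total` row.
#' @export
aggregate_sites <- function(rows, group = NULL, values = NULL) {
  if (is.null(values)) {
    values <- if ("weighted_dH" %in% names(rows)) {
      c("weighted_dH", "weighted_mTdS", "weighted_dG")
    } else c("dH", "mTdS", "dG")
  }
  if (is.null(group)) {
    sums <- lapply(rows[values], sum)
    return(as_tibble(c(list(group = "Total"), sums)))
  }
  g <- rows |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(values), sum),
                     .groups = "drop")
  names(g)[1] <- "group"
  total <- as_tibble(c(list(group = "Total"),
                       lapply(rows[values], sum)))
  dplyr::bind_rows(g, total)
}
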