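#' Read a structure from PDB-format text
#'
#' Parses fixed-column `ATOM`/`HETATM` records into an [new_system()] object
#' with coordinates attached and force-field parameters unassigned. Water
#' residues are flagged by residue name. Alternate locations keep the
#' highest-occupancy conformer; insertion codes are carried in the residue
#' key.
#'
#' @param input Path to a PDB file, or a character vector of PDB lines.
#' @param water_names Residue names treated as water
#'   (default [water_residue_names()]).
#' @return An `mm_system` with coordinates.
#' @export
read_structure <- function(input, water_names = water_residue_names()) {
  lines <- if (length(input) == 1 && !grepl("\n", input) &&
               file.exists(input)) readLines(input) else
    unlist(strsplit(input, "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  # a single model is enough for a structure; stop at the first ENDMDL
  endm <- which(trimws(rec) == "ENDMDL")
  if (length(endm) > 0) keep <- keep[keep < endm[1]]
  if (length(keep) == 0) abort("no ATOM/HETATM records found (empty input)")
  parsed <- parse_pdb_atoms(lines[keep], keep)
  atoms <- parsed$atoms
  coords <- parsed$coords
  # alternate locations: keep the highest-occupancy conformer
  alt <- parsed$altloc
  if (any(alt != "" & alt != " ")) {
    key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name)
    ord <- order(key, -parsed$occupancy)
    dup <- duplicated(key[ord])
    keep2 <- sort(ord[!dup])
    atoms <- atoms[keep2, ]
    coords <- coords[keep2, , drop = FALSE]
  }
  atoms$is_water <- atoms$resname %in% water_names
  new_system(atoms, coords = coords)
}

parse_pdb_atoms <- function(lines, line_numbers) {
  num_field <- function(txt, what) {
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & trimws(txt) != "")
    bad <- c(bad, which(trimws(txt) == ""))
    if (length(bad) > 0) {
      abort(sprintf("malformed PDB record: non-numeric %s field at line %d",
                    what, line_numbers[bad[1]]))
    }
    val
  }
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 21))
  x <- num_field(substr(lines, 31, 38), "x coordinate")
  y <- num_field(substr(lines, 39, 46), "y coordinate")
  z <- num_field(substr(lines, 47, 54), "z coordinate")
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  if (anyNA(resid)) {
    abort(sprintf("malformed PDB record: bad residue number at line %d",
                  line_numbers[which(is.na(resid))[1]]))
  }
  el <- trimws(substr(lines, 77, 78))
  el[el == ""] <- guess_element(name[el == ""])
  atoms <- tibble(
    serial = serial, name = name, element = toupper(el),
    resname = resname, resid = resid,
    chain = trimws(substr(lines, 22, 22)),
    icode = trimws(substr(lines, 27, 27))
  )
  list(atoms = atoms, coords = cbind(x, y, z),
       altloc = substr(lines, 17, 17), occupancy = occ)
}

#' Write a system (or trajectory) to a PDB file
#'
#' @param system An `mm_system` with coordinates (or with `trajectory` given).
#' @param path Output file path.
#' @param trajectory Optional `mm_trajectory`; frames are written as
#'   `MODEL`/`ENDMDL` blocks.
#' @export
write_structure <- function(system, path, trajectory = NULL) {
  a <- system$atoms
  fmt_one <- function(coords) {
    sprintf("%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$is_water, "HETATM", "ATOM"),
            a$serial %% 100000,
            formatC(a$name, width = -4),
            " ", a$resname, ifelse(a$chain == "", " ", a$chain),
            a$resid %% 10000, ifelse(a$icode == "", " ", a$icode),
            coords[, 1], coords[, 2], coords[, 3], 1, 0,
            a$element)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(trajectory)) {
    writeLines(fmt_one(system$coords), con)
    writeLines("END", con)
  } else {
    for (f in seq_len(n_frames(trajectory))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(fmt_one(frame_coords(trajectory, f)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' Supports multi-model PDB, XYZ, and CHARMM-style binary DCD. The atom count
#' must match `system`.
#'
#' @param path Trajectory file.
#' @param system The `mm_system` the frames belong to.
#' @param interval Frame interval in ps.
#' @param format One of `"auto"`, `"pdb"`, `"xyz"`, `"dcd"`.
#' @return An `mm_trajectory`.
#' @export
read_trajectory <- function(path, system, interval = 1, format = "auto") {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyz = "xyz", dcd = "dcd",
                     abort(sprintf("unsupported trajectory format '.%s'", ext)))
  }
  traj <- switch(format,
    pdb = read_traj_pdb(path, interval),
    xyz = read_traj_xyz(path, interval),
    dcd = read_traj_dcd(path, interval),
    abort(sprintf("unsupported trajectory format '%s'", format)))
  if (dim(traj$coords)[1] != n_atoms(system)) {
    abort(sprintf("trajectory has %d atoms but the system has %d",
                  dim(traj$coords)[1], n_atoms(system)))
  }
  traj
}

read_traj_pdb <- function(path, interval) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0) model_starts <- 1
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_ends) == 0) model_ends <- length(lines)
  frames <- vector("list", length(model_starts))
  for (f in seq_along(model_starts)) {
    span <- model_starts[f]:model_ends[f]
    at <- span[rec[span] %in% c("ATOM  ", "HETATM")]
    parsed <- parse_pdb_atoms(lines[at], at)
    frames[[f]] <- parsed$coords
  }
  new_trajectory(frames, frame_interval = interval, source = path)
}

read_traj_xyz <- function(path, interval) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines) && trimws(lines[i]) != "") {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) abort(sprintf("bad XYZ atom count at line %d", i))
    block <- lines[(i + 2):(i + 1 + na)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    xyz <- apply(parts[, 2:4, drop = FALSE], 2, as.numeric)
    frames[[length(frames) + 1]] <- matrix(xyz, ncol = 3)
    i <- i + 2 + na
  }
  new_trajectory(frames, frame_interval = interval, source = path)
}

# CHARMM-style DCD with 32-bit Fortran record markers, little endian.
read_traj_dcd <- function(path, interval) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_rec <- function() {
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(len) == 0) return(NULL)
    dat <- readBin(con, "raw", len)
    readBin(con, "integer", 1, size = 4, endian = "little")
    dat
  }
  hdr <- rd_rec()
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD") {
    abort("not a DCD file (missing CORD magic)")
  }
  icntrl <- readBin(hdr[5:84], "integer", 20, size = 4, endian = "little")
  nframes <- icntrl[1]
  has_box <- icntrl[11] != 0
  rd_rec() # title block
  natom_rec <- rd_rec()
  natom <- readBin(natom_rec, "integer", 1, size = 4, endian = "little")
  frames <- vector("list", nframes)
  box <- if (has_box) matrix(0, nframes, 3) else NULL
  for (f in seq_len(nframes)) {
    if (has_box) {
      b <- readBin(rd_rec(), "double", 6, size = 8, endian = "little")
      box[f, ] <- b[c(1, 3, 6)]
    }
    x <- readBin(rd_rec(), "double", natom, size = 4, endian = "little")
    y <- readBin(rd_rec(), "double", natom, size = 4, endian = "little")
    z <- readBin(rd_rec(), "double", natom, size = 4, endian = "little")
    frames[[f]] <- cbind(x, y, z)
  }
  new_trajectory(frames, frame_interval = interval, box = box, source = path)
}

#' Write a trajectory to a CHARMM-style DCD file
#'
#' @param trajectory An `mm_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_dcd <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wr_rec <- function(raw) {
    writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
    writeBin(raw, con)
    writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
  }
  nf <- n_frames(trajectory)
  na <- dim(trajectory$coords)[1]
  has_box <- !is.null(trajectory$box)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_box) 1L else 0L
  icntrl[20] <- 24L
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl, raw(), size = 4, endian = "little"))
  wr_rec(hdr)
  title <- charToRaw(formatC("generated by hydrobind", width = -80))
  wr_rec(c(writeBin(1L, raw(), size = 4, endian = "little"), title))
  wr_rec(writeBin(as.integer(na), raw(), size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    co <- frame_coords(trajectory, f)
    if (has_box) {
      b <- trajectory$box[f, ]
      wr_rec(writeBin(as.double(c(b[1], 90, b[2], 90, 90, b[3])), raw(),
                      size = 8, endian = "little"))
    }
    for (d in 1:3) {
      wr_rec(writeBin(as.double(co[, d]), raw(), size = 4,
                      endian = "little"))
    }
  }
  invisible(path)
}

#' Write a trajectory in XYZ format
#' @param trajectory An `mm_trajectory`.
#' @param system The matching `mm_system` (for element symbols).
#' @param path Output path.
#' @export
write_trajectory_xyz <- function(trajectory, system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- system$atoms$element
  for (f in seq_len(n_frames(trajectory))) {
    co <- frame_coords(trajectory, f)
    writeLines(as.character(length(el)), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el,
                       co[, 1], co[, 2], co[, 3]), con)
  }
  invisible(path)
}
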