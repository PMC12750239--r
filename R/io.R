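# GRO (fixed-column, nm) and PDB (Angstrom) structure I/O. GRO is the
# canonical fixture format; PDB is read-only. Atom indices are 0-based in
# memory and 1-based in files, following the formats' own convention.

parse_gro_block <- function(lines, start) {
  title <- lines[start]
  n <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(n)) rlang::abort("malformed GRO: atom count line not an integer")
  atom_lines <- lines[(start + 2):(start + 1 + n)]
  box_line <- lines[start + 2 + n]
  if (is.na(box_line) || !nzchar(trimws(box_line))) {
    rlang::abort("malformed GRO: missing box line")
  }
  time <- NA_real_
  tm <- regmatches(title, regexec("t=\\s*([0-9eE+.-]+)", title))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])

  resid <- as.integer(substr(atom_lines, 1, 5))
  resname <- trimws(substr(atom_lines, 6, 10))
  atomname <- trimws(substr(atom_lines, 11, 15))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  box <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])[1:3]
  if (anyNA(box) || any(box <= 0)) rlang::abort("malformed GRO: bad box line")

  list(time = time, resid = resid, resname = resname, atomname = atomname,
       xyz = cbind(x, y, z), box = box,
       next_start = start + 3 + n)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  start <- 1
  while (start <= length(lines) && nzchar(trimws(lines[start]))) {
    blk <- parse_gro_block(lines, start)
    frames[[length(frames) + 1]] <- blk
    start <- blk$next_start
  }
  if (length(frames) == 0) rlang::abort("no frames found in GRO file")
  frames
}

#' Read a structure file into a topology and a coordinate frame
#'
#' Reads a GRO (nm) or PDB (Angstrom, converted to nm) file and resolves
#' every atom's role, charge and selector label through the species map.
#' Atoms of residues listed under `solvent` get no lipid membership; an
#' atom absent from the map is an error naming the atom, so role
#' assignment is always explicit.
#'
#' @param path GRO or PDB file.
#' @param species_map A [read_species_map()] result, or a path to one.
#' @return A list with elements `topology` ([bl_topology]) and `frame`
#'   (list with `time`, `xyz`, `box`).
#' @export
read_structure <- function(path, species_map) {
  if (is.character(species_map)) species_map <- read_species_map(species_map)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    gro = read_gro_frames(path)[[1]],
    pdb = read_pdb_frame(path),
    rlang::abort(paste0("unsupported structure format: .", ext)))

  n <- length(raw$resname)
  role <- character(n); charge <- numeric(n); carbon <- integer(n)
  label <- character(n); mass <- numeric(n); solvent <- logical(n)
  for (i in seq_len(n)) {
    e <- species_map_entry(species_map, raw$resname[i], raw$atomname[i])
    role[i] <- e$role; charge[i] <- e$charge; carbon[i] <- e$carbon
    label[i] <- e$label; mass[i] <- e$mass; solvent[i] <- e$solvent
  }

  # consecutive residues -> molecules; solvent residues get NA lipid_id
  res_change <- c(TRUE, diff(raw$resid) != 0 |
                    raw$resname[-1] != raw$resname[-n])
  mol <- cumsum(res_change)
  lipid_id <- ifelse(solvent, NA_integer_, mol)
  if (any(!solvent)) {
    lipid_id[!solvent] <- as.integer(factor(lipid_id[!solvent]))
  }

  atoms <- tibble::tibble(
    atom_id = seq_len(n) - 1L, name = raw$atomname,
    lipid_id = as.integer(lipid_id), species = raw$resname,
    role = role, carbon = carbon, charge = charge, label = label, mass = mass)
  topology <- bl_topology(atoms)
  frame <- list(time = if (is.na(raw$time)) 0 else raw$time,
                xyz = unname(raw$xyz), box = raw$box)
  list(topology = topology, frame = frame)
}

read_pdb_frame <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    rlang::abort("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cryst) == 0) rlang::abort("PDB file has no CRYST1 box record")
  abc <- c(as.numeric(substr(cryst[1], 7, 15)),
           as.numeric(substr(cryst[1], 16, 24)),
           as.numeric(substr(cryst[1], 25, 33)))
  if (anyNA(abc) || any(abc <= 0)) {
    rlang::abort("PDB CRYST1 record has no usable box lengths")
  }
  a <- pdb$atom
  list(time = NA_real_,
       resid = as.integer(a$resno), resname = trimws(a$resid),
       atomname = trimws(a$elety),
       xyz = cbind(a$x, a$y, a$z) / 10,   # Angstrom -> nm
       box = abc / 10)
}

#' Load a trajectory from frame files
#'
#' Reads one or more (multi-frame) GRO files, checks each frame against
#' the topology, orders frames in time and applies the analysis window.
#' Frames without a `t=` stamp in their title line are numbered by file
#' order at `dt_fallback` spacing.
#'
#' @param topology A [bl_topology] (from [read_structure()]).
#' @param paths Character vector of GRO trajectory files.
#' @param window Optional `c(t_start, t_end)` ps; default the full range.
#' @param dt_fallback Frame spacing (ps) assumed when files carry no time
#'   stamps.
#' @return A [bl_trajectory].
#' @export
load_trajectory <- function(topology, paths, window = NULL, dt_fallback = 1) {
  blocks <- purrr::list_flatten(purrr::map(paths, read_gro_frames))
  n_atoms <- nrow(topology$atoms)
  frames <- purrr::imap(blocks, function(b, i) {
    if (nrow(b$xyz) != n_atoms) {
      rlang::abort(sprintf(
        "frame %d has %d atoms but topology has %d", i, nrow(b$xyz), n_atoms))
    }
    list(time = b$time, xyz = unname(b$xyz), box = b$box)
  })
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(times)) {
    times <- (seq_along(frames) - 1) * dt_fallback
    frames <- purrr::map2(frames, times, function(f, t) { f$time <- t; f })
  }
  bl_trajectory(topology, frames, window = window)
}

#' Write a trajectory (or single frame) as multi-frame GRO
#'
#' @param traj A [bl_trajectory].
#' @param path Output file.
#' @param frames_only Optional integer indices of frames to write.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, frames_only = NULL) {
  atoms <- traj$topology$atoms
  frames <- traj$frames
  if (!is.null(frames_only)) frames <- frames[frames_only]
  resid <- ifelse(is.na(atoms$lipid_id),
                  max(atoms$lipid_id, na.rm = TRUE) + 1L, atoms$lipid_id)
  resid <- ((resid - 1L) %% 99999L) + 1L
  atnum <- ((atoms$atom_id) %% 99999L) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("bilayr frame t= %.3f", f$time), con)
    writeLines(sprintf("%5d", nrow(atoms)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, substr(atoms$species, 1, 5),
                       substr(atoms$name, 1, 5), atnum,
                       f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}
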