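#' Coarse-grained lipid topology
#'
#' Bead-level description of a lipid system: one row per bead with the
#' owning lipid id, species label, bead name and structural role. Roles
#' follow the coarse-grained lipid architecture: `head` (choline/amine),
#' `marker` (phosphate; the headgroup-marker bead anchoring all region and
#' leaflet logic), `linker` (glycerol), `tail` and `tail_end` (terminal
#' acyl bead). Cardiolipin species carry two phosphate markers; their lipid
#' position is the midpoint of the two.
#'
#' @param species character vector, one entry per lipid (e.g.
#'   `rep(c("POPC", "POPE"), c(80, 20))`), or a named count vector.
#' @param templates named list of per-species bead templates (data frames
#'   with columns `bead`, `role`); defaults cover POPC/POPE/DOPE-style
#'   two-tail lipids, four-tail cardiolipin (CDL1, CDL2) and the label-only
#'   TEST species.
#' @return a `topology` data frame with columns `lipid_id`, `species`,
#'   `bead`, `role`, `charge`.
#' @examples
#' topo <- make_topology(c(POPC = 8, POPE = 2))
#' head(topo)
#' @export
make_topology <- function(species, templates = bead_templates()) {
  if (!is.null(names(species)) && is.numeric(species))
    species <- rep(names(species), as.integer(species))
  species <- as.character(species)
  unknown <- setdiff(unique(species), names(templates))
  if (length(unknown))
    stop("no bead template for species: ", paste(unknown, collapse = ", "))
  rows <- lapply(seq_along(species), function(i) {
    tpl <- templates[[species[i]]]
    data.frame(lipid_id = i, species = species[i], bead = tpl$bead,
               role = tpl$role, charge = tpl$charge,
               stringsAsFactors = FALSE)
  })
  topo <- do.call(rbind, rows)
  class(topo) <- c("topology", "data.frame")
  topo
}

#' @rdname make_topology
#' @export
bead_templates <- function() {
  two_tail <- function(charge) data.frame(
    bead = c("NC3", "PO4", "GL1", "GL2",
             "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B"),
    role = c("head", "marker", "linker", "linker",
             "tail", "tail", "tail", "tail_end",
             "tail", "tail", "tail", "tail_end"),
    charge = charge, stringsAsFactors = FALSE)
  cdl <- function(charge) data.frame(
    bead = c("GL0", "PO41", "PO42", "GL1", "GL2", "GL3", "GL4",
             paste0("C", rep(1:4, 4), rep(c("A", "B", "C", "D"), each = 4))),
    role = c("linker", "marker", "marker", rep("linker", 4),
             rep(c("tail", "tail", "tail", "tail_end"), 4)),
    charge = charge, stringsAsFactors = FALSE)
  list(POPC = two_tail(0), POPE = two_tail(0), DOPE = two_tail(0),
       TEST = two_tail(0), CDL2 = cdl(-2), CDL1 = cdl(-1))
}

n_lipids <- function(topology) length(unique(topology$lipid_id))

# Per-lipid anchor position: the marker bead, or the midpoint of the
# marker beads for species with two phosphates (cardiolipin).
marker_positions <- function(topology, coords) {
  stopifnot(nrow(topology) == nrow(coords))
  idx <- which(topology$role == "marker")
  lid <- topology$lipid_id[idx]
  x <- rowsum(coords[idx, , drop = FALSE], lid)
  cnt <- as.vector(table(lid)[rownames(x)])
  pos <- x / cnt
  lipid_ids <- as.integer(rownames(x))
  ord <- order(lipid_ids)
  species <- topology$species[match(lipid_ids[ord], topology$lipid_id)]
  list(lipid_id = lipid_ids[ord], species = species,
       xyz = pos[ord, , drop = FALSE])
}

new_frame <- function(time, coords, box, forces = NULL,
                      atom_names = NULL, res_ids = NULL, res_names = NULL) {
  coords <- as_xyz(coords)
  if (!is.null(forces)) forces <- as_xyz(forces)
  structure(list(time = time, coords = coords, box = box, forces = forces,
                 atom_names = atom_names, res_ids = res_ids,
                 res_names = res_names),
            class = "imm_frame")
}

new_trajectory <- function(topology, frames) {
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  structure(list(topology = topology, frames = frames),
            class = "imm_trajectory")
}

#' @export
print.imm_trajectory <- function(x, ...) {
  tm <- frame_times(x)
  cat(sprintf("imm_trajectory: %d frames, %d lipids (%d beads), t = %.3g..%.3g ns\n",
              length(x$frames), n_lipids(x$topology), nrow(x$topology),
              min(tm), max(tm)))
  print(table(species = x$topology$species[!duplicated(x$topology$lipid_id)]))
  invisible(x)
}

#' Frame times of a trajectory (ns)
#' @param traj an `imm_trajectory`.
#' @return numeric vector of frame times.
#' @export
frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Read coordinate frames
#'
#' Reads a GRO file, a PDB file, or a tabular "frame table" (CSV with
#' columns `time, lipid_id, species, bead, x, y, z` and optional
#' `fx, fy, fz` force columns) into a trajectory. GRO coordinates (nm) and
#' frame-table/PDB coordinates (Angstrom) are all returned in Angstrom.
#' When a `topology` is supplied, bead counts are checked against it;
#' for frame tables the topology is reconstructed from the table when
#' omitted.
#'
#' @param path file path.
#' @param format `"gro"`, `"pdb"` or `"frame-table"`; guessed from the file
#'   extension by default.
#' @param topology optional [make_topology()] result to validate against.
#' @return an `imm_trajectory`.
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb", "frame-table"),
                        topology = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb",
                     csv = "frame-table", tsv = "frame-table",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "gro" = read_gro(path, topology),
         "pdb" = read_pdb_frames(path, topology),
         "frame-table" = read_frame_table(path, topology))
}

check_topology <- function(frame_n, topology, path) {
  if (!is.null(topology) && nrow(topology) != frame_n)
    stop(sprintf("topology mismatch for %s: file has %d beads, topology %d",
                 path, frame_n, nrow(topology)))
}

read_gro <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) break
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n))
      stop(sprintf("malformed GRO atom count at line %d of %s", i + 1L, path))
    if (i + 1L + n + 1L > length(lines))
      stop(sprintf("truncated GRO frame starting at line %d of %s", i, path))
    body <- lines[(i + 2L):(i + 1L + n)]
    res_ids <- suppressWarnings(as.integer(substr(body, 1, 5)))
    res_names <- trimws(substr(body, 6, 10))
    atom_names <- trimws(substr(body, 11, 15))
    xs <- suppressWarnings(as.numeric(substr(body, 21, 28)))
    ys <- suppressWarnings(as.numeric(substr(body, 29, 36)))
    zs <- suppressWarnings(as.numeric(substr(body, 37, 44)))
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | is.na(res_ids))
    if (length(bad))
      stop(sprintf("malformed GRO record at line %d of %s", i + 1L + bad[1], path))
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + n]),
                                                 "\\s+")[[1]]))
    if (length(boxv) < 3 || any(is.na(boxv[1:3])))
      stop(sprintf("malformed GRO box line at line %d of %s", i + 2L + n, path))
    tm <- 0
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m)) tm <- as.numeric(sub("t=\\s*", "", m)) / 1000  # ps -> ns
    check_topology(n, topology, path)
    frames[[length(frames) + 1L]] <- new_frame(
      time = tm, coords = nm_to_ang(cbind(xs, ys, zs)),
      box = nm_to_ang(boxv[1:3]),
      atom_names = atom_names, res_ids = res_ids, res_names = res_names)
    i <- i + n + 3L
  }
  if (!length(frames)) stop("no frames found in ", path)
  if (is.null(topology)) topology <- topology_from_atoms(frames[[1L]])
  new_trajectory(topology, frames)
}

# Reconstruct a minimal topology from residue/atom records when none given.
topology_from_atoms <- function(frame) {
  rid <- frame$res_ids
  lipid_id <- cumsum(c(TRUE, rid[-1] != rid[-length(rid)]))
  role <- rep("tail", length(rid))
  role[grepl("^PO4", frame$atom_names)] <- "marker"
  role[grepl("^GL", frame$atom_names)] <- "linker"
  role[frame$atom_names %in% c("NC3", "NH3")] <- "head"
  role[grepl("^C4", frame$atom_names)] <- "tail_end"
  topo <- data.frame(lipid_id = lipid_id, species = frame$res_names,
                     bead = frame$atom_names, role = role, charge = 0,
                     stringsAsFactors = FALSE)
  class(topo) <- c("topology", "data.frame")
  topo
}

#' Write coordinate frames
#'
#' Writes a trajectory (or single frame) to GRO, PDB or frame-table format.
#' GRO output is in nm at the format's fixed 0.001 nm precision; PDB and
#' frame tables are in Angstrom.
#'
#' @param traj an `imm_trajectory`.
#' @param path output file.
#' @param format `"gro"`, `"pdb"` or `"frame-table"`; guessed from the
#'   extension by default.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path,
                         format = c("auto", "gro", "pdb", "frame-table")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", csv = "frame-table",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  switch(format,
         "gro" = write_gro(traj, path),
         "pdb" = write_pdb_frames(traj, path),
         "frame-table" = write_frame_table(traj, path))
  invisible(path)
}

write_gro <- function(traj, path) {
  topo <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    nm <- ang_to_nm(fr$coords)
    writeLines(sprintf("immsort frame t= %.3f", fr$time * 1000), con)
    writeLines(sprintf("%5d", nrow(nm)), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     topo$lipid_id %% 100000L, substr(topo$species, 1, 5),
                     substr(topo$bead, 1, 5), seq_len(nrow(nm)) %% 100000L,
                     nm[, 1], nm[, 2], nm[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", ang_to_nm(fr$box[1]),
                       ang_to_nm(fr$box[2]), ang_to_nm(fr$box[3])), con)
  }
}

# Fixed-column PDB dialect with 4-character lipid residue names occupying
# columns 18-21 (the common membrane-simulation extension of the standard
# 3-character field); orthorhombic box on CRYST1.
read_pdb_frames <- function(path, topology = NULL) {
  lines <- readLines(path)
  box <- c(NA_real_, NA_real_, NA_real_)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl))
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
  at <- grep("^(ATOM  |HETATM)", lines)
  if (!length(at)) stop("no ATOM records in ", path)
  body <- lines[at]
  xs <- suppressWarnings(as.numeric(substr(body, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(body, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(body, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop(sprintf("malformed PDB record at line %d of %s", at[bad[1]], path))
  check_topology(length(xs), topology, path)
  fr <- new_frame(time = 0, coords = cbind(xs, ys, zs), box = box,
                  atom_names = trimws(substr(body, 13, 16)),
                  res_ids = suppressWarnings(as.integer(substr(body, 23, 26))),
                  res_names = trimws(substr(body, 18, 21)))
  if (is.null(topology)) topology <- topology_from_atoms(fr)
  new_trajectory(topology, list(fr))
}

write_pdb_frames <- function(traj, path) {
  topo <- traj$topology
  fr <- traj$frames[[1L]]
  if (length(traj$frames) > 1L)
    warning("PDB export writes the first frame only")
  out <- character()
  if (all(is.finite(fr$box)))
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   fr$box[1], fr$box[2], fr$box[3], 90, 90, 90)
  out <- c(out, sprintf(
    "ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(fr$coords)) %% 100000L, substr(topo$bead, 1, 4),
    substr(topo$species, 1, 4), topo$lipid_id %% 10000L,
    fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), "END")
  writeLines(out, path)
  invisible(path)
}

#' @rdname read_frames
#' @export
read_frame_table <- function(path, topology = NULL) {
  dt <- data.table::fread(path)
  req <- c("time", "lipid_id", "species", "bead", "x", "y", "z")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("frame table missing columns: ", paste(miss, collapse = ", "))
  has_forces <- all(c("fx", "fy", "fz") %in% names(dt))
  times <- sort(unique(dt$time))
  box <- if (all(c("box_x", "box_y", "box_z") %in% names(dt)))
    unlist(dt[1L, c("box_x", "box_y", "box_z")]) else rep(NA_real_, 3)
  frames <- lapply(times, function(tm) {
    sub <- dt[dt$time == tm, ]
    sub <- sub[order(sub$lipid_id), ]
    new_frame(time = tm, coords = cbind(sub$x, sub$y, sub$z), box = box,
              forces = if (has_forces) cbind(sub$fx, sub$fy, sub$fz) else NULL,
              atom_names = sub$bead, res_ids = sub$lipid_id,
              res_names = sub$species)
  })
  n0 <- nrow(frames[[1L]]$coords)
  for (fr in frames) check_topology(nrow(fr$coords), topology, path)
  if (any(vapply(frames, function(f) nrow(f$coords), 0L) != n0))
    stop("frame table: bead count varies across frames")
  if (is.null(topology)) topology <- topology_from_atoms(frames[[1L]])
  new_trajectory(topology, frames)
}

#' @rdname write_frames
#' @export
write_frame_table <- function(traj, path) {
  topo <- traj$topology
  rows <- lapply(traj$frames, function(fr) {
    d <- data.table::data.table(
      time = fr$time, lipid_id = topo$lipid_id, species = topo$species,
      bead = topo$bead, x = fr$coords[, 1], y = fr$coords[, 2],
      z = fr$coords[, 3])
    if (!is.null(fr$forces)) {
      d$fx <- fr$forces[, 1]; d$fy <- fr$forces[, 2]; d$fz <- fr$forces[, 3]
    }
    if (all(is.finite(fr$box))) {
      d$box_x <- fr$box[1]; d$box_y <- fr$box[2]; d$box_z <- fr$box[3]
    }
    d
  })
  data.table::fwrite(data.table::rbindlist(rows, fill = TRUE), path)
  invisible(path)
}

#' Assign leaflet and region labels to a frame
#'
#' Labels every lipid of a frame by leaflet and cristae region using its
#' headgroup-marker position (midpoint of the two phosphates for
#' cardiolipin): the leaflet is the sign of the signed distance from the
#' marker to the mid-surface along the local normal (negative = inner), the
#' region comes from [assign_region()]. Markers farther than the bilayer
#' thickness from the mid-surface are flagged unassigned.
#'
#' @param frame an `imm_frame` (one element of `traj$frames`).
#' @param geom an [imm_geometry()].
#' @param topology the bead topology of the frame.
#' @return a `labeled_frame`: the frame plus a `lipids` data frame with
#'   columns `lipid_id, species, rho, z, sdist, leaflet, region`.
#' @export
assign_leaflets <- function(frame, geom, topology) {
  mk <- marker_positions(topology, frame$coords)
  rz <- polar_transform(mk$xyz)
  sc <- surface_coords_rz(rz[, 1], rz[, 2], geom)
  leaflet <- ifelse(sc$sdist >= 0, "outer", "inner")
  region <- sc$region
  un <- abs(sc$sdist) > geom$bilayer_thickness
  leaflet[un] <- NA_character_
  region[un] <- "unassigned"
  frame$lipids <- data.frame(
    lipid_id = mk$lipid_id, species = mk$species,
    rho = rz[, 1], z = rz[, 2], sdist = sc$sdist,
    leaflet = leaflet, region = region, stringsAsFactors = FALSE)
  class(frame) <- c("labeled_frame", class(frame))
  frame
}

#' Label every frame of a trajectory
#'
#' @inheritParams assign_leaflets
#' @param traj an `imm_trajectory`.
#' @return the trajectory with every frame labelled (class
#'   `labeled_trajectory`).
#' @export
label_trajectory <- function(traj, geom) {
  traj$frames <- lapply(traj$frames, assign_leaflets, geom = geom,
                        topology = traj$topology)
  class(traj) <- c("labeled_trajectory", class(traj))
  traj
}
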