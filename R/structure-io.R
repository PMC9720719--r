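#' Read a multi-chain channel structure from PDB text
#'
#' Parses PDB v3.3 `ATOM`/`HETATM` records into a [structure_model()].  The
#' chain-to-subunit mapping is explicit user configuration (deposited chain
#' IDs vary between entries); unmapped chains, waters, lipids and ions are
#' dropped.  Alternate locations other than `''`/`'A'` are discarded so the
#' atom set is deterministic; insertion codes are rejected outright because a
#' silently shifted numbering would corrupt every downstream residue
#' selection.  Hydrogens are retained here and excluded later by element
#' filter where an analysis is defined over heavy atoms.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chain_map named integer vector mapping chain IDs to subunit indices,
#'   e.g. `c(A = 1, B = 2, C = 3, D = 4)`.
#' @param keep_hetatm keep non-water `HETATM` records (default drops them; the
#'   analyses are protein-only).
#' @param label,state_tag passed to [structure_model()].
#' @return A [structure_model()] with `numbering = "deposited"`.
#' @seealso [read_trajectory()] for multi-model (MODEL/ENDMDL) files.
#' @export
read_structure <- function(pdb, chain_map, keep_hetatm = FALSE,
                           label = "", state_tag = "unknown") {
  lines <- .pdb_lines_in(pdb)
  if (sum(grepl("^MODEL ", lines)) > 1L)
    stop("multi-model file: use read_trajectory() for trajectories")
  atoms <- .parse_pdb_atoms(lines, chain_map, keep_hetatm)
  if (nrow(atoms) == 0L)
    stop("no atoms selected: check chain_map against the file's chain IDs")
  structure_model(atoms, label = label, state_tag = state_tag,
                  numbering = "deposited")
}

.pdb_lines_in <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
    return(readLines(pdb, warn = FALSE))
  unlist(strsplit(pdb, "\n", fixed = TRUE))
}

# fixed-column extraction of ATOM/HETATM records; line numbers kept for errors
.parse_pdb_atoms <- function(lines, chain_map, keep_hetatm = FALSE) {
  if (is.null(names(chain_map)) || any(!nzchar(names(chain_map))))
    stop("chain_map must be a named vector: c(A = 1, B = 2, ...)")
  if (any(!chain_map %in% 1:4)) stop("chain_map subunits must be in 1..4")
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  idx <- which(is_atom)
  if (length(idx) == 0L) return(.empty_atoms())
  ln <- lines[idx]
  short <- nchar(ln) < 54L
  if (any(short))
    stop("unparseable coordinate line ", idx[which(short)[1L]],
         ": record shorter than 54 columns")
  icode <- substr(ln, 27L, 27L)
  if (any(icode != " "))
    stop("insertion code at line ", idx[which(icode != " ")[1L]],
         ": insertion codes are not supported; renumber the input")
  x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
  resno <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
  serial <- suppressWarnings(as.integer(substr(ln, 7L, 11L)))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resno)
  if (any(bad))
    stop("unparseable coordinate line ", idx[which(bad)[1L]],
         ": non-numeric coordinate or residue-number field")
  chain <- substr(ln, 22L, 22L)
  altloc <- substr(ln, 17L, 17L)
  resname <- trimws(substr(ln, 18L, 20L))
  keep <- chain %in% names(chain_map) &
    altloc %in% c(" ", "A") &
    !resname %in% c("HOH", "WAT", "TIP3", "SOL", "NA", "CL", "K", "MG", "CA2")
  if (!any(keep)) return(.empty_atoms())
  ln <- ln[keep]
  name <- trimws(substr(ln, 13L, 16L))
  element <- trimws(substr(ln, 77L, 78L))
  noel <- !nzchar(element)
  if (any(noel)) element[noel] <- .element_from_name(name[noel])
  data.frame(
    serial = serial[keep], name = name, element = element,
    resno = resno[keep], resname = resname[keep],
    subunit = as.integer(chain_map[chain[keep]]),
    x = x[keep], y = y[keep], z = z[keep],
    stringsAsFactors = FALSE
  )
}

.empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             resno = integer(), resname = character(), subunit = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

# first alphabetic character of the atom name, skipping leading digits
# ("1HB" -> H, "CA" -> C); two-letter metals are not expected in protein input
.element_from_name <- function(name) {
  el <- sub("^[0-9]*", "", name)
  substr(el, 1L, 1L)
}

#' Write a structure model as PDB text
#'
#' Subunits are written as chains A-D with a regenerated `TER` record after
#' each; serials are renumbered sequentially; coordinates to 3 decimals per
#' the PDB convention, so a read-write-read cycle is stable on the atom table.
#'
#' @param model a [structure_model()].
#' @param path output file; if `NULL`, the PDB lines are returned instead.
#' @return Invisibly, the lines written (or the lines themselves if
#'   `path = NULL`).
#' @export
write_structure <- function(model, path = NULL) {
  lines <- c(.format_pdb_atoms(model), "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

.format_pdb_atoms <- function(model, serial_start = 1L) {
  a <- model$atoms
  serial <- seq.int(serial_start, length.out = nrow(a))
  nm <- ifelse(nchar(a$name) <= 3L, paste0(" ", a$name), a$name)
  rows <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  serial %% 100000L, nm, a$resname, LETTERS[a$subunit],
                  a$resno, a$x, a$y, a$z, 1, 0, a$element)
  out <- character(0)
  for (s in sort(unique(a$subunit))) {
    sel <- a$subunit == s
    last <- which(sel)[sum(sel)]
    out <- c(out, rows[sel],
             sprintf("TER   %5d      %-3s %1s%4d",
                     (serial[last] + 1L) %% 100000L, a$resname[last],
                     LETTERS[s], a$resno[last]))
  }
  out
}

#' Trajectory ensembles
#'
#' Ordered coordinate frames sharing one topology (atom identity and order).
#' `frame_spacing` is a nominal inter-frame time (e.g. 1 ns/frame when 1000
#' equally spaced frames are retained from a 1 microsecond run).
#'
#' @param topology a [structure_model()] defining atom identity and order.
#' @param frames list of n x 3 coordinate matrices, one per frame.
#' @param frame_spacing nominal time per frame (arbitrary units).
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(topology, frames, frame_spacing = 1) {
  stopifnot(inherits(topology, "structure_model"), is.list(frames))
  if (length(frames) < 1L) stop("trajectory needs at least one frame")
  n <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3L,
               logical(1L))
  if (!all(ok)) stop("every frame must be an n x 3 matrix matching the topology")
  structure(list(topology = topology, frames = frames,
                 frame_spacing = frame_spacing),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", length(x$frames), "frames x",
      nrow(x$topology$atoms), "atoms, spacing", x$frame_spacing, "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory_ensemble()].
#' @export
n_frames <- function(traj) length(traj$frames)

#' One frame of a trajectory as a structure model
#'
#' @param traj a [trajectory_ensemble()].
#' @param i frame index.
#' @return The topology with frame `i` coordinates.
#' @export
frame_model <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  set_model_xyz(traj$topology, traj$frames[[i]])
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames; the first block defines the topology
#' (parsed exactly as in [read_structure()]) and later blocks must present the
#' same atoms in the same order.
#'
#' @inheritParams read_structure
#' @param frame_spacing nominal time per frame.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory <- function(pdb, chain_map, keep_hetatm = FALSE,
                            label = "", frame_spacing = 1) {
  lines <- .pdb_lines_in(pdb)
  starts <- grep("^MODEL ", lines)
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1L] - 1L, length(lines))
  frames <- vector("list", length(starts))
  topo <- NULL
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    atoms <- .parse_pdb_atoms(blk, chain_map, keep_hetatm)
    if (nrow(atoms) == 0L) stop("frame ", k, " contains no mapped atoms")
    m <- structure_model(atoms, label = label, numbering = "deposited")
    if (is.null(topo)) {
      topo <- m
    } else if (nrow(m$atoms) != nrow(topo$atoms) ||
               any(m$atoms$resno != topo$atoms$resno) ||
               any(m$atoms$name != topo$atoms$name)) {
      stop("frame ", k, " does not match the topology of frame 1")
    }
    frames[[k]] <- model_xyz(m)
  }
  trajectory_ensemble(topo, frames, frame_spacing = frame_spacing)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory_ensemble()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(.format_pdb_atoms(frame_model(traj, k)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
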