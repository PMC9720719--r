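#' RMSD time series against the first frame
#'
#' Each frame is rigid-body fitted (Kabsch) to the first frame over the
#' selected atoms before the RMSD is taken over the same atoms, removing
#' global translation and rotation.  The first entry is exactly zero.
#'
#' @param traj a [trajectory_ensemble()] with at least 2 frames.
#' @param atom_names atom names used for fitting and RMSD (default
#'   alpha-carbons); `NULL` selects all heavy atoms.
#' @return Data frame with columns `frame`, `time`, `rmsd` (Angstrom).
#' @export
rmsd_timeseries <- function(traj, atom_names = "CA") {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (n_frames(traj) < 2L) stop("need at least 2 frames for a time series")
  sel <- .atom_selection(traj$topology, atom_names)
  if (length(sel) == 0L) stop("empty atom selection")
  ref <- traj$frames[[1L]][sel, , drop = FALSE]
  r <- vapply(seq_len(n_frames(traj)), function(k) {
    .kabsch(traj$frames[[k]][sel, , drop = FALSE], ref)$rmsd
  }, numeric(1L))
  r[1L] <- 0
  data.frame(frame = seq_len(n_frames(traj)),
             time = (seq_len(n_frames(traj)) - 1L) * traj$frame_spacing,
             rmsd = r)
}

.atom_selection <- function(topology, atom_names) {
  a <- topology$atoms
  heavy <- !.is_hydrogen(a$element)
  if (is.null(atom_names)) which(heavy) else which(heavy & a$name %in% atom_names)
}

#' Average structure over the last N frames
#'
#' Retains the final `last_n` frames, fits each to the first retained frame to
#' remove the global translational and rotational degrees of freedom, and
#' averages the coordinates arithmetically.  The result is a single structure
#' summarizing the tail of the run (e.g. the last 100 of 1000 frames, i.e.
#' the last 100 ns at 1 frame/ns); highly flexible regions can look distorted
#' in such an average, which is accepted — it exists to compare well-ordered
#' structural elements across systems with one structure per system.
#'
#' @param traj a [trajectory_ensemble()].
#' @param last_n number of trailing frames to average (>= 1).
#' @param fit_atom_names atom selection for the removal fit (default: all
#'   heavy atoms).
#' @return A [structure_model()] with the averaged coordinates; the label
#'   records the frame window.
#' @export
average_structure <- function(traj, last_n, fit_atom_names = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  nf <- n_frames(traj)
  if (last_n < 1L) stop("last_n must be at least 1")
  if (last_n > nf) stop("last_n (", last_n, ") exceeds frame count (", nf, ")")
  idx <- seq.int(nf - last_n + 1L, nf)
  sel <- .atom_selection(traj$topology, fit_atom_names)
  ref <- traj$frames[[idx[1L]]]
  acc <- matrix(0, nrow(ref), 3L)
  for (k in idx) {
    f <- traj$frames[[k]]
    fit <- .kabsch(f[sel, , drop = FALSE], ref[sel, , drop = FALSE])
    acc <- acc + .transform_xyz(f, fit)
  }
  out <- set_model_xyz(traj$topology, acc / length(idx))
  out$label <- sprintf("%s avg[%d-%d]", traj$topology$label, idx[1L], nf)
  out
}

#' Substructure RMSD under the best-aligned-chain-pair criterion
#'
#' Both tetramers are reduced to the region on all four subunits; then, for
#' each of the 4 x 4 subunit pairings, the model's subunit i is superposed
#' onto the reference's subunit j and the RMSD of the *whole four-subunit*
#' substructure is evaluated under that single transform, with the cyclic
#' subunit correspondence (i+k vs j+k mod 4) implied by the pairing.  The
#' minimum over all pairings is reported — anchoring on the best-aligned pair
#' of chains while keeping the four subunits in their mutual 3-D arrangement,
#' since it is that arrangement (the gate aperture) that encodes the channel
#' state.
#'
#' @param model,reference tetramer [structure_model()] objects (all four
#'   subunits present) in canonical numbering.
#' @param region a [residue_region()] present on all four subunits of both.
#' @param atom_names RMSD atom selection (default alpha-carbons).
#' @return List of class `substructure_rmsd`: `rmsd` (the minimum, Angstrom),
#'   `best_pair` (model subunit, reference subunit), `all_pairings` (4 x 4
#'   matrix of RMSDs).
#' @export
substructure_rmsd <- function(model, reference, region, atom_names = "CA") {
  m <- extract_regions(model, region)
  r <- extract_regions(reference, region)
  for (s in 1:4) {
    if (!s %in% m$atoms$subunit)
      stop("region '", region$name, "' absent from model subunit ", s)
    if (!s %in% r$atoms$subunit)
      stop("region '", region$name, "' absent from reference subunit ", s)
  }
  # per-subunit paired coordinate sets with a common (resno, name) key order
  key_of <- function(x, s) {
    a <- x$atoms[x$atoms$subunit == s & x$atoms$name %in% atom_names &
                   !.is_hydrogen(x$atoms$element), , drop = FALSE]
    a[order(a$resno, a$name), , drop = FALSE]
  }
  keys <- lapply(1:4, function(s) {
    am <- key_of(m, s); ar <- key_of(r, s)
    shared <- intersect(paste(am$resno, am$name), paste(ar$resno, ar$name))
    list(shared = shared, am = am, ar = ar)
  })
  # a common residue/atom key set across all subunits keeps pairings comparable
  shared <- Reduce(intersect, lapply(keys, `[[`, "shared"))
  if (length(shared) < 3L)
    stop("fewer than 3 shared '", paste(atom_names, collapse = ","),
         "' atoms in region '", region$name, "'")
  coords <- function(a, ord) as.matrix(a[match(shared, ord), c("x", "y", "z")])
  M <- lapply(keys, function(k) coords(k$am, paste(k$am$resno, k$am$name)))
  R <- lapply(keys, function(k) coords(k$ar, paste(k$ar$resno, k$ar$name)))

  rm_mat <- matrix(NA_real_, 4L, 4L, dimnames = list(model = 1:4, reference = 1:4))
  for (i in 1:4) for (j in 1:4) {
    fit <- .kabsch(M[[i]], R[[j]])
    dev2 <- 0
    npts <- 0L
    for (k in 0:3) {
      mi <- ((i - 1L + k) %% 4L) + 1L
      rj <- ((j - 1L + k) %% 4L) + 1L
      d <- .transform_xyz(M[[mi]], fit) - R[[rj]]
      dev2 <- dev2 + sum(d^2)
      npts <- npts + nrow(d)
    }
    rm_mat[i, j] <- sqrt(dev2 / npts)
  }
  best <- which(rm_mat == min(rm_mat), arr.ind = TRUE)[1L, ]
  structure(list(rmsd = min(rm_mat),
                 best_pair = c(model = unname(best[1L]),
                               reference = unname(best[2L])),
                 all_pairings = rm_mat),
            class = "substructure_rmsd")
}

#' @export
print.substructure_rmsd <- function(x, ...) {
  cat(sprintf("substructure RMSD %.3f A (model subunit %d onto reference subunit %d)\n",
              x$rmsd, x$best_pair[1L], x$best_pair[2L]))
  invisible(x)
}
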