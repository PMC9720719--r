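#' Specification of a toy C4-symmetric channel
#'
#' Describes a four-subunit pseudo-helical channel around the z axis with a
#' central constriction of tunable radius, mimicking the geometry a
#' tetrameric ion channel presents to a pore profiler.  The walls are rings
#' of single-sphere pseudo-atoms (one residue per ring per subunit, backbone
#' `CA` plus side-chain `CB`); this is geometry, not chemistry — the analysis
#' stack only consumes coordinates, elements and numbering, so chemically
#' valid polypeptides are unnecessary.
#'
#' Defaults mimic a closed cardiac channel: a gate ring whose atom centers sit
#' `gate_center_radius` = 2.44 Angstrom from the axis, which with carbon
#' spheres of vdW 1.70 gives an analytic gate radius of 0.74 Angstrom, the
#' closed-cluster value; `channel_spec(gate_center_radius = 5.1,
#' state_tag = "open")` gives the open-cluster 3.4 Angstrom.
#'
#' @param n_residues_per_subunit rings per subunit (default 41).
#' @param gate_center_radius distance of gate-ring atom centers from the axis
#'   (Angstrom).
#' @param lumen_center_radius wall radius everywhere else (Angstrom).
#' @param gate_residue_number canonical residue number of the gate ring
#'   (default 4867); residues are numbered consecutively with the gate at the
#'   middle ring.
#' @param atom_vdw nominal sphere radius of the pseudo-atoms; atoms are
#'   carbon, so profile radii follow `center_radius - vdw_C`.
#' @param axial_span z extent of each subunit (Angstrom).
#' @param twist_deg helical twist per ring (degrees).
#' @param state_tag `"closed"`, `"open"` or `"unknown"`.
#' @param placement_jitter isotropic Gaussian coordinate noise applied to
#'   every atom (Angstrom, default 0 = exact geometry).
#' @param seed RNG seed; together with the spec it fixes the output exactly.
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(n_residues_per_subunit = 41L,
                         gate_center_radius = 2.44,
                         lumen_center_radius = 6.0,
                         gate_residue_number = 4867L,
                         atom_vdw = 1.70,
                         axial_span = 40,
                         twist_deg = 10,
                         state_tag = "closed",
                         placement_jitter = 0,
                         seed = 1L) {
  if (gate_center_radius <= 0 || lumen_center_radius <= 0)
    stop("ring radii must be positive")
  if (gate_center_radius > lumen_center_radius)
    stop("gate_center_radius must not exceed lumen_center_radius")
  if (n_residues_per_subunit < 3L) stop("need at least 3 residues per subunit")
  structure(list(n_residues_per_subunit = as.integer(n_residues_per_subunit),
                 gate_center_radius = gate_center_radius,
                 lumen_center_radius = lumen_center_radius,
                 gate_residue_number = as.integer(gate_residue_number),
                 atom_vdw = atom_vdw, axial_span = axial_span,
                 twist_deg = twist_deg,
                 state_tag = match.arg(state_tag, c("closed", "open", "unknown")),
                 placement_jitter = placement_jitter,
                 seed = as.integer(seed)),
            class = "channel_spec")
}

#' Generate a toy tetramer channel
#'
#' Builds the [channel_spec()] geometry: four C4-symmetric subunits (chains
#' related by 90 degree rotations about z), rings of `CA`/`CB` carbon
#' pseudo-atoms at the lumen radius, and a gate ring of four residues at the
#' gate radius whose z is the known gate plane.  Output is deterministic
#' under `(spec, seed)`.
#'
#' @param spec a [channel_spec()].
#' @return A [structure_model()] in canonical numbering; attributes
#'   `gate_z` (true gate plane) and `spec` record the construction.
#' @examples
#' m <- make_tetramer(channel_spec(seed = 7))
#' attr(m, "gate_z")
#' @export
make_tetramer <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues_per_subunit
  gate_idx <- (n + 1L) %/% 2L
  z_ring <- seq(-spec$axial_span / 2, spec$axial_span / 2, length.out = n)
  resno <- spec$gate_residue_number - gate_idx + seq_len(n)
  radius <- rep(spec$lumen_center_radius, n)
  radius[gate_idx] <- spec$gate_center_radius
  twist <- spec$twist_deg * pi / 180

  rows <- vector("list", 4L * n)
  k <- 0L
  for (s in 0:3) {
    for (j in seq_len(n)) {
      th <- s * pi / 2 + twist * j
      for (at in c("CA", "CB")) {
        a_th <- th + if (at == "CB") pi / 4 else 0
        k <- k + 1L
        rows[[k]] <- c(s + 1L, resno[j], radius[j] * cos(a_th),
                       radius[j] * sin(a_th), z_ring[j],
                       if (at == "CA") 1L else 2L)
      }
    }
  }
  m <- do.call(rbind, rows)
  atoms <- data.frame(
    serial = seq_len(nrow(m)),
    name = rep(c("CA", "CB"), length.out = nrow(m)),
    element = "C",
    resno = as.integer(m[, 2L]),
    resname = ifelse(m[, 2L] == spec$gate_residue_number, "ILE", "ALA"),
    subunit = as.integer(m[, 1L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    stringsAsFactors = FALSE)
  if (spec$placement_jitter > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = spec$placement_jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = spec$placement_jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = spec$placement_jitter)
  }
  out <- structure_model(atoms, label = paste0("toy-", spec$state_tag),
                         state_tag = spec$state_tag, numbering = "canonical")
  attr(out, "gate_z") <- z_ring[gate_idx]
  attr(out, "spec") <- spec
  out
}

#' Specification of a toy trajectory
#'
#' Frames are the base model plus i.i.d. Gaussian coordinate jitter; in
#' addition, for each scheduled residue pair a designated side-chain atom is
#' placed exactly `contact` Angstrom from its partner in a Bernoulli(p)
#' subset of frames and `apart` Angstrom away otherwise, so the pair's true
#' contact occupancy is known by construction.
#'
#' @param n_frames number of frames.
#' @param jitter_sigma per-coordinate Gaussian jitter (Angstrom).
#' @param contact_schedule list of entries `list(a = c(subunit, resno),
#'   b = c(subunit, resno), p =, contact =, apart =)`; for any intended
#'   cutoff, `contact < cutoff < apart` must hold.
#' @param exact if `TRUE`, the pair is in contact in exactly
#'   `round(p * n_frames)` frames (a seeded random subset) instead of a
#'   Bernoulli draw — useful for placing occupancies exactly on a threshold.
#' @param seed RNG seed.
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 100L, jitter_sigma = 0.1,
                            contact_schedule = list(), exact = FALSE,
                            seed = 1L) {
  for (sc in contact_schedule) {
    if (!all(c("a", "b", "p") %in% names(sc)))
      stop("each schedule entry needs 'a', 'b' and 'p'")
    if (sc$p < 0 || sc$p > 1) stop("schedule p must be in [0, 1]")
  }
  structure(list(n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma,
                 contact_schedule = contact_schedule,
                 exact = isTRUE(exact),
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate a toy trajectory with engineered contact occupancies
#'
#' @param model base [structure_model()], typically from [make_tetramer()].
#' @param spec a [trajectory_spec()].
#' @return A [trajectory_ensemble()]; attribute `true_counts` records, per
#'   schedule entry, the number of frames actually placed in contact.
#' @examples
#' m <- make_tetramer(channel_spec(seed = 1))
#' tr <- make_trajectory(m, trajectory_spec(n_frames = 10, seed = 2))
#' n_frames(tr)
#' @export
make_trajectory <- function(model, spec) {
  stopifnot(inherits(model, "structure_model"), inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  a <- model$atoms
  base <- model_xyz(model)
  sched <- lapply(spec$contact_schedule, function(sc) {
    ia <- which(a$subunit == sc$a[1L] & a$resno == sc$a[2L] & a$name == "CB")
    ib <- which(a$subunit == sc$b[1L] & a$resno == sc$b[2L] & a$name == "CB")
    if (length(ia) != 1L || length(ib) != 1L)
      stop("scheduled residue (subunit ", sc$a[1L], ", ", sc$a[2L],
           ") or (subunit ", sc$b[1L], ", ", sc$b[2L],
           ") lacks a unique CB atom in the model")
    u <- base[ib, ] - base[ia, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) stop("scheduled atoms are coincident")
    list(ia = ia, ib = ib, u = u / nu, p = sc$p,
         contact = if (is.null(sc$contact)) 2.8 else sc$contact,
         apart = if (is.null(sc$apart)) 6.0 else sc$apart)
  })
  moved <- unlist(lapply(sched, function(s) s$ib))
  anchors <- unlist(lapply(sched, function(s) s$ia))
  if (anyDuplicated(c(moved)) || length(intersect(moved, anchors)))
    stop("schedule conflict: the same atom appears in two schedule entries")

  nf <- spec$n_frames
  in_contact <- lapply(sched, function(s) {
    if (spec$exact) {
      k <- round(s$p * nf)
      hits <- rep(FALSE, nf)
      hits[sample.int(nf, k)] <- TRUE
      hits
    } else {
      stats::runif(nf) < s$p
    }
  })
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- base
    if (spec$jitter_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$jitter_sigma),
                          ncol = 3L)
    for (si in seq_along(sched)) {
      s <- sched[[si]]
      d <- if (in_contact[[si]][f]) s$contact else s$apart
      xyz[s$ib, ] <- xyz[s$ia, ] + s$u * d
    }
    frames[[f]] <- xyz
  }
  out <- trajectory_ensemble(model, frames, frame_spacing = 1)
  attr(out, "true_counts") <- vapply(in_contact, sum, integer(1L))
  out
}

#' Construct a mutation catalogue with a known within-k fraction
#'
#' Places exactly `hits` entries within `k` residues of some site and
#' `misses` entries farther than `k` from every site, so
#' `fraction_within[k] = hits / (hits + misses)` by construction — e.g.
#' `hits = 36, misses = 13, k = 5` yields 36/49.
#'
#' @param sites integer vector of site residue numbers.
#' @param hits,misses entry counts to place inside/outside the k-band.
#' @param k the band half-width in residues.
#' @param seed RNG seed for the placements.
#' @return A [mutation_catalogue()]; attribute `true_fraction` records
#'   `hits / (hits + misses)`.
#' @export
make_catalogue <- function(sites, hits, misses, k, seed = 1L) {
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) == 0L) stop("need at least one site")
  if (hits < 0L || misses < 0L || hits + misses < 1L)
    stop("need at least one entry")
  set.seed(seed)
  near <- sort(unique(as.vector(outer(sites, -k:k, "+"))))
  near <- near[near > 0L]
  if (hits > 0L && length(near) < hits)
    stop("cannot place ", hits, " distinct in-band entries around ",
         length(sites), " site(s) with k = ", k)
  picked_hits <- if (hits > 0L) sample(near, hits) else integer(0)
  far_lo <- max(sites) + k + 1L
  candidates <- seq.int(far_lo, far_lo + 10L * (misses + 1L))
  ok <- vapply(candidates, function(r) min(abs(sites - r)) > k, logical(1L))
  candidates <- candidates[ok]
  if (misses > 0L && length(candidates) < misses)
    stop("cannot place ", misses, " out-of-band entries beyond the sites")
  picked_misses <- if (misses > 0L) sample(candidates, misses) else integer(0)
  out <- mutation_catalogue(c(picked_hits, picked_misses),
                            provenance = "synthetic")
  attr(out, "true_fraction") <- hits / (hits + misses)
  out
}

#' Generate an ideal cylindrical channel
#'
#' Rings of carbon pseudo-atoms at a constant wall radius along z — the
#' analytic benchmark for the pore profiler: the axis radius is exactly
#' `ring_radius - vdw` (up to the ring discretization).  An optional
#' constriction narrows one ring to a smaller wall radius.
#'
#' @param ring_radius wall (atom-center) radius, Angstrom.
#' @param n_rings number of rings.
#' @param ring_spacing z spacing of rings, Angstrom.
#' @param atoms_per_ring atoms per ring (spread over 360 degrees and assigned
#'   to quadrant subunits).
#' @param constriction `NULL`, or `list(ring = index, radius = r)` narrowing
#'   that ring's wall to `r`.
#' @param res_start residue number of the first ring.
#' @return A [structure_model()].
#' @export
make_cylinder <- function(ring_radius = 6.0, n_rings = 21L, ring_spacing = 1.0,
                          atoms_per_ring = 8L, constriction = NULL,
                          res_start = 1L) {
  z_ring <- (seq_len(n_rings) - (n_rings + 1L) / 2) * ring_spacing
  wall <- rep(ring_radius, n_rings)
  if (!is.null(constriction)) wall[constriction$ring] <- constriction$radius
  th0 <- (seq_len(atoms_per_ring) - 1L) * 2 * pi / atoms_per_ring
  rows <- do.call(rbind, lapply(seq_len(n_rings), function(j) {
    cbind(j, th0, wall[j] * cos(th0), wall[j] * sin(th0), z_ring[j])
  }))
  atoms <- data.frame(
    serial = seq_len(nrow(rows)),
    name = "CA", element = "C",
    resno = res_start + as.integer(rows[, 1L]) - 1L,
    resname = "ALA",
    subunit = pmin(4L, (as.integer(floor(rows[, 2L] / (pi / 2))) %% 4L) + 1L),
    x = rows[, 3L], y = rows[, 4L], z = rows[, 5L],
    stringsAsFactors = FALSE)
  structure_model(atoms, label = "cylinder", numbering = "canonical")
}
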