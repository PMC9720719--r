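#' Bondi van der Waals radii
#'
#' Default element-to-radius table used by the pore profiler (Angstrom):
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20.  Other profilers ship
#' slightly different tables, so absolute pore radii computed with different
#' software can differ by one or two tenths of an Angstrom; published radii
#' should be treated as approximate anchors rather than exact targets.
#'
#' @return Named numeric vector of radii.
#' @export
bondi_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

#' Pore-radius profile along the channel axis
#'
#' At each z-slab the pore radius is the largest sphere that fits at some
#' in-plane probe center: the maximum over probe positions of (distance to the
#' nearest atom center minus that atom's van der Waals radius), clamped at 0.
#' The maximization is deterministic — a vectorized coarse grid around a seed
#' point followed by Nelder-Mead refinement — and each slab is seeded from the
#' previous slab's optimal center, so the probe tracks the pore through
#' off-axis wanderings without a random number stream.  The profile extends in
#' both directions from the starting slab until the radius exceeds
#' `cutoff_radius` (the samples beyond the cutoff are not kept), which bounds
#' the extent of the channel pore.
#'
#' The channel axis is taken as laboratory z (the membrane normal in a
#' standard membrane-embedded setup); re-orient the model first if needed.
#'
#' @param model a [structure_model()]; hydrogens are excluded internally.
#' @param step slab spacing in Angstrom (default 0.25).
#' @param cutoff_radius profile termination radius in Angstrom (default 10;
#'   12 suits widely dilated pores whose radius passes 10 inside the channel).
#' @param radius_set named element-to-vdW-radius table, default
#'   [bondi_radii()]; elements missing from the table fall back to 1.70.
#' @param z_start starting slab (default: median atom z).
#' @param seed_xy starting in-plane probe seed (default: centroid of atoms
#'   within 5 Angstrom of the starting slab).
#' @param search_halfwidth half-width of the coarse search grid around the
#'   seed, Angstrom.
#' @return An object of class `pore_profile`: data frame `samples` with
#'   columns `z` (strictly increasing) and `radius` (>= 0), plus the
#'   parameters and per-sample probe centers.
#' @examples
#' m <- make_tetramer(channel_spec(seed = 1))
#' p <- compute_profile(m, step = 0.5)
#' min(p$samples$radius)
#' @export
compute_profile <- function(model, step = 0.25, cutoff_radius = 10,
                            radius_set = bondi_radii(), z_start = NULL,
                            seed_xy = NULL, search_halfwidth = 2.0) {
  hm <- heavy_atoms(model)
  xyz <- model_xyz(hm)
  vdw <- unname(radius_set[hm$atoms$element])
  vdw[is.na(vdw)] <- 1.70
  if (is.null(z_start)) z_start <- stats::median(xyz[, 3L])
  if (is.null(seed_xy)) {
    near <- abs(xyz[, 3L] - z_start) <= 5
    if (!any(near)) near <- rep(TRUE, nrow(xyz))
    seed_xy <- colMeans(xyz[near, 1:2, drop = FALSE])
  }
  zmin <- min(xyz[, 3L]) - 2
  zmax <- max(xyz[, 3L]) + 2

  first <- .slab_radius(xyz, vdw, z_start, seed_xy, cutoff_radius,
                        search_halfwidth, step)
  if (is.null(first))
    stop("no atoms within search range of the starting slab at z = ",
         format(z_start))
  if (first$radius > cutoff_radius)
    stop("starting slab radius ", format(first$radius),
         " already exceeds the cutoff radius; choose z_start inside the pore")

  sweep_dir <- function(dir) {
    zs <- numeric(0); rs <- numeric(0); cx <- numeric(0); cy <- numeric(0)
    seed <- first$center
    z <- z_start + dir * step
    while (z >= zmin && z <= zmax) {
      sl <- .slab_radius(xyz, vdw, z, seed, cutoff_radius,
                         search_halfwidth, step)
      if (is.null(sl) || sl$radius > cutoff_radius) break
      zs <- c(zs, z); rs <- c(rs, sl$radius)
      cx <- c(cx, sl$center[1L]); cy <- c(cy, sl$center[2L])
      seed <- sl$center
      z <- z + dir * step
    }
    data.frame(z = zs, radius = rs, cx = cx, cy = cy)
  }

  up <- sweep_dir(+1)
  down <- sweep_dir(-1)
  mid <- data.frame(z = z_start, radius = first$radius,
                    cx = first$center[1L], cy = first$center[2L])
  samples <- rbind(down[rev(seq_len(nrow(down))), , drop = FALSE], mid, up)
  rownames(samples) <- NULL
  structure(list(samples = samples[, c("z", "radius")],
                 centers = samples[, c("z", "cx", "cy")],
                 gate_z_raw = NA_real_, orientation = +1L,
                 cutoff_radius = cutoff_radius, step = step),
            class = "pore_profile")
}

# largest probe sphere in one z-slab; NULL when no atoms are in range
.slab_radius <- function(xyz, vdw, z, seed, cutoff, halfwidth, step) {
  margin <- cutoff + max(vdw) + 2 * halfwidth
  keep <- abs(xyz[, 3L] - z) <= margin
  if (!any(keep)) return(NULL)
  A <- xyz[keep, , drop = FALSE]
  r <- vdw[keep]
  dz2 <- (A[, 3L] - z)^2
  f_grid <- function(px, py) {
    # min over atoms of 3-D distance minus vdw, vectorized over probe points
    d2 <- outer(px^2 + py^2, rowSums(A[, 1:2, drop = FALSE]^2) + dz2, "+") -
      2 * (outer(px, A[, 1L]) + outer(py, A[, 2L]))
    do.call(pmin, as.data.frame(sweep(sqrt(pmax(d2, 0)), 2L, r)))
  }
  g <- seq(-halfwidth, halfwidth, by = min(step, 0.25))
  pts <- expand.grid(px = seed[1L] + g, py = seed[2L] + g)
  vals <- f_grid(pts$px, pts$py)
  best <- which.max(vals)
  f_one <- function(p) {
    d <- sqrt((A[, 1L] - p[1L])^2 + (A[, 2L] - p[2L])^2 + dz2)
    min(d - r)
  }
  opt <- stats::optim(c(pts$px[best], pts$py[best]), f_one,
                      control = list(fnscale = -1, maxit = 200, reltol = 1e-10))
  if (opt$value >= vals[best]) {
    center <- opt$par
    val <- opt$value
  } else {
    center <- c(pts$px[best], pts$py[best])
    val <- vals[best]
  }
  list(radius = max(val, 0), center = if (val > 0) center else seed)
}

#' Locate the hydrophobic gate along z
#'
#' The gate plane is the z of the centroid of the four gate residues'
#' side-chain heavy atoms (the constriction formed by the four I4867 residues
#' in RyR2).  All four subunits must carry the gate residue.
#'
#' @param model a [structure_model()] in canonical numbering.
#' @param gate_residue canonical residue number of the gate (default 4867).
#' @return `gate_z_raw`, the gate z in the model's frame (Angstrom).
#' @export
locate_gate <- function(model, gate_residue = 4867) {
  stopifnot(inherits(model, "structure_model"))
  a <- heavy_atoms(model)$atoms
  sel <- a$resno == gate_residue
  have <- sort(unique(a$subunit[sel]))
  if (!identical(have, 1:4))
    stop("gate residue ", gate_residue, " missing on subunit(s) ",
         paste(setdiff(1:4, have), collapse = ", "))
  side <- sel & !a$name %in% c("N", "CA", "C", "O", "OXT")
  if (!any(side)) side <- sel  # glycine-like gate: fall back to all heavy atoms
  mean(a$z[side])
}

#' Anchor a pore profile at the gate
#'
#' Shifts the z origin so the hydrophobic gate sits at z = 0 and flips the
#' axis if needed so that positive z is the luminal side (declared per input
#' structure; auto-detection from coordinates alone is unreliable).
#'
#' @param profile a [pore_profile()] computed on the same model used for
#'   [locate_gate()].
#' @param gate_z_raw gate z from [locate_gate()].
#' @param orientation `+1` if positive raw z is already luminal, `-1` to flip.
#' @return The normalized `pore_profile` (z strictly increasing, gate at 0).
#' @export
normalize_profile <- function(profile, gate_z_raw, orientation = +1L) {
  stopifnot(inherits(profile, "pore_profile"), orientation %in% c(-1L, 1L))
  profile$samples$z <- orientation * (profile$samples$z - gate_z_raw)
  profile$centers$z <- orientation * (profile$centers$z - gate_z_raw)
  if (orientation < 0) {
    profile$samples <- profile$samples[rev(seq_len(nrow(profile$samples))), ]
    profile$centers <- profile$centers[rev(seq_len(nrow(profile$centers))), ]
    rownames(profile$samples) <- rownames(profile$centers) <- NULL
  }
  profile$gate_z_raw <- gate_z_raw
  profile$orientation <- as.integer(orientation)
  profile
}

#' @export
print.pore_profile <- function(x, ...) {
  s <- x$samples
  cat(sprintf("pore_profile: %d samples, z in [%.2f, %.2f] A (step %.2f), min radius %.2f A\n",
              nrow(s), min(s$z), max(s$z), x$step, min(s$radius)))
  if (!is.na(x$gate_z_raw)) cat("  gate-anchored (gate at z = 0)\n")
  invisible(x)
}

#' Call the gating state from a normalized profile
#'
#' The gate radius is read at the sample nearest z = 0; because a discrete
#' profile may place its local constriction a sample or two off the anchored
#' origin, the minimum radius within 2 Angstrom of the gate is also reported
#' (`gate_radius_local_min`).  The state is decided solely by the gate radius
#' against `threshold`: closed channels cluster well below ~1 Angstrom and
#' open ones at 2 Angstrom and above, so the default threshold of 1.5 splits
#' the clusters; radii exactly at the threshold are called open.
#'
#' @param profile a gate-anchored [normalize_profile()] output.
#' @param threshold open/closed decision boundary in Angstrom (default 1.5).
#' @return A list of class `gate_call`: `gate_radius`, `gate_radius_local_min`,
#'   `min_radius`, `min_z`, `state`.
#' @export
call_state <- function(profile, threshold = 1.5) {
  stopifnot(inherits(profile, "pore_profile"))
  if (is.na(profile$gate_z_raw))
    stop("profile is not gate-anchored; run normalize_profile() first")
  s <- profile$samples
  if (min(s$z) > 0 || max(s$z) < 0)
    stop("z = 0 lies outside the profile support [",
         format(min(s$z)), ", ", format(max(s$z)), "]")
  i_gate <- which.min(abs(s$z))
  near <- abs(s$z) <= 2
  i_min <- which.min(s$radius)
  structure(list(
    gate_radius = s$radius[i_gate],
    gate_radius_local_min = min(s$radius[near]),
    min_radius = s$radius[i_min],
    min_z = s$z[i_min],
    state = if (s$radius[i_gate] < threshold) "closed" else "open",
    threshold = threshold
  ), class = "gate_call")
}

#' @export
print.gate_call <- function(x, ...) {
  cat(sprintf("gate_call: %s (gate %.2f A, local min %.2f A, profile min %.2f A at z %.2f)\n",
              x$state, x$gate_radius, x$gate_radius_local_min,
              x$min_radius, x$min_z))
  invisible(x)
}
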