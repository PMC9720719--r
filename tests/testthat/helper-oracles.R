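# Independent brute-force oracles used to validate the fast implementations.

# Largest probe sphere in a z-slab by exhaustive 2-D grid search (3-D atom
# distances), independent of the profiler's seeded local search.
slab_grid_oracle <- function(model, z, radius_set = bondi_radii(),
                             halfwidth = 3, grid = 0.05, center = c(0, 0)) {
  hm <- heavy_atoms(model)
  xyz <- model_xyz(hm)
  vdw <- unname(radius_set[hm$atoms$element])
  vdw[is.na(vdw)] <- 1.70
  g <- seq(-halfwidth, halfwidth, by = grid)
  px <- rep(center[1] + g, times = length(g))
  py <- rep(center[2] + g, each = length(g))
  dz2 <- (xyz[, 3] - z)^2
  best <- -Inf
  for (chunk in split(seq_along(px), ceiling(seq_along(px) / 5000))) {
    d2 <- outer(px[chunk]^2 + py[chunk]^2, rowSums(xyz[, 1:2]^2) + dz2, "+") -
      2 * (outer(px[chunk], xyz[, 1]) + outer(py[chunk], xyz[, 2]))
    f <- apply(sweep(sqrt(pmax(d2, 0)), 2, vdw), 1, min)
    best <- max(best, max(f))
  }
  max(best, 0)
}

# Residue-pair contact detection by explicit per-pair minimum distances,
# looping over residue blocks (independent of the vectorized atom-matrix
# route in frame_contacts).
naive_contacts <- function(model, cutoff = 3.0, exclude_within = 2L) {
  a <- heavy_atoms(model)$atoms
  res <- unique(a[, c("subunit", "resno")])
  res <- res[order(res$subunit, res$resno), , drop = FALSE]
  blocks <- lapply(seq_len(nrow(res)), function(i)
    as.matrix(a[a$subunit == res$subunit[i] & a$resno == res$resno[i],
                c("x", "y", "z"), drop = FALSE]))
  keys <- character(0)
  dists <- numeric(0)
  for (i in seq_len(nrow(res) - 1L)) {
    for (j in (i + 1L):nrow(res)) {
      if (res$subunit[i] == res$subunit[j] &&
          abs(res$resno[i] - res$resno[j]) <= exclude_within) next
      d2 <- outer(rowSums(blocks[[i]]^2), rowSums(blocks[[j]]^2), "+") -
        2 * tcrossprod(blocks[[i]], blocks[[j]])
      dmin <- sqrt(max(min(d2), 0))
      if (dmin <= cutoff + 1e-12) {
        keys <- c(keys, paste(res$subunit[i], res$resno[i],
                              res$subunit[j], res$resno[j]))
        dists <- c(dists, dmin)
      }
    }
  }
  data.frame(key = keys, min_distance = dists, stringsAsFactors = FALSE)
}

# random multi-residue frame: 4 subunits, n_res residues each, atoms_per_res
# atoms scattered in a box; optionally with hydrogens
random_frame <- function(n_res = 25L, atoms_per_res = 5L, box = 20,
                         with_h = FALSE, seed = 1L) {
  set.seed(seed)
  n <- 4L * n_res * atoms_per_res
  atoms <- data.frame(
    serial = seq_len(n),
    name = rep(c("N", "CA", "C", "O", "CB")[seq_len(atoms_per_res)],
               times = 4L * n_res),
    element = rep(c("N", "C", "C", "O", "C")[seq_len(atoms_per_res)],
                  times = 4L * n_res),
    resno = rep(rep(seq_len(n_res) + 100L, each = atoms_per_res), times = 4L),
    resname = "ALA",
    subunit = rep(1:4, each = n_res * atoms_per_res),
    x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
    z = stats::runif(n, 0, box),
    stringsAsFactors = FALSE)
  if (with_h) {
    h <- atoms[atoms$name == "CA", ]
    h$name <- "HA"
    h$element <- "H"
    h$serial <- h$serial + n
    # park each hydrogen right next to a random other residue's CA
    h$x <- h$x + stats::runif(nrow(h), -0.3, 0.3)
    atoms <- rbind(atoms, h)
  }
  structure_model(atoms, label = "random", numbering = "canonical")
}

# small closed/open toy pair used across tests
toy_closed <- function(seed = 1L, jitter = 0)
  make_tetramer(channel_spec(n_residues_per_subunit = 21L, axial_span = 20,
                             gate_center_radius = 2.44, state_tag = "closed",
                             placement_jitter = jitter, seed = seed))

toy_open <- function(seed = 1L, jitter = 0)
  make_tetramer(channel_spec(n_residues_per_subunit = 21L, axial_span = 20,
                             gate_center_radius = 5.1, state_tag = "open",
                             placement_jitter = jitter, seed = seed))

gate_call_of <- function(model, step = 0.5, ...) {
  p <- compute_profile(model, step = step, ...)
  call_state(normalize_profile(p, locate_gate(model)))
}
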