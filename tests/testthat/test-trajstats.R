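rigid_frames <- function(base_xyz, n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    if (k == 1) return(base_xyz)
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    sweep(base_xyz %*% R, 2, stats::rnorm(3, sd = 5), "+")
  })
}

test_that("identical and rigidly transformed frames give zero RMSD", {
  m <- toy_closed(seed = 1)
  same <- trajectory_ensemble(m, rep(list(model_xyz(m)), 5))
  expect_equal(rmsd_timeseries(same)$rmsd, rep(0, 5))
  tr <- trajectory_ensemble(m, rigid_frames(model_xyz(m), 6, seed = 2))
  ts <- rmsd_timeseries(tr)
  expect_equal(ts$rmsd, rep(0, 6), tolerance = 1e-9)
  expect_identical(ts$rmsd[1], 0)
})

test_that("jittered frames reproduce the Monte-Carlo RMSD expectation", {
  # frames = base + iid N(0, sigma^2) per coordinate; after fitting many
  # atoms, RMSD to the unjittered first frame approaches sigma * sqrt(3)
  set.seed(3)
  n_atoms <- 1000
  sigma <- 0.5
  base <- matrix(stats::runif(3 * n_atoms, 0, 50), ncol = 3)
  atoms <- data.frame(serial = 1:n_atoms, name = "CA", element = "C",
                      resno = 1:n_atoms, resname = "ALA", subunit = 1L,
                      x = base[, 1], y = base[, 2], z = base[, 3])
  m <- structure_model(atoms, numbering = "canonical")
  frames <- c(list(base), lapply(1:40, function(k)
    base + matrix(stats::rnorm(3 * n_atoms, sd = sigma), ncol = 3)))
  ts <- rmsd_timeseries(trajectory_ensemble(m, frames))
  expect_equal(mean(ts$rmsd[-1]), sigma * sqrt(3), tolerance = 0.02)
})

test_that("rmsd_timeseries rejects an empty selection", {
  m <- toy_closed(seed = 1)
  tr <- trajectory_ensemble(m, rep(list(model_xyz(m)), 2))
  expect_error(rmsd_timeseries(tr, atom_names = "ZZ"), "empty")
})

test_that("averaging rigid-transform frames recovers the source model", {
  m <- toy_closed(seed = 4)
  tr <- trajectory_ensemble(m, rigid_frames(model_xyz(m), 8, seed = 5))
  avg <- average_structure(tr, last_n = 8)
  # the average equals the first retained frame's pose of the source model
  expect_equal(model_xyz(avg), tr$frames[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
  same <- trajectory_ensemble(m, rep(list(model_xyz(m)), 4))
  expect_equal(model_xyz(average_structure(same, 3)), model_xyz(m),
               ignore_attr = TRUE)
  expect_error(average_structure(tr, 0), "at least 1")
  expect_error(average_structure(tr, 9), "exceeds")
})

test_that("only the trailing window enters the average", {
  m <- toy_closed(seed = 6)
  garbage <- model_xyz(m) + 100
  frames <- c(rep(list(garbage), 20), rep(list(model_xyz(m)), 10))
  avg <- average_structure(trajectory_ensemble(m, frames), last_n = 10)
  expect_equal(model_xyz(avg), model_xyz(m), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("averaging commutes with a global rigid transform of every frame", {
  m <- toy_closed(seed = 7)
  tr <- make_trajectory(m, trajectory_spec(n_frames = 6, jitter_sigma = 0.2,
                                           seed = 8))
  avg <- average_structure(tr, 6)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- trajectory_ensemble(m, lapply(tr$frames, function(f)
    sweep(f %*% R, 2, c(3, -1, 2), "+")))
  avg_moved <- average_structure(moved, 6)
  expect_equal(model_xyz(avg_moved),
               sweep(model_xyz(avg) %*% R, 2, c(3, -1, 2), "+"),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("substructure RMSD of a model against itself is zero", {
  m <- toy_closed(seed = 9)
  r <- residue_region("mid", c(4862, 4872))
  sr <- substructure_rmsd(m, m, r)
  expect_equal(sr$rmsd, 0, tolerance = 1e-9)
})

test_that("a single displaced subunit gives the hand-computed RMSD", {
  m <- toy_closed(seed = 10)
  r <- residue_region("mid", c(4862, 4872))
  a <- m$atoms
  move <- a$subunit == 3
  a$x[move] <- a$x[move] + 2
  ref <- structure_model(a, numbering = "canonical")
  sr <- substructure_rmsd(m, ref, r)
  # anchored on an unmoved subunit: 1 of 4 subunits deviates by 2 A rigidly,
  # so RMSD = sqrt(4/4) = 2/sqrt(4)
  expect_equal(sr$rmsd, 1.0, tolerance = 1e-6)
})

test_that("the 16-pairing minimum matches brute force and is symmetric", {
  m1 <- toy_closed(seed = 11, jitter = 0.3)
  m2 <- toy_open(seed = 12, jitter = 0.3)
  r <- residue_region("win", c(4860, 4874))
  sr <- substructure_rmsd(m1, m2, r)
  # brute force: recompute every pairing from scratch with the public API
  get_ca <- function(m, s) {
    a <- extract_regions(m, r)$atoms
    a <- a[a$subunit == s & a$name == "CA", ]
    as.matrix(a[order(a$resno), c("x", "y", "z")])
  }
  M <- lapply(1:4, get_ca, m = m1)
  Rf <- lapply(1:4, get_ca, m = m2)
  brute <- Inf
  for (i in 1:4) for (j in 1:4) {
    sp <- superpose(
      structure_model(within(extract_regions(m1, r)$atoms[
        extract_regions(m1, r)$atoms$subunit == i, ], subunit <- 1),
        numbering = "canonical"),
      structure_model(within(extract_regions(m2, r)$atoms[
        extract_regions(m2, r)$atoms$subunit == j, ], subunit <- 1),
        numbering = "canonical"))
    dev2 <- 0; npt <- 0
    for (k in 0:3) {
      mi <- ((i - 1 + k) %% 4) + 1
      rj <- ((j - 1 + k) %% 4) + 1
      d <- sweep(M[[mi]] %*% sp$rotation, 2, sp$translation, "+") - Rf[[rj]]
      dev2 <- dev2 + sum(d^2); npt <- npt + nrow(d)
    }
    brute <- min(brute, sqrt(dev2 / npt))
  }
  expect_equal(sr$rmsd, brute, tolerance = 1e-9)
  expect_equal(substructure_rmsd(m2, m1, r)$rmsd, sr$rmsd, tolerance = 1e-9)
})

test_that("region absent from a subunit is a hard error", {
  m <- toy_closed(seed = 13)
  a <- m$atoms[!(m$atoms$subunit == 2 & m$atoms$resno >= 4870), ]
  holed <- structure_model(a, numbering = "canonical")
  expect_error(substructure_rmsd(holed, m, residue_region("tail", c(4871, 4875))),
               "subunit 2")
})
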