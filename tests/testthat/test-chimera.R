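rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
}

test_that("superposing a subunit onto itself is the identity transform", {
  s <- get_subunit(toy_closed(seed = 1), 1)
  sp <- superpose(s, s)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
})

test_that("a known rigid transform is recovered exactly", {
  s <- get_subunit(toy_closed(seed = 2), 1)
  moved <- set_model_xyz(s, sweep(model_xyz(s) %*% rot_z(37), 2, c(1, 2, 3), "+"))
  sp <- superpose(moved, s)
  expect_equal(sp$rmsd, 0, tolerance = 1e-6)
  expect_equal(model_xyz(apply_transform(moved, sp)), model_xyz(s),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
})

test_that("superposition rmsd is symmetric and translation-invariant", {
  set.seed(5)
  s1 <- get_subunit(toy_closed(seed = 5, jitter = 0.3), 1)
  s2 <- get_subunit(toy_closed(seed = 6, jitter = 0.3), 1)
  r12 <- superpose(s1, s2)$rmsd
  r21 <- superpose(s2, s1)$rmsd
  expect_equal(r12, r21, tolerance = 1e-9)
  shifted <- set_model_xyz(s1, sweep(model_xyz(s1), 2, c(100, -50, 7), "+"))
  expect_equal(superpose(shifted, s2)$rmsd, r12, tolerance = 1e-9)
  expect_error(superpose(extract_regions(s1, residue_region("tiny", c(4857, 4858))),
                         s2),
               "fewer than 3")
})

test_that("rmsd after fitting matches an independent aligner", {
  skip_if_not_installed("bio3d")
  s1 <- get_subunit(toy_closed(seed = 7, jitter = 0.4), 1)
  s2 <- get_subunit(toy_closed(seed = 8, jitter = 0.4), 1)
  ours <- superpose(s1, s2)$rmsd
  ca1 <- as.vector(t(model_xyz(s1)[s1$atoms$name == "CA", ]))
  ca2 <- as.vector(t(model_xyz(s2)[s2$atoms$name == "CA", ]))
  theirs <- bio3d::rmsd(ca2, ca1, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("pruned refits never report a larger rmsd than the full fit", {
  s1 <- get_subunit(toy_closed(seed = 9, jitter = 0.5), 1)
  s2 <- get_subunit(toy_closed(seed = 10, jitter = 0.5), 1)
  full <- superpose(s1, s2)
  pruned <- superpose(s1, s2, prune = TRUE)
  expect_lte(pruned$rmsd, full$rmsd + 1e-12)
  expect_lte(pruned$n_matched, full$n_matched)
  expect_gte(pruned$rmsd_all, pruned$rmsd)
})

test_that("whole-subunit substitution replaces exactly the target subunit", {
  closed <- toy_closed(seed = 1)
  open <- toy_open(seed = 2)
  ch <- build_chimera(open, closed, target_subunit = 1, label = "1C3O")
  out <- ch$model
  for (s in 2:4)
    expect_equal(model_xyz(get_subunit(out, s)),
                 model_xyz(get_subunit(open, s)), ignore_attr = TRUE)
  donor_fit <- apply_transform(get_subunit(closed, 1), ch$superposition)
  expect_equal(model_xyz(get_subunit(out, 1)), model_xyz(donor_fit),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nrow(out$atoms), nrow(open$atoms))
  expect_equal(out$atoms$serial, seq_len(nrow(out$atoms)))
})

test_that("segment substitution changes exactly the scoped residues", {
  closed <- toy_closed(seed = 3)
  open <- toy_open(seed = 4)
  seg <- residue_region("gate-seg", c(4862, 4872))
  ch <- build_chimera(closed, open, target_subunit = 1, scope = seg)
  out <- ch$model
  a1 <- get_subunit(closed, 1)$atoms
  o1 <- get_subunit(out, 1)$atoms
  in_seg <- region_contains(seg, a1$resno)
  expect_equal(as.matrix(o1[!region_contains(seg, o1$resno), c("x", "y", "z")]),
               as.matrix(a1[!in_seg, c("x", "y", "z")]), ignore_attr = TRUE)
  moved <- as.matrix(o1[region_contains(seg, o1$resno), c("x", "y", "z")]) -
    as.matrix(a1[in_seg, c("x", "y", "z")])
  expect_gt(max(abs(moved)), 0.5)  # the gate segment really changed
  expect_equal(ch$n_replaced_residues, 11)
})

test_that("full-residue-set scope is equivalent to a whole-subunit swap", {
  closed <- toy_closed(seed = 5)
  open <- toy_open(seed = 6)
  whole <- build_chimera(open, closed, 1)$model
  allres <- residue_region("all", range(closed$atoms$resno))
  scoped <- build_chimera(open, closed, 1, scope = allres)$model
  expect_equal(model_xyz(whole), model_xyz(scoped), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("substitution is idempotent and conserves atom counts", {
  closed <- toy_closed(seed = 7)
  open <- toy_open(seed = 8)
  once <- build_chimera(open, closed, 1)$model
  twice <- build_chimera(once, closed, 1)$model
  expect_equal(model_xyz(twice), model_xyz(once), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(nrow(once$atoms), nrow(open$atoms))
})

test_that("scope residues missing from the donor are reported by number", {
  closed <- toy_closed(seed = 9)
  open <- toy_open(seed = 10)
  expect_error(build_chimera(open, closed, 1,
                             scope = residue_region("ghost", c(5000, 5005))),
               "5000")
})

test_that("clash detection finds planted near-contacts and nothing else", {
  m <- toy_closed(seed = 11)
  expect_equal(nrow(clash_check(m, 1.0)), 0)
  # plant two heavy atoms 0.5 apart in different residues
  a <- m$atoms
  a$x[a$subunit == 1 & a$resno == 4858 & a$name == "CA"] <- 0
  a$y[a$subunit == 1 & a$resno == 4858 & a$name == "CA"] <- 0
  a$x[a$subunit == 2 & a$resno == 4876 & a$name == "CA"] <- 0.5
  a$y[a$subunit == 2 & a$resno == 4876 & a$name == "CA"] <- 0
  a$z[a$subunit == 1 & a$resno == 4858 & a$name == "CA"] <- 0
  a$z[a$subunit == 2 & a$resno == 4876 & a$name == "CA"] <- 0
  planted <- structure_model(a, numbering = "canonical")
  cl <- clash_check(planted, 1.0)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$distance, 0.5, tolerance = 1e-9)
  # a chimera of two lightly jittered copies of the same tetramer stays clash-free
  ch <- build_chimera(toy_closed(seed = 12, jitter = 0.05),
                      toy_closed(seed = 13, jitter = 0.05), 1)
  expect_equal(nrow(clash_check(ch$model, 1.0)), 0)
})
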