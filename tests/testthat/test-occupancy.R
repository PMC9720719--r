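two_residue_model <- function(gap, h_dist = NULL) {
  atoms <- data.frame(
    serial = 1:2, name = "CB", element = "C",
    resno = c(100L, 200L), resname = c("ASN", "ASP"), subunit = c(1L, 2L),
    x = c(0, gap), y = 0, z = 0, stringsAsFactors = FALSE)
  if (!is.null(h_dist)) {
    atoms <- rbind(atoms, data.frame(
      serial = 3L, name = "HB", element = "H", resno = 100L, resname = "ASN",
      subunit = 1L, x = h_dist, y = 0, z = 0))
  }
  structure_model(atoms, numbering = "canonical")
}

test_that("the 3.0 A heavy-atom cutoff is inclusive and ignores hydrogens", {
  expect_equal(nrow(frame_contacts(two_residue_model(2.9))), 1)
  expect_equal(nrow(frame_contacts(two_residue_model(3.0))), 1)
  expect_equal(nrow(frame_contacts(two_residue_model(3.1))), 0)
  # hydrogen 1.0 A from the partner residue while heavies sit 4 A apart
  m <- two_residue_model(4.0, h_dist = 3.0)
  expect_equal(nrow(frame_contacts(m)), 0)
})

test_that("contact events are canonically ordered and unduplicated", {
  set.seed(14)
  m <- random_frame(n_res = 15, seed = 14)
  ev <- frame_contacts(m, cutoff = 4.0)
  expect_true(all(ev$subunit_a < ev$subunit_b |
                    (ev$subunit_a == ev$subunit_b & ev$res_a < ev$res_b)))
  key <- paste(ev$subunit_a, ev$res_a, ev$subunit_b, ev$res_b)
  rkey <- paste(ev$subunit_b, ev$res_b, ev$subunit_a, ev$res_a)
  expect_false(any(duplicated(key)))
  expect_equal(length(intersect(key, rkey)), 0)
})

test_that("vectorized contact detection equals the per-pair oracle", {
  for (seed in 1:20) {
    m <- random_frame(n_res = 12, seed = seed, with_h = (seed %% 2 == 0))
    ev <- frame_contacts(m, cutoff = 3.0)
    key <- paste(ev$subunit_a, ev$res_a, ev$subunit_b, ev$res_b)
    oracle <- naive_contacts(m, cutoff = 3.0)
    expect_setequal(key, oracle$key)
    expect_equal(ev$min_distance[match(oracle$key, key)], oracle$min_distance,
                 tolerance = 1e-9)
  }
})

test_that("scope and partner scope restrict pairs and drop intra-scope pairs", {
  m <- toy_closed(seed = 15)
  scope <- residue_region("probe", c(4866, 4868))
  ev_all <- frame_contacts(m, cutoff = 8.0)
  ev_sc <- frame_contacts(m, cutoff = 8.0, scope = scope,
                          partner_scope = scope)
  expect_true(all(region_contains(scope, ev_sc$res_a)))
  expect_true(all(region_contains(scope, ev_sc$res_b)))
  # same-subunit pairs entirely inside the scope are excluded
  expect_true(all(ev_sc$subunit_a != ev_sc$subunit_b))
  expect_lt(nrow(ev_sc), nrow(ev_all))
})

test_that("occupancy is the fraction of frames with the contact present", {
  m <- toy_closed(seed = 16)
  sched <- list(list(a = c(1, 4860), b = c(2, 4860), p = 0.4))
  tr <- make_trajectory(m, trajectory_spec(n_frames = 100, jitter_sigma = 0.05,
                                           contact_schedule = sched,
                                           exact = TRUE, seed = 17))
  expect_equal(attr(tr, "true_counts"), 40L)
  occ <- occupancy_table(tr, system = "toy",
                         scope = residue_region("s", c(4860, 4860)))
  hit <- occ[occ$subunit_a == 1 & occ$subunit_b == 2 & occ$res_a == 4860, ]
  expect_equal(hit$occupancy, 0.40)
  expect_equal(hit$locality, "inter")
  # an always-on pair reports exactly 1.0
  tr1 <- make_trajectory(m, trajectory_spec(n_frames = 20, jitter_sigma = 0.05,
    contact_schedule = list(list(a = c(1, 4860), b = c(2, 4860), p = 1.0)),
    seed = 18))
  occ1 <- occupancy_table(tr1, scope = residue_region("s", c(4860, 4860)))
  expect_equal(occ1$occupancy[occ1$subunit_a == 1 & occ1$subunit_b == 2 &
                                occ1$res_a == 4860 & occ1$res_b == 4860], 1.0)
})

test_that("the window argument restricts analysis to trailing frames", {
  m <- toy_closed(seed = 19)
  sched <- list(list(a = c(1, 4860), b = c(2, 4860), p = 1.0))
  tr_on <- make_trajectory(m, trajectory_spec(n_frames = 10, jitter_sigma = 0,
                                              contact_schedule = sched, seed = 1))
  tr_off <- make_trajectory(m, trajectory_spec(n_frames = 10, jitter_sigma = 0,
    contact_schedule = list(list(a = c(1, 4860), b = c(2, 4860), p = 0)),
    seed = 1))
  mixed <- trajectory_ensemble(m, c(tr_off$frames[1:5], tr_on$frames[6:10]))
  pick <- function(o) o$occupancy[o$subunit_a == 1 & o$subunit_b == 2 &
                                    o$res_a == 4860 & o$res_b == 4860]
  occ <- occupancy_table(mixed, window = 5,
                         scope = residue_region("s", c(4860, 4860)))
  expect_equal(pick(occ), 1.0)
  occ_all <- occupancy_table(mixed,
                             scope = residue_region("s", c(4860, 4860)))
  expect_equal(pick(occ_all), 0.5)
  expect_error(occupancy_table(mixed, window = 11), "between 1 and")
})

test_that("the high-occupancy filter keeps the inclusive 30% boundary", {
  recs <- data.frame(occupancy = c(0.30, 0.29, 0.31, 1.0, 0.299999))
  kept <- filter_high_occupancy(recs)
  expect_equal(kept$occupancy, c(0.30, 0.31, 1.0))
  expect_equal(nrow(filter_high_occupancy(recs[0, , drop = FALSE])), 0)
})

test_that("pooled summaries count by the requested residue role", {
  rec <- function(sa, ra, sb, rb, occ = 0.5, src_s = sa, src_r = ra)
    data.frame(subunit_a = sa, res_a = ra, name_a = "X",
               subunit_b = sb, res_b = rb, name_b = "Y",
               occupancy = occ,
               locality = ifelse(sa == sb, "intra", "inter"),
               source_subunit = src_s, source_res = src_r)
  sys1 <- rbind(rec(1, 4763, 1, 4868), rec(1, 4763, 2, 4874))
  sys2 <- rbind(rec(1, 4763, 1, 4868))
  pools <- list(closed = c("sysA", "sysB"))
  src <- summarize_counts(list(sysA = sys1, sysB = sys2), pools, mode = "source")
  expect_equal(src$count[src$residue == 4763], 3)
  expect_equal(sum(src$count), nrow(sys1) + nrow(sys2))
  par <- summarize_counts(list(sysA = sys1, sysB = sys2), pools, mode = "partner")
  expect_equal(par$count[par$residue == 4868], 2)
  expect_equal(par$count[par$residue == 4874], 1)
  inter <- summarize_counts(list(sysA = sys1, sysB = sys2), pools,
                            mode = "interface")
  # only the inter-subunit record contributes, both of its residues counted
  expect_setequal(inter$residue, c(4763, 4874))
  expect_equal(inter$count, c(1, 1))
})

test_that("the minimum-appearances rule keeps a residue if any pool reaches it", {
  rec <- function(res_b, sys) data.frame(
    subunit_a = 1, res_a = 4763, name_a = "X", subunit_b = 2, res_b = res_b,
    name_b = "Y", occupancy = 0.5, locality = "inter",
    source_subunit = 1, source_res = 4763)
  closed_recs <- do.call(rbind, rep(list(rec(4874)), 2))   # residue seen twice
  open_recs <- do.call(rbind, rep(list(rec(4874)), 3))     # and three times
  out <- summarize_counts(list(c1 = closed_recs, o1 = open_recs),
                          pools = list(closed = "c1", open = "o1"),
                          mode = "interface", min_appearances = 3)
  # 4874 retained (open pool reaches 3); 4763 counts: closed 2, open 3 -> kept
  expect_true(all(c(4763, 4874) %in% out$residue))
  out2 <- summarize_counts(list(c1 = closed_recs),
                           pools = list(closed = "c1", open = character()),
                           mode = "interface", min_appearances = 3)
  expect_equal(nrow(out2), 0)
})

test_that("pooling four subunits over three systems accumulates counts", {
  mk <- function() do.call(rbind, lapply(1:4, function(s) data.frame(
    subunit_a = s, res_a = 4763, name_a = "ASN",
    subunit_b = (s %% 4) + 1, res_b = 4868, name_b = "ASP",
    occupancy = 0.6, locality = "inter", source_subunit = s,
    source_res = 4763)))
  sets <- list(`4C` = mk(), `1C3O` = mk(), `1C3O-HID` = mk())
  pools <- list(closed = c("4C", "1C3O", "1C3O-HID"))
  out <- summarize_counts(sets, pools, mode = "source")
  expect_equal(out$count[out$residue == 4763], 12)
})

test_that("a system assigned to two pools is rejected", {
  rec <- data.frame(subunit_a = 1, res_a = 1, name_a = "X", subunit_b = 2,
                    res_b = 2, name_b = "Y", occupancy = 1,
                    locality = "inter", source_subunit = 1, source_res = 1)
  expect_error(summarize_counts(list(s1 = rec),
                                pools = list(a = "s1", b = "s1")),
               "mixed groupings")
  expect_error(summarize_counts(list(s1 = rec), pools = list(a = "other")),
               "not assigned")
})
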