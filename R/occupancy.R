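#' Residue-pair heavy-atom contacts in one frame
#'
#' Two residues are in contact when any pair of their heavy (non-hydrogen)
#' atoms lies within `cutoff` Angstrom (default 3.0, near the mean
#' donor-acceptor distance of protein hydrogen bonds; the bound is
#' inclusive).  One event is reported per residue pair with the minimum
#' atom-atom distance; pairs are stored in canonical order (lower subunit
#' first, then lower residue number).
#'
#' `scope`/`partner_scope` restrict the analysis: one residue of the pair must
#' match `scope` and the other `partner_scope` (`NULL` means no restriction).
#' Same-subunit pairs within `exclude_within` sequence positions of each other
#' are dropped (backbone neighbors are trivially in contact), and when both
#' scopes are given, same-subunit pairs falling inside both scopes are
#' dropped too — the element-against-environment analysis counts
#' element-to-element pairs only when they bridge adjacent subunits.
#'
#' @param model a single-frame [structure_model()].
#' @param cutoff contact cutoff in Angstrom (default 3.0, inclusive).
#' @param scope,partner_scope [residue_region()] restrictions or `NULL`.
#' @param exclude_within drop same-subunit pairs with |residue difference| at
#'   or below this value (default 2).
#' @return Data frame of class `contact_events`: `subunit_a`, `res_a`,
#'   `name_a` (residue name), `subunit_b`, `res_b`, `name_b`, `min_distance`,
#'   plus `source_res`/`source_subunit` marking the scope-matching side.
#' @export
frame_contacts <- function(model, cutoff = 3.0, scope = NULL,
                           partner_scope = NULL, exclude_within = 2L) {
  a <- heavy_atoms(model)$atoms
  in_scope <- if (is.null(scope)) rep(TRUE, nrow(a))
              else region_contains(scope, a$resno)
  in_partner <- if (is.null(partner_scope)) rep(TRUE, nrow(a))
                else region_contains(partner_scope, a$resno)
  ia <- which(in_scope)
  ib <- which(in_partner)
  if (length(ia) == 0L || length(ib) == 0L) return(.empty_contacts())
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(a[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(.empty_contacts())
  gi <- ia[hit[, 1L]]
  gj <- ib[hit[, 2L]]
  d <- sqrt(pmax(d2[hit], 0))

  same_res <- a$subunit[gi] == a$subunit[gj] & a$resno[gi] == a$resno[gj]
  near_seq <- a$subunit[gi] == a$subunit[gj] &
    abs(a$resno[gi] - a$resno[gj]) <= exclude_within
  keep <- !same_res & !near_seq
  if (!is.null(scope) && !is.null(partner_scope)) {
    both_in_both <- a$subunit[gi] == a$subunit[gj] &
      region_contains(scope, a$resno[gi]) & region_contains(scope, a$resno[gj]) &
      region_contains(partner_scope, a$resno[gi]) &
      region_contains(partner_scope, a$resno[gj])
    keep <- keep & !both_in_both
  }
  if (!any(keep)) return(.empty_contacts())
  gi <- gi[keep]; gj <- gj[keep]; d <- d[keep]

  # canonical pair order; remember which side matched the scope
  swap <- (a$subunit[gj] < a$subunit[gi]) |
    (a$subunit[gj] == a$subunit[gi] & a$resno[gj] < a$resno[gi])
  p1 <- ifelse(swap, gj, gi)
  p2 <- ifelse(swap, gi, gj)
  src <- gi  # gi always matches `scope` by construction
  ev <- data.frame(
    subunit_a = a$subunit[p1], res_a = a$resno[p1], name_a = a$resname[p1],
    subunit_b = a$subunit[p2], res_b = a$resno[p2], name_b = a$resname[p2],
    min_distance = d,
    source_subunit = a$subunit[src], source_res = a$resno[src],
    stringsAsFactors = FALSE)
  key <- paste(ev$subunit_a, ev$res_a, ev$subunit_b, ev$res_b)
  ord <- order(key, ev$min_distance)
  ev <- ev[ord[!duplicated(key[ord])], , drop = FALSE]
  ev <- ev[order(ev$subunit_a, ev$res_a, ev$subunit_b, ev$res_b), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("contact_events", "data.frame")
  ev
}

.empty_contacts <- function() {
  ev <- data.frame(subunit_a = integer(), res_a = integer(), name_a = character(),
                   subunit_b = integer(), res_b = integer(), name_b = character(),
                   min_distance = numeric(),
                   source_subunit = integer(), source_res = integer(),
                   stringsAsFactors = FALSE)
  class(ev) <- c("contact_events", "data.frame")
  ev
}

#' Percent occupancy of residue-pair contacts over a frame window
#'
#' Runs [frame_contacts()] on the last `window` frames of a trajectory and
#' reports, for each residue pair ever observed in contact, the fraction of
#' frames in which the contact is present — the pair's percent occupancy.
#' Locality is `"inter"` when the two residues sit on different subunits,
#' `"intra"` otherwise.
#'
#' @param traj a [trajectory_ensemble()].
#' @param window number of trailing frames to analyze (default: all frames;
#'   100 reproduces a last-100-frames convention).
#' @param system system label stamped on every record (defaults to the
#'   topology label).
#' @inheritParams frame_contacts
#' @return Data frame of class `occupancy_records`: `system`, `subunit_a`,
#'   `res_a`, `name_a`, `subunit_b`, `res_b`, `name_b`, `n_present`,
#'   `n_frames`, `occupancy`, `locality`, `source_subunit`, `source_res`.
#' @export
occupancy_table <- function(traj, window = NULL, cutoff = 3.0, scope = NULL,
                            partner_scope = NULL, exclude_within = 2L,
                            system = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  nf <- n_frames(traj)
  if (is.null(window)) window <- nf
  if (window < 1L || window > nf)
    stop("window must be between 1 and the frame count (", nf, ")")
  if (is.null(system)) system <- traj$topology$label
  idx <- seq.int(nf - window + 1L, nf)
  tally <- new.env(parent = emptyenv())
  for (k in idx) {
    ev <- frame_contacts(frame_model(traj, k), cutoff = cutoff, scope = scope,
                         partner_scope = partner_scope,
                         exclude_within = exclude_within)
    if (nrow(ev) == 0L) next
    keys <- paste(ev$subunit_a, ev$res_a, ev$subunit_b, ev$res_b, sep = "|")
    for (i in seq_along(keys)) {
      k0 <- keys[i]
      if (is.null(tally[[k0]])) {
        rec <- ev[i, , drop = FALSE]
        rec$n_present <- 1L
        tally[[k0]] <- rec
      } else {
        tally[[k0]]$n_present <- tally[[k0]]$n_present + 1L
        if (ev$min_distance[i] < tally[[k0]]$min_distance)
          tally[[k0]]$min_distance <- ev$min_distance[i]
      }
    }
  }
  recs <- as.list(tally)
  if (length(recs) == 0L) {
    out <- .empty_contacts()
    out$n_present <- integer()
    out$n_frames <- integer()
    out$occupancy <- numeric()
    out$locality <- character()
    out$system <- character()
  } else {
    out <- do.call(rbind, unname(recs))
    out$n_frames <- length(idx)
    out$occupancy <- out$n_present / out$n_frames
    out$locality <- ifelse(out$subunit_a == out$subunit_b, "intra", "inter")
    out$system <- system
  }
  cols <- c("system", "subunit_a", "res_a", "name_a", "subunit_b", "res_b",
            "name_b", "n_present", "n_frames", "occupancy", "locality",
            "source_subunit", "source_res", "min_distance")
  out <- out[, cols, drop = FALSE]
  out <- out[order(out$subunit_a, out$res_a, out$subunit_b, out$res_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occupancy_records", "data.frame")
  out
}

#' Keep high-percent-occupancy interactions
#'
#' Retains records with occupancy at or above `threshold` (default 0.30; the
#' bound is inclusive, so a contact present in exactly 30 of 100 frames is
#' kept).
#'
#' @param records an `occupancy_records` data frame.
#' @param threshold occupancy fraction in \[0, 1\].
#' @return The filtered records.
#' @export
filter_high_occupancy <- function(records, threshold = 0.30) {
  stopifnot(is.data.frame(records))
  out <- records[records$occupancy >= threshold - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled per-residue interaction counts
#'
#' Pools high-occupancy records from several systems (all four subunits of
#' each) into named pools — e.g. a closed pool {4C, 1C3O, 1C3O-HID} against an
#' open pool {4O, 1C3O-open-S4S5L, 1C3O-open-S4S5L-HID} — and counts
#' interactions per residue position:
#'
#' * `mode = "source"`: count at the scope-side residue of each record (how
#'   many interactions a given position within the analyzed element makes);
#' * `mode = "partner"`: count at the other residue (which environment
#'   positions the element interacts with);
#' * `mode = "interface"`: inter-subunit records only, both residues of each
#'   pair counted (subunit-subunit interface map).
#'
#' With `min_appearances > 0`, residue positions whose count fails to reach
#' the minimum in *every* pool are dropped — with 3, a position is kept when
#' either pool shows the interaction at least three times.
#'
#' @param record_sets named list: system label -> `occupancy_records`
#'   (pre-filtered to high occupancy with [filter_high_occupancy()]).
#' @param pools named list: pool name -> character vector of system labels.
#'   Every system must belong to exactly one pool.
#' @param mode counting mode, see above.
#' @param min_appearances minimum count a residue must reach in at least one
#'   pool to be retained (default 0 = keep all).
#' @return Data frame of class `count_summary`: `pool`, `residue`, `count`,
#'   with attribute `mode`.
#' @export
summarize_counts <- function(record_sets, pools,
                             mode = c("source", "partner", "interface"),
                             min_appearances = 0L) {
  mode <- match.arg(mode)
  stopifnot(is.list(record_sets), is.list(pools))
  if (is.null(names(record_sets)) || is.null(names(pools)))
    stop("record_sets and pools must be named")
  membership <- unlist(lapply(names(pools), function(p)
    stats::setNames(rep(p, length(pools[[p]])), pools[[p]])))
  if (anyDuplicated(names(membership)))
    stop("mixed groupings: system(s) assigned to more than one pool: ",
         paste(unique(names(membership)[duplicated(names(membership))]),
               collapse = ", "))
  unknown <- setdiff(names(record_sets), names(membership))
  if (length(unknown))
    stop("system(s) not assigned to any pool: ", paste(unknown, collapse = ", "))

  counts <- list()
  for (sys in names(record_sets)) {
    rec <- record_sets[[sys]]
    if (nrow(rec) == 0L) next
    pool <- membership[[sys]]
    res <- switch(mode,
      source = rec$source_res,
      partner = ifelse(rec$source_subunit == rec$subunit_a &
                         rec$source_res == rec$res_a, rec$res_b, rec$res_a),
      interface = {
        inter <- rec[rec$locality == "inter", , drop = FALSE]
        c(inter$res_a, inter$res_b)
      })
    if (length(res) == 0L) next
    counts[[pool]] <- c(counts[[pool]], res)
  }
  rows <- do.call(rbind, lapply(names(pools), function(p) {
    if (is.null(counts[[p]])) return(NULL)
    tb <- table(counts[[p]])
    data.frame(pool = p, residue = as.integer(names(tb)),
               count = as.integer(tb), stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(pool = character(), residue = integer(),
                       count = integer(), stringsAsFactors = FALSE)
  if (min_appearances > 0L && nrow(rows) > 0L) {
    max_per_res <- tapply(rows$count, rows$residue, max)
    keep_res <- as.integer(names(max_per_res)[max_per_res >= min_appearances])
    rows <- rows[rows$residue %in% keep_res, , drop = FALSE]
  }
  rows <- rows[order(rows$pool, rows$residue), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "mode") <- mode
  class(rows) <- c("count_summary", "data.frame")
  rows
}

#' Interface sites of a pooled summary
#'
#' Convenience accessor: the residue positions appearing in a
#' [summarize_counts()] result, optionally for one pool.  With an
#' interface-mode summary of a closed pool this is the site list against
#' which disease mutations are scored by [proximity_fractions()].
#'
#' @param summary a `count_summary`.
#' @param pool pool name, or `NULL` for all pools.
#' @return Sorted integer vector of residue numbers.
#' @export
summary_sites <- function(summary, pool = NULL) {
  stopifnot(inherits(summary, "count_summary"))
  if (!is.null(pool)) summary <- summary[summary$pool == pool, , drop = FALSE]
  sort(unique(summary$residue))
}
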