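#' Residue regions
#'
#' A `residue_region` is a named set of closed integer intervals of canonical
#' residue numbers.  Intervals are normalized on construction: sorted, with
#' overlapping or abutting intervals merged, so membership tests are
#' well-defined and the representation is unique.
#'
#' @param name character scalar naming the region (e.g. `"S4S5L"`).
#' @param intervals two-column integer matrix (or a vector of length 2 for a
#'   single interval) of inclusive `[lo, hi]` residue-number intervals.
#' @return An object of class `residue_region`.
#' @examples
#' s4s5l <- residue_region("S4S5L", c(4746, 4766))
#' region_size(s4s5l)
#' @export
residue_region <- function(name, intervals) {
  if (!is.character(name) || length(name) != 1L)
    stop("region name must be a single string")
  if (is.vector(intervals) && length(intervals) == 2L)
    intervals <- matrix(intervals, ncol = 2L)
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L || nrow(intervals) < 1L)
    stop("intervals must be a two-column matrix of [lo, hi] pairs")
  storage.mode(intervals) <- "integer"
  if (any(is.na(intervals))) stop("intervals contain NA")
  if (any(intervals[, 1L] > intervals[, 2L]))
    stop("interval lower bound exceeds upper bound")
  intervals <- .merge_intervals(intervals)
  structure(list(name = name, intervals = intervals), class = "residue_region")
}

# sort and merge overlapping or abutting [lo, hi] integer intervals
.merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2L:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, 1L] <= out[last, 2L] + 1L) {
      out[last, 2L] <- max(out[last, 2L], iv[k, 2L])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  dimnames(out) <- list(NULL, c("lo", "hi"))
  out
}

#' @export
print.residue_region <- function(x, ...) {
  iv <- apply(x$intervals, 1L, function(r) paste0(r[1L], "-", r[2L]))
  cat("residue_region '", x$name, "': ", paste(iv, collapse = ", "),
      " (", region_size(x), " residues)\n", sep = "")
  invisible(x)
}

#' Test residue membership in a region
#'
#' @param region a [residue_region()].
#' @param residues integer vector of residue numbers.
#' @return Logical vector, `TRUE` where the residue lies in the region.
#' @export
region_contains <- function(region, residues) {
  stopifnot(inherits(region, "residue_region"))
  iv <- region$intervals
  out <- rep(FALSE, length(residues))
  for (k in seq_len(nrow(iv)))
    out <- out | (residues >= iv[k, 1L] & residues <= iv[k, 2L])
  out
}

#' Expand a region to its residue numbers
#'
#' @inheritParams region_contains
#' @return Sorted integer vector of every residue number in the region.
#' @export
region_residues <- function(region) {
  stopifnot(inherits(region, "residue_region"))
  iv <- region$intervals
  sort(unique(unlist(lapply(seq_len(nrow(iv)),
                            function(k) seq.int(iv[k, 1L], iv[k, 2L])))))
}

#' @rdname region_residues
#' @export
region_size <- function(region) {
  iv <- region$intervals
  sum(iv[, 2L] - iv[, 1L] + 1L)
}

#' Region set arithmetic
#'
#' `region_union()` and `region_difference()` combine regions; the result is
#' re-normalized.  These back the construction of whole-model regions from
#' printed modeled ranges minus missing (disordered) segments.
#'
#' @param a,b [residue_region()] objects.
#' @param name name for the result; defaults to a composite of the inputs.
#' @return A [residue_region()].
#' @export
region_union <- function(a, b, name = paste(a$name, "+", b$name)) {
  .region_from_residues(name, c(region_residues(a), region_residues(b)))
}

#' @rdname region_union
#' @export
region_difference <- function(a, b, name = paste(a$name, "-", b$name)) {
  keep <- setdiff(region_residues(a), region_residues(b))
  if (length(keep) == 0L) stop("region difference '", name, "' is empty")
  .region_from_residues(name, keep)
}

# compress a residue-number set into a residue_region
.region_from_residues <- function(name, residues) {
  residues <- sort(unique(as.integer(residues)))
  breaks <- c(0L, which(diff(residues) > 1L), length(residues))
  iv <- cbind(residues[breaks[-length(breaks)] + 1L], residues[breaks[-1L]])
  residue_region(name, iv)
}

#' Canonical RyR2 regions
#'
#' Named regions of the RyR2 channel domain in canonical human numbering
#' (isoform 1): the modeled ranges of the closed- and open-state tetramer
#' systems (two cryo-EM ranges, 4099-4206 and 4485-4963, minus the two
#' disordered segments 4524-4556 and 4672-4694 absent from the deposits; the
#' open model additionally lacks residue 4523), the S4-S5 linker, the U-motif,
#' the S6 helix, and the missing segments themselves.
#'
#' @return Named list of [residue_region()] objects: `closed_model`,
#'   `open_model`, `s4s5l`, `u_motif`, `s6`, `missing`.
#' @examples
#' region_size(ryr2_regions()$closed_model)  # 531 residues per subunit
#' @export
ryr2_regions <- function() {
  modeled <- residue_region("modeled", rbind(c(4099L, 4206L), c(4485L, 4963L)))
  missing <- residue_region("missing", rbind(c(4524L, 4556L), c(4672L, 4694L)))
  closed <- region_difference(modeled, missing, name = "closed_model")
  open <- region_difference(closed, residue_region("r4523", c(4523L, 4523L)),
                            name = "open_model")
  list(
    closed_model = closed,
    open_model = open,
    s4s5l = residue_region("S4S5L", c(4746L, 4766L)),
    u_motif = residue_region("U-motif", c(4167L, 4184L)),
    s6 = residue_region("S6", c(4839L, 4889L)),
    missing = missing
  )
}
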