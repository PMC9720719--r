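#' Disease-mutation catalogues
#'
#' A catalogue of mutation positions (canonical residue numbers) with
#' free-text labels, e.g. an arrhythmia-associated (CPVT1) mutation list.
#' Duplicate residue numbers are collapsed and their labels merged.
#'
#' @param residues integer vector of positive residue numbers.
#' @param labels optional character labels (defaults to the residue numbers).
#' @param provenance free-text description of where the list came from.
#' @return An object of class `mutation_catalogue` (a data frame with columns
#'   `residue`, `label`, plus a `provenance` attribute).
#' @export
mutation_catalogue <- function(residues, labels = NULL, provenance = "") {
  residues <- as.integer(residues)
  if (length(residues) == 0L) stop("empty mutation catalogue")
  if (any(is.na(residues) | residues <= 0L))
    stop("residue numbers must be positive integers")
  if (is.null(labels)) labels <- as.character(residues)
  if (length(labels) != length(residues))
    stop("labels must match residues in length")
  merged <- tapply(labels, residues, function(x) paste(unique(x), collapse = ";"))
  out <- data.frame(residue = as.integer(names(merged)),
                    label = unname(unlist(merged)), stringsAsFactors = FALSE)
  out <- out[order(out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("mutation_catalogue", "data.frame")
  out
}

#' Read a mutation catalogue from a two-column TSV
#'
#' @param path TSV with columns `residue` and `label` (header required).
#' @param provenance recorded on the catalogue (defaults to the path).
#' @return A [mutation_catalogue()].
#' @export
read_catalogue <- function(path, provenance = path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "label") %in% names(df)))
    stop("catalogue TSV needs 'residue' and 'label' columns")
  mutation_catalogue(df$residue, df$label, provenance = provenance)
}

#' Restrict a catalogue to residues covered by the structural models
#'
#' Mutations falling outside the modeled residue ranges cannot be scored
#' against model-derived interaction sites and are removed (e.g. 49 of a
#' 63-entry catalogue fall inside the modeled channel-domain ranges).
#'
#' @param catalogue a [mutation_catalogue()].
#' @param model_regions a [residue_region()] of the modeled residues.
#' @return The restricted catalogue; its `n_in_model` attribute records the
#'   retained count.
#' @export
restrict_to_model <- function(catalogue, model_regions) {
  stopifnot(inherits(catalogue, "mutation_catalogue"),
            inherits(model_regions, "residue_region"))
  keep <- region_contains(model_regions, catalogue$residue)
  out <- catalogue[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(catalogue, "provenance")
  attr(out, "n_in_model") <- nrow(out)
  class(out) <- class(catalogue)
  out
}

#' Sequence proximity of mutations to interaction sites
#'
#' For each catalogue entry, the distance to the nearest site is the minimum
#' absolute residue-number difference — a pure sequence criterion ("within
#' five residues of a high-percent-occupancy interaction site"), not a
#' spatial one.  `fraction_within[k]` is the share of entries at distance
#' <= k (inclusive); each entry counts once no matter how many sites are
#' near it, so duplicating sites never changes the result and adding a site
#' can only shrink distances.
#'
#' @param catalogue a [mutation_catalogue()].
#' @param sites non-empty integer vector of interaction-site residue numbers
#'   (typically [summary_sites()] of an inter-subunit high-occupancy summary).
#' @param ks integer thresholds for the within-k fractions (default `c(3, 5)`).
#' @return List of class `proximity_result`: `distances` (data frame
#'   `residue`, `label`, `nearest_site`, `distance`), `fraction_within`
#'   (named numeric, one entry per k), `n_entries`.
#' @export
proximity_fractions <- function(catalogue, sites, ks = c(3L, 5L)) {
  stopifnot(inherits(catalogue, "mutation_catalogue"))
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) == 0L) stop("empty site list")
  dmat <- abs(outer(catalogue$residue, sites, "-"))
  nearest <- apply(dmat, 1L, which.min)
  dist <- dmat[cbind(seq_len(nrow(dmat)), nearest)]
  fw <- vapply(ks, function(k) mean(dist <= k), numeric(1L))
  names(fw) <- as.character(ks)
  structure(list(
    distances = data.frame(residue = catalogue$residue,
                           label = catalogue$label,
                           nearest_site = sites[nearest],
                           distance = as.integer(dist),
                           stringsAsFactors = FALSE),
    fraction_within = fw,
    n_entries = nrow(catalogue)
  ), class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("proximity_result:", x$n_entries, "mutations;",
      paste(sprintf("within-%s %.0f%%", names(x$fraction_within),
                    100 * x$fraction_within), collapse = ", "), "\n")
  invisible(x)
}

#' Flag mutations adjacent to unmodeled gaps
#'
#' Entries lying within `window` residues of a residue missing from the
#' models (the disordered segments absent from the deposits) are flagged:
#' their apparent remoteness from interaction sites may be an artifact of the
#' gap rather than biology.  With `window = 0` only entries inside a gap are
#' flagged.
#'
#' @param catalogue a [mutation_catalogue()].
#' @param model_regions a [residue_region()] of the modeled residues; gaps
#'   are its complement inside the modeled span.
#' @param window flagging distance in residues (default 5).
#' @return Logical vector, one flag per catalogue entry.
#' @export
annotate_missing_adjacent <- function(catalogue, model_regions, window = 5L) {
  stopifnot(inherits(catalogue, "mutation_catalogue"),
            inherits(model_regions, "residue_region"))
  present <- region_residues(model_regions)
  span <- seq.int(min(present), max(present))
  gaps <- setdiff(span, present)
  if (length(gaps) == 0L) return(rep(FALSE, nrow(catalogue)))
  vapply(catalogue$residue,
         function(r) min(abs(gaps - r)) <= window, logical(1L))
}
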