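#' Structure models
#'
#' A `structure_model` is the universal coordinate container: an atom table
#' grouped into up to four subunits of a homotetrameric channel, plus a system
#' label, a gating-state tag and a numbering-scheme flag.  Atoms are kept
#' sorted by (subunit, residue number, serial); this ordering is relied on
#' throughout the pipeline.
#'
#' @param atoms data frame with columns `serial` (integer), `name` (atom
#'   name), `element` (element symbol, non-empty), `resno` (integer residue
#'   number), `resname` (3-letter residue code), `subunit` (integer 1-4),
#'   `x`, `y`, `z` (coordinates in Angstrom, finite).
#' @param label system label, e.g. `"4C"`, `"4O"`, `"1C3O"`.
#' @param state_tag one of `"closed"`, `"open"`, `"unknown"`.
#' @param numbering one of `"deposited"`, `"canonical"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "", state_tag = "unknown",
                            numbering = "canonical") {
  required <- c("serial", "name", "element", "resno", "resname",
                "subunit", "x", "y", "z")
  miss <- setdiff(required, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure_model must contain at least one atom")
  state_tag <- match.arg(state_tag, c("closed", "open", "unknown"))
  numbering <- match.arg(numbering, c("deposited", "canonical"))
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$subunit <- as.integer(atoms$subunit)
  if (any(!atoms$subunit %in% 1:4)) stop("subunit indices must be in 1..4")
  if (any(!nzchar(atoms$element))) stop("empty element symbol in atom table")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinate in atom table")
  atoms <- atoms[order(atoms$subunit, atoms$resno, atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label, state_tag = state_tag,
                 numbering = numbering),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cn <- count_residues(x)
  cat("structure_model", if (nzchar(x$label)) paste0("'", x$label, "'"),
      sprintf("(%s state, %s numbering)\n", x$state_tag, x$numbering))
  cat(" ", nrow(x$atoms), "atoms,", cn$total, "residues in",
      length(cn$per_subunit), "subunit(s):",
      paste(sprintf("%d:%d", as.integer(names(cn$per_subunit)), cn$per_subunit),
            collapse = " "), "\n")
  invisible(x)
}

#' Coordinate matrix of a model
#'
#' @param model a [structure_model()].
#' @return Numeric n x 3 matrix of atom coordinates (Angstrom), in atom-table
#'   order.
#' @export
model_xyz <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a model
#'
#' @param model a [structure_model()].
#' @param xyz n x 3 matrix matching the atom table.
#' @return The model with new coordinates.
#' @export
set_model_xyz <- function(model, xyz) {
  stopifnot(inherits(model, "structure_model"), nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

# hydrogen flag from the element symbol (covers H and D)
.is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

#' Drop hydrogen atoms
#'
#' Contact and pore analyses are defined over heavy (non-hydrogen) atoms;
#' hydrogens are retained on read and excluded downstream by this filter.
#'
#' @param model a [structure_model()].
#' @return The model restricted to heavy atoms.
#' @export
heavy_atoms <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  keep <- !.is_hydrogen(model$atoms$element)
  if (!any(keep)) stop("model contains no heavy atoms")
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Extract one subunit as a single-subunit model
#'
#' @param model a [structure_model()].
#' @param subunit subunit index in 1..4.
#' @return A [structure_model()] containing only that subunit.
#' @export
get_subunit <- function(model, subunit) {
  stopifnot(inherits(model, "structure_model"), subunit %in% 1:4)
  atoms <- model$atoms[model$atoms$subunit == subunit, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("subunit ", subunit, " absent from model")
  structure_model(atoms, label = model$label, state_tag = model$state_tag,
                  numbering = model$numbering)
}

#' Count residues per subunit and in total
#'
#' Counts distinct (subunit, residue number) pairs.  Canonical numbering is
#' required so that counts line up across systems.
#'
#' @param model a [structure_model()] in canonical numbering.
#' @return List with `per_subunit` (named integer vector) and `total`.
#' @examples
#' m <- make_tetramer(channel_spec(seed = 1))
#' count_residues(m)$total
#' @export
count_residues <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (model$numbering != "canonical")
    stop("count_residues requires canonical numbering; apply_numbering_offset first")
  key <- unique(model$atoms[, c("subunit", "resno")])
  per <- table(factor(key$subunit, levels = sort(unique(key$subunit))))
  list(per_subunit = c(per), total = nrow(key))
}

#' Restrict a model to a residue region
#'
#' Keeps only atoms whose residue number lies in `region` and whose subunit is
#' in `subunits`; atom ordering is preserved.  Used to carve substructures
#' (S4-S5 linker, S6 helix, ...) out of whole-channel models before RMSD
#' comparison.
#'
#' @param model a [structure_model()] in canonical numbering.
#' @param region a [residue_region()].
#' @param subunits subunits to retain (default all present).
#' @return The filtered [structure_model()].
#' @export
extract_regions <- function(model, region, subunits = 1:4) {
  stopifnot(inherits(model, "structure_model"), inherits(region, "residue_region"))
  if (model$numbering != "canonical")
    stop("extract_regions requires canonical numbering")
  keep <- region_contains(region, model$atoms$resno) &
    model$atoms$subunit %in% subunits
  if (!any(keep))
    stop("region '", region$name, "' selects no atoms in model '",
         model$label, "'")
  model$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Shift residue numbering between deposited and canonical schemes
#'
#' Deposited porcine RyR2 files are numbered one higher than the canonical
#' human sequence (deposited G4865 is canonical G4864, deposited H4763 is
#' canonical H4762); subtracting the offset converts to canonical numbering.
#'
#' @param model a [structure_model()] with `numbering = "deposited"`.
#' @param offset integer subtracted from every residue number (1 for the
#'   porcine deposits; 0 leaves numbers unchanged).
#' @return The model in canonical numbering.
#' @export
apply_numbering_offset <- function(model, offset) {
  stopifnot(inherits(model, "structure_model"))
  if (model$numbering != "deposited")
    stop("model is already in canonical numbering")
  model$atoms$resno <- model$atoms$resno - as.integer(offset)
  model$numbering <- "canonical"
  model
}
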