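#' Rigid-body superposition of two subunits
#'
#' Least-squares (Kabsch) fit of `mobile` onto `reference`, pairing atoms of
#' the selected names by canonical residue number over the intersection of
#' residues present on both sides.  A proper rotation is enforced (the
#' reflection-optimal case is sign-corrected), and the mobile model is not
#' mutated: the transform is returned and can be applied with
#' [apply_transform()].
#'
#' The default is a single full-pair fit.  `prune = TRUE` adds an iterative
#' prune-and-refit mode (drop pairs deviating more than `prune_sd` standard
#' deviations above the mean pair deviation, refit, at most `max_cycles`
#' cycles), comparable to what interactive structure aligners do before
#' quoting an RMSD.
#'
#' @param mobile,reference single-subunit [structure_model()] objects sharing
#'   at least 3 residues bearing the selected atom.
#' @param atom_names atom names used for pairing (default alpha-carbons).
#' @param prune enable prune-and-refit.
#' @param prune_sd pruning threshold in standard deviations.
#' @param max_cycles maximum prune-refit cycles.
#' @return An object of class `superposition_result`: `rotation` (3 x 3,
#'   applied on the right of row vectors), `translation` (length-3),
#'   `rmsd` (Angstrom over the pairs used), `n_matched`, and `rmsd_all`
#'   (RMSD over all initial pairs under the final transform, equal to `rmsd`
#'   unless pruning removed pairs).
#' @examples
#' m <- get_subunit(make_tetramer(channel_spec(seed = 1)), 1)
#' superpose(m, m)$rmsd  # 0
#' @export
superpose <- function(mobile, reference, atom_names = "CA",
                      prune = FALSE, prune_sd = 2, max_cycles = 5) {
  pq <- .paired_coords(mobile, reference, atom_names)
  P <- pq$P
  Q <- pq$Q
  if (nrow(P) < 3L)
    stop("fewer than 3 paired '", paste(atom_names, collapse = ","),
         "' atoms between the two subunits")
  fit <- .kabsch(P, Q)
  n_all <- nrow(P)
  rmsd_all <- fit$rmsd
  if (prune) {
    for (cyc in seq_len(max_cycles)) {
      dev <- sqrt(rowSums((.transform_xyz(P, fit) - Q)^2))
      thr <- mean(dev) + prune_sd * stats::sd(dev)
      keep <- dev <= thr
      if (all(keep) || sum(keep) < 3L) break
      P <- P[keep, , drop = FALSE]
      Q <- Q[keep, , drop = FALSE]
      fit <- .kabsch(P, Q)
    }
    devall <- sqrt(rowSums((.transform_xyz(pq$P, fit) - pq$Q)^2))
    rmsd_all <- sqrt(mean(devall^2))
  }
  structure(list(rotation = fit$R, translation = fit$t, rmsd = fit$rmsd,
                 n_matched = nrow(P), n_paired = n_all, rmsd_all = rmsd_all),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d atoms", x$rmsd, x$n_matched))
  if (x$n_matched < x$n_paired)
    cat(sprintf(" (pruned from %d; all-pair rmsd %.3f A)", x$n_paired, x$rmsd_all))
  cat("\n")
  invisible(x)
}

# pair atoms by (resno, name) over the residue intersection
.paired_coords <- function(mobile, reference, atom_names) {
  pick <- function(m) {
    a <- m$atoms[m$atoms$name %in% atom_names & !.is_hydrogen(m$atoms$element), ]
    a[order(a$resno, a$name), , drop = FALSE]
  }
  am <- pick(mobile)
  ar <- pick(reference)
  km <- paste(am$resno, am$name)
  kr <- paste(ar$resno, ar$name)
  shared <- intersect(km, kr)
  am <- am[match(shared, km), , drop = FALSE]
  ar <- ar[match(shared, kr), , drop = FALSE]
  list(P = as.matrix(am[, c("x", "y", "z")]),
       Q = as.matrix(ar[, c("x", "y", "z")]))
}

# Kabsch fit mapping row-vector coords P onto Q: x %*% R + t
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- unname(cq - drop(cp %*% R))
  dev2 <- rowSums((sweep(P %*% R, 2L, t, "+") - Q)^2)
  list(R = R, t = t, rmsd = sqrt(mean(dev2)))
}

.transform_xyz <- function(xyz, fit) sweep(xyz %*% fit$R, 2L, fit$t, "+")

#' Apply a superposition transform to a model
#'
#' @param model a [structure_model()].
#' @param sp a `superposition_result` from [superpose()].
#' @return The transformed model.
#' @export
apply_transform <- function(model, sp) {
  stopifnot(inherits(sp, "superposition_result"))
  set_model_xyz(model, .transform_xyz(model_xyz(model),
                                      list(R = sp$rotation, t = sp$translation)))
}

#' Build a chimera tetramer by subunit or segment substitution
#'
#' The donor's target subunit is superposed onto the acceptor's target subunit
#' (whole-subunit alpha-carbon fit) and then either the whole subunit or only
#' a residue segment (e.g. the S4-S5 linker, residues 4746-4766) of the
#' acceptor is excised and replaced by the transformed donor atoms.  Atoms
#' outside the scope are untouched.  Splices are made at the peptide bond
#' without geometry regularization — junction N-C distances are reported so a
#' caller can verify they are near bonding range, and [clash_check()] guards
#' against interpenetration; in a simulation workflow strained junctions relax
#' during equilibration.
#'
#' @param acceptor tetramer [structure_model()] providing everything outside
#'   the scope.
#' @param donor tetramer [structure_model()] providing the substituted atoms.
#' @param target_subunit subunit index 1..4 to operate on.
#' @param scope `NULL` for a whole-subunit swap, or a [residue_region()] for a
#'   segment swap.  Scope residues must exist in the donor.
#' @param atom_names superposition atom selection (default alpha-carbons).
#' @param label label for the product (default `"chimera"`).
#' @return A list of class `chimera_result`: `model` (the chimera),
#'   `superposition` (the [superpose()] record), `junctions` (data frame of
#'   splice-point C-N distances, empty for whole-subunit swaps or when
#'   backbone atoms are absent), `n_replaced_residues`.
#' @export
build_chimera <- function(acceptor, donor, target_subunit, scope = NULL,
                          atom_names = "CA", label = "chimera") {
  stopifnot(inherits(acceptor, "structure_model"),
            inherits(donor, "structure_model"))
  a_sub <- get_subunit(acceptor, target_subunit)
  d_sub <- get_subunit(donor, target_subunit)
  sp <- superpose(d_sub, a_sub, atom_names = atom_names)
  d_fit <- apply_transform(d_sub, sp)

  scope_res <- if (is.null(scope)) unique(d_fit$atoms$resno)
               else region_residues(scope)
  if (!is.null(scope)) {
    miss_d <- setdiff(scope_res, unique(d_fit$atoms$resno))
    if (length(miss_d))
      stop("scope residues absent from donor subunit: ",
           paste(utils::head(miss_d, 10L), collapse = ", "),
           if (length(miss_d) > 10L) " ...")
  }

  in_scope_a <- a_sub$atoms$resno %in% scope_res
  in_scope_d <- d_fit$atoms$resno %in% scope_res
  new_sub <- rbind(a_sub$atoms[!in_scope_a, , drop = FALSE],
                   d_fit$atoms[in_scope_d, , drop = FALSE])
  src <- c(rep("acceptor", sum(!in_scope_a)), rep("donor", sum(in_scope_d)))
  ord <- order(new_sub$resno, match(src, c("acceptor", "donor")), new_sub$serial)
  new_sub <- new_sub[ord, , drop = FALSE]
  src <- src[ord]

  others <- acceptor$atoms[acceptor$atoms$subunit != target_subunit, , drop = FALSE]
  atoms <- rbind(others, new_sub)
  atoms <- atoms[order(atoms$subunit, atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, label = label,
                           state_tag = "unknown",
                           numbering = acceptor$numbering)

  junctions <- .junction_lengths(new_sub, src)
  n_rep <- length(unique(new_sub$resno[src == "donor"]))
  structure(list(model = model, superposition = sp, junctions = junctions,
                 n_replaced_residues = n_rep),
            class = "chimera_result")
}

# C(i)-N(i+1) distances where consecutive residues come from different sources
.junction_lengths <- function(atoms, src) {
  res <- unique(atoms$resno)
  out <- data.frame(res_before = integer(), res_after = integer(),
                    distance = numeric())
  if (length(res) < 2L) return(out)
  res_src <- vapply(res, function(r) src[which(atoms$resno == r)[1L]], "")
  for (k in seq_len(length(res) - 1L)) {
    if (res_src[k] == res_src[k + 1L]) next
    ci <- which(atoms$resno == res[k] & atoms$name == "C")
    ni <- which(atoms$resno == res[k + 1L] & atoms$name == "N")
    if (length(ci) != 1L || length(ni) != 1L) next
    d <- sqrt(sum((as.numeric(atoms[ci, c("x", "y", "z")]) -
                     as.numeric(atoms[ni, c("x", "y", "z")]))^2))
    out <- rbind(out, data.frame(res_before = res[k], res_after = res[k + 1L],
                                 distance = d))
  }
  out
}

#' Detect steric clashes
#'
#' Reports every heavy-atom pair from different residues closer than
#' `min_separation` (an automated stand-in for the manual inspection one would
#' perform on an assembled chimera before simulating it).  An empty result is
#' success.
#'
#' @param model a [structure_model()].
#' @param min_separation distance threshold in Angstrom (default 1.0).
#' @return Data frame with one row per offending pair: subunit, residue,
#'   atom name on each side, and the distance.
#' @export
clash_check <- function(model, min_separation = 1.0) {
  a <- heavy_atoms(model)$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  out <- data.frame(subunit_a = integer(), res_a = integer(), name_a = character(),
                    subunit_b = integer(), res_b = integer(), name_b = character(),
                    distance = numeric())
  # block the pairwise scan to bound memory on large tetramers
  bs <- 1500L
  starts <- seq.int(1L, n, by = bs)
  for (i0 in starts) {
    ii <- i0:min(i0 + bs - 1L, n)
    for (j0 in starts[starts >= i0]) {
      jj <- j0:min(j0 + bs - 1L, n)
      d2 <- outer(rowSums(xyz[ii, , drop = FALSE]^2),
                  rowSums(xyz[jj, , drop = FALSE]^2), "+") -
        2 * tcrossprod(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      hit <- which(d2 < min_separation^2, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      gi <- ii[hit[, 1L]]
      gj <- jj[hit[, 2L]]
      keep <- gi < gj &
        !(a$subunit[gi] == a$subunit[gj] & a$resno[gi] == a$resno[gj])
      if (!any(keep)) next
      gi <- gi[keep]
      gj <- gj[keep]
      out <- rbind(out, data.frame(
        subunit_a = a$subunit[gi], res_a = a$resno[gi], name_a = a$name[gi],
        subunit_b = a$subunit[gj], res_b = a$resno[gj], name_b = a$name[gj],
        distance = sqrt(pmax(d2[cbind(match(gi, ii), match(gj, jj))], 0))))
    }
  }
  out[order(out$distance), , drop = FALSE]
}
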