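# Superposition and per-residue RMSD profiling of structural ensembles.
#
# All comparisons are between monomers. A pair is first superposed
# globally on a masked backbone selection (least squares, proper rotation
# only), after which RMSDs are computed either globally (pairwise matrix)
# or residue by residue (profile). Residues missing from either member
# of a pair contribute a fixed placeholder distance to the profile so
# that disorder shows up as maximal divergence rather than silently
# shrinking the average.

#' Region mask over author residue numbers
#'
#' @param intervals list of length-2 integer vectors `c(start, end)`
#'   (inclusive, author numbering). Must be sorted and non-overlapping.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(intervals) {
  stopifnot(length(intervals) >= 1)
  m <- do.call(rbind, lapply(intervals, function(iv) {
    stopifnot(length(iv) == 2, iv[1] <= iv[2])
    as.integer(iv)
  }))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
    stop("mask intervals overlap")
  structure(list(intervals = m), class = "region_mask")
}

#' Default superposition mask: ordered core excluding the two mobile loops
#' (residues 48-55 and 63-70) and the termini.
#' @export
default_core_mask <- function() region_mask(list(c(1, 47), c(56, 112)))

mask_contains <- function(mask, resno) {
  if (is.null(mask)) return(rep(TRUE, length(resno)))
  iv <- mask$intervals
  out <- rep(FALSE, length(resno))
  for (k in seq_len(nrow(iv)))
    out <- out | (resno >= iv[k, 1] & resno <= iv[k, 2])
  out
}

# atom table filtered to atom_set and mask, keyed by resno|elety
sel_atoms <- function(model, atom_set, mask = NULL) {
  a <- model$atoms
  keep <- a$elety %in% atom_set & mask_contains(mask, a$resno)
  a <- a[keep, , drop = FALSE]
  a$key <- paste(a$resno, a$elety, sep = "|")
  a
}

# least-squares proper rotation mapping P onto Q (rows are points)
kabsch_core <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- unname(cq - as.vector(R %*% cp))
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = nrow(P))
}

#' Kabsch superposition of one monomer onto another
#'
#' Atoms are paired by residue number and atom name over residues present
#' in both models (restricted to `atom_set` and `mask`). Returns the
#' proper rotation (det = +1) and translation minimizing the RMSD, never
#' a reflection.
#'
#' @param mobile,reference `monomer_model` objects.
#' @param atom_set atom names used for fitting (default backbone).
#' @param mask optional `region_mask` restricting the fitted residues.
#' @return list with `rotation` (3x3), `translation` (length 3),
#'   `rmsd` (Angstrom) and `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, reference,
                             atom_set = c("N", "CA", "C", "O"),
                             mask = NULL) {
  am <- sel_atoms(mobile, atom_set, mask)
  ar <- sel_atoms(reference, atom_set, mask)
  common <- intersect(am$key, ar$key)
  if (length(common) < 3)
    stop("fewer than 3 paired atoms for superposition")
  P <- as.matrix(am[match(common, am$key), c("x", "y", "z")])
  Q <- as.matrix(ar[match(common, ar$key), c("x", "y", "z")])
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-8 * max(sv))
    stop("degenerate (collinear) atom selection")
  kabsch_core(P, Q)
}

# apply a superposition to a full coordinate matrix (rows = atoms)
apply_superposition <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, `+`)
}

pair_list <- function(n_a, n_b, same) {
  if (same) {
    if (n_a < 2) return(matrix(integer(0), ncol = 2))
    t(utils::combn(n_a, 2))
  } else {
    as.matrix(expand.grid(i = seq_len(n_a), j = seq_len(n_b)))
  }
}

#' Pairwise global RMSD matrix between (or within) ensembles
#'
#' Entry (i, j) is the backbone RMSD of member i of `ensemble_a` after
#' least-squares superposition onto member j of `ensemble_b`, over the
#' atoms present in both (restricted to `atom_set`/`mask`). Within one
#' ensemble the matrix is symmetric with a zero diagonal.
#'
#' @param ensemble_a,ensemble_b `structure_ensemble`s; pass the same
#'   object (or omit `ensemble_b`) for a within-ensemble matrix.
#' @inheritParams kabsch_superpose
#' @return numeric matrix with member labels as dimnames; `NA` entries
#'   (with a warning) where a pair shares too few residues.
#' @export
pairwise_rmsd_matrix <- function(ensemble_a, ensemble_b = NULL,
                                 atom_set = c("N", "CA", "C", "O"),
                                 mask = NULL) {
  same <- is.null(ensemble_b)
  if (same) ensemble_b <- ensemble_a
  na <- length(ensemble_a$members); nb <- length(ensemble_b$members)
  M <- matrix(if (same) 0 else NA_real_, na, nb)
  lab <- function(e) make.unique(vapply(
    e$members, function(m) paste0(m$model_id, "_", m$chain_id),
    character(1)))
  dimnames(M) <- list(lab(ensemble_a), lab(ensemble_b))
  for (i in seq_len(na)) {
    jrange <- if (same) seq_len(na)[-seq_len(i)] else seq_len(nb)
    for (j in jrange) {
      fit <- tryCatch(
        kabsch_superpose(ensemble_a$members[[i]],
                         ensemble_b$members[[j]], atom_set, mask),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("no usable overlap for pair (%d,%d)", i, j))
        M[i, j] <- NA_real_
      } else M[i, j] <- fit$rmsd
      if (same) M[j, i] <- M[i, j]
    }
  }
  M
}

#' Per-residue pairwise RMSD profile
#'
#' For every monomer pair (unordered distinct pairs within one ensemble;
#' all cross pairs between two ensembles) the pair is superposed globally
#' on the masked backbone, then the RMSD is computed per residue over
#' `atom_set`. Residues absent from either member contribute `placeholder`
#' Angstrom (default 10) to that pair. The profile reports mean, min and
#' max across pairs, plus how often the placeholder fired.
#'
#' @inheritParams pairwise_rmsd_matrix
#' @param placeholder RMSD in Angstrom recorded for unmodeled residues.
#' @param seq_nums residue numbers to profile; default is the union of
#'   residues modeled in any member.
#' @return data frame: `resno`, `mean`, `min`, `max`, `n_placeholder`,
#'   with the placeholder value in `attr(, "placeholder")`.
#' @export
per_residue_profile <- function(ensemble_a, ensemble_b = NULL,
                                atom_set = c("N", "CA", "C", "O"),
                                mask = NULL, placeholder = 10,
                                seq_nums = NULL) {
  same <- is.null(ensemble_b)
  members_a <- ensemble_a$members
  members_b <- if (same) members_a else ensemble_b$members
  if (is.null(seq_nums)) {
    seq_nums <- sort(unique(c(
      unlist(lapply(members_a, residue_numbers)),
      unlist(lapply(members_b, residue_numbers)))))
  }
  pairs <- pair_list(length(members_a), length(members_b), same)
  if (nrow(pairs) == 0) stop("need at least one pair of members")
  vals <- matrix(NA_real_, length(seq_nums), nrow(pairs))
  ph <- matrix(FALSE, length(seq_nums), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    mi <- members_a[[pairs[p, 1]]]
    mj <- members_b[[pairs[p, 2]]]
    fit <- kabsch_superpose(mi, mj, atom_set, mask)
    ai <- sel_atoms(mi, atom_set, NULL)
    aj <- sel_atoms(mj, atom_set, NULL)
    common <- intersect(ai$key, aj$key)
    xi <- apply_superposition(
      as.matrix(ai[match(common, ai$key), c("x", "y", "z")]), fit)
    xj <- as.matrix(aj[match(common, aj$key), c("x", "y", "z")])
    resno_common <- ai$resno[match(common, ai$key)]
    d2 <- rowSums((xi - xj)^2)
    per_res <- tapply(d2, resno_common, function(v) sqrt(mean(v)))
    idx <- match(as.integer(names(per_res)), seq_nums)
    col <- rep(placeholder, length(seq_nums))
    isph <- rep(TRUE, length(seq_nums))
    col[idx] <- per_res
    isph[idx] <- FALSE
    vals[, p] <- col
    ph[, p] <- isph
  }
  out <- data.frame(
    resno = seq_nums,
    mean = rowMeans(vals),
    min = apply(vals, 1, min),
    max = apply(vals, 1, max),
    n_placeholder = rowSums(ph))
  attr(out, "placeholder") <- placeholder
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' RMSD of each ensemble member to the ensemble average structure
#'
#' Members are superposed onto their unweighted coordinate average
#' (computed over members modeling each residue; residues modeled in
#' fewer than half the members are excluded from the average), with two
#' refinement passes of re-averaging and re-superposing. Reports each
#' member's RMSD to the final average over `atom_set` within `mask`,
#' and the ensemble mean and standard deviation.
#'
#' @param ensemble a `structure_ensemble` with at least 2 members.
#' @inheritParams kabsch_superpose
#' @param n_passes refinement passes after the initial superposition.
#' @return list with `per_member` (numeric vector), `mean`, `sd`.
#' @export
rmsd_to_mean <- function(ensemble, atom_set = c("N", "CA", "C", "O"),
                         mask = NULL, n_passes = 2) {
  members <- ensemble$members
  if (length(members) < 2) stop("need >= 2 members")
  tabs <- lapply(members, sel_atoms, atom_set = atom_set, mask = mask)
  keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  counts <- rowSums(vapply(tabs, function(a) keys %in% a$key,
                           logical(length(keys))))
  keys <- keys[counts >= length(members) / 2]
  if (length(keys) < 3) stop("too few commonly modeled atoms")
  coords <- lapply(tabs, function(a) {
    X <- matrix(NA_real_, length(keys), 3)
    idx <- match(keys, a$key)
    ok <- !is.na(idx)
    X[ok, ] <- as.matrix(a[idx[ok], c("x", "y", "z")])
    X
  })
  # initial frame: superpose all onto member 1 over shared atoms
  ref <- coords[[1]]
  align_onto <- function(X, R) {
    ok <- stats::complete.cases(X) & stats::complete.cases(R)
    if (sum(ok) < 3) stop("too few shared atoms during averaging")
    fit <- kabsch_core(X[ok, , drop = FALSE], R[ok, , drop = FALSE])
    apply_superposition(X, fit)
  }
  aligned <- lapply(coords, align_onto, R = ref)
  for (pass in seq_len(n_passes)) {
    avg <- apply(simplify2array(aligned), c(1, 2), mean, na.rm = TRUE)
    aligned <- lapply(aligned, align_onto, R = avg)
  }
  avg <- apply(simplify2array(aligned), c(1, 2), mean, na.rm = TRUE)
  per_member <- vapply(aligned, function(X) {
    ok <- stats::complete.cases(X)
    sqrt(mean(rowSums((X[ok, , drop = FALSE] - avg[ok, , drop = FALSE])^2)))
  }, numeric(1))
  list(per_member = per_member, mean = mean(per_member),
       sd = stats::sd(per_member), n_atoms_avg = length(keys))
}

#' Apply a rigid transformation to a monomer (testing/production helper)
#' @param model a `monomer_model`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @export
transform_monomer <- function(model, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(rotation), 2, translation, `+`)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]
  model$atoms$z <- new[, 3]
  model
}
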