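# Crystal-lattice contact analysis: solvent-accessible surface area,
# symmetry-mate generation from cell + space group, unique contact
# interfaces and per-residue buried-surface-area profiles. This is a
# simplified PISA-style pipeline: contacts are defined geometrically
# (heavy-atom centers within a cutoff), burial is the per-residue SASA
# lost upon forming the chain pair, and no interface thermodynamics is
# attempted.

# Bondi van der Waals radii (Angstrom), keyed by element
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)
VDW_DEFAULT <- 1.70

element_from_name <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", elety))
  first <- substr(e, 1, 1)
  ifelse(substr(e, 1, 2) == "SE", "SE", first)
}

vdw_radius <- function(elety) {
  el <- element_from_name(elety)
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ","),
            "; using default radius ", VDW_DEFAULT, " Angstrom")
    r[is.na(r)] <- VDW_DEFAULT
  }
  unname(r)
}

#' Deterministic golden-spiral points on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic variant using a golden-spiral point lattice per atom, so
#' repeated runs give identical areas for a fixed `n_points`.
#'
#' @param models a `monomer_model` or list of them (areas are computed for
#'   the whole set, so occlusion between models counts).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @return list with `total` (Angstrom^2), `per_atom`, and `per_residue`
#'   (data frame `chain`, `resno`, `area` summing to `total`).
#' @export
sasa <- function(models, probe = 1.4, n_points = 960) {
  if (inherits(models, "monomer_model")) models <- list(models)
  atoms <- do.call(rbind, lapply(seq_along(models), function(k) {
    m <- models[[k]]
    data.frame(chain = paste0(m$chain_id, ".", k), resno = m$atoms$resno,
               elety = m$atoms$elety, x = m$atoms$x, y = m$atoms$y,
               z = m$atoms$z, stringsAsFactors = FALSE)
  }))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$elety) + probe
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  area <- numeric(n)
  # neighbor prefilter via cell lists would be overkill at these sizes;
  # a plain cutoff on pairwise distance per atom is fast enough
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + maxr)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    area[i] <- 4 * pi * rad[i]^2 * frac
  }
  per_res <- stats::aggregate(area,
                              by = list(key = atoms$chain,
                                        resno = atoms$resno), FUN = sum)
  names(per_res)[3] <- "area"
  per_res$copy <- as.integer(sub("^.*\\.", "", per_res$key))
  per_res$chain <- sub("\\.[0-9]+$", "", per_res$key)
  per_res <- per_res[order(per_res$copy, per_res$resno),
                     c("chain", "copy", "resno", "area")]
  rownames(per_res) <- NULL
  list(total = sum(area), per_atom = area, per_residue = per_res)
}

# ---- space-group operators ---------------------------------------------

# rotation parts and fractional translations for the supported groups
# (operator triplets follow International Tables settings)
sg_ops_table <- function(symbol) {
  ops <- switch(symbol,
    "P1" = list(c("x", "y", "z")),
    "P212121" = list(
      c("x", "y", "z"),
      c("-x+1/2", "-y", "z+1/2"),
      c("x+1/2", "-y+1/2", "-z"),
      c("-x", "y+1/2", "-z+1/2")),
    "C2221" = list(
      c("x", "y", "z"),
      c("-x", "-y", "z+1/2"),
      c("x", "-y", "-z"),
      c("-x", "y", "-z+1/2"),
      c("x+1/2", "y+1/2", "z"),
      c("-x+1/2", "-y+1/2", "z+1/2"),
      c("x+1/2", "-y+1/2", "-z"),
      c("-x+1/2", "y+1/2", "-z+1/2")),
    stop("unsupported space group '", symbol,
         "'; supported: P1, P212121 (P 21 21 21), C2221 (C 2 2 21)"))
  lapply(ops, parse_triplet)
}

normalize_sg <- function(symbol) {
  s <- toupper(gsub("[ _()]", "", symbol))
  if (s %in% c("P1")) return("P1")
  if (s %in% c("P212121")) return("P212121")
  if (s %in% c("C2221")) return("C2221")
  symbol
}

parse_triplet <- function(triplet) {
  R <- matrix(0, 3, 3); t_frac <- numeric(3)
  for (k in 1:3) {
    expr <- triplet[k]
    for (ax in 1:3) {
      v <- c("x", "y", "z")[ax]
      if (grepl(paste0("-", v), expr, fixed = TRUE)) R[k, ax] <- -1
      else if (grepl(v, expr, fixed = TRUE)) R[k, ax] <- 1
    }
    frac <- gsub("[xyz]|-(?=[xyz])", "", expr, perl = TRUE)
    frac <- gsub("^\\+", "", gsub("[+]$", "", frac))
    frac <- gsub("-(?![0-9])", "", frac, perl = TRUE)
    if (nchar(frac)) t_frac[k] <- eval(parse(text = frac))
  }
  list(rot = R, trans = t_frac)
}

#' Space-group operators
#' @param space_group symbol, e.g. "P 21 21 21".
#' @return list of operators, each `list(rot = 3x3, trans = fractional)`.
#' @export
space_group_operators <- function(space_group) {
  sg_ops_table(normalize_sg(space_group))
}

# orthogonalization matrix (fractional -> cartesian), PDB convention
orth_matrix <- function(form) {
  a <- form$cell_a; b <- form$cell_b; c <- form$cell_c
  al <- form$cell_alpha * pi / 180; be <- form$cell_beta * pi / 180
  ga <- form$cell_gamma * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)), 3, 3, byrow = TRUE)
}

apply_op_cartesian <- function(xyz, op, shift, M, Minv) {
  frac <- xyz %*% t(Minv)
  frac <- sweep(frac %*% t(op$rot), 2, op$trans + shift, `+`)
  frac %*% t(M)
}

#' Generate contacting symmetry mates of a model
#'
#' Enumerates all space-group operators combined with lattice translations
#' in \{-1, 0, 1\}^3, transforms the model, and keeps every copy (other
#' than the identity) with at least one atom pair within `cutoff` of the
#' original.
#'
#' @param model a `monomer_model` (cartesian coordinates).
#' @param form a `crystal_form` giving cell and space group.
#' @param cutoff contact distance between heavy-atom centers, Angstrom.
#' @return list of mates: each `list(model, op_index, shift, descriptor)`.
#' @export
symmetry_mates <- function(model, form, cutoff = 5.0) {
  ops <- space_group_operators(form$space_group)
  M <- orth_matrix(form); Minv <- solve(M)
  xyz0 <- as.matrix(model$atoms[, c("x", "y", "z")])
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  mates <- list()
  for (oi in seq_along(ops)) {
    for (si in seq_len(nrow(shifts))) {
      shift <- as.numeric(shifts[si, ])
      if (oi == 1 && all(shift == 0)) next
      xyz <- apply_op_cartesian(xyz0, ops[[oi]], shift, M, Minv)
      # bounding box prefilter
      if (any(apply(xyz, 2, min) > apply(xyz0, 2, max) + cutoff) ||
          any(apply(xyz, 2, max) < apply(xyz0, 2, min) - cutoff)) next
      if (!any_contact(xyz0, xyz, cutoff)) next
      mate <- model
      mate$atoms$x <- xyz[, 1]; mate$atoms$y <- xyz[, 2]
      mate$atoms$z <- xyz[, 3]
      mates[[length(mates) + 1L]] <- list(
        model = mate, op_index = oi, shift = shift,
        descriptor = sprintf("%s:op%d+(%d,%d,%d)", model$chain_id, oi,
                             shift[1], shift[2], shift[3]))
    }
  }
  mates
}

any_contact <- function(A, B, cutoff) {
  min_contact_count(A, B, cutoff, stop_at_one = TRUE) > 0
}

min_contact_count <- function(A, B, cutoff, stop_at_one = FALSE) {
  c2 <- cutoff^2
  n <- 0L
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
      (B[, 3] - A[i, 3])^2
    if (any(d2 < c2)) {
      n <- n + 1L
      if (stop_at_one) return(n)
    }
  }
  n
}

# canonical key for one lattice interface: unordered chain pair plus the
# operator equivalence class (rotation and fractional screw translation,
# identified with its inverse, lattice translations ignored)
interface_key <- function(chain_a, chain_b, op) {
  fmt <- function(R, t) paste(c(round(R, 6), round(t %% 1, 6)),
                              collapse = ",")
  Rinv <- solve(op$rot)
  tinv <- -Rinv %*% op$trans
  k1 <- paste(chain_a, chain_b, fmt(op$rot, op$trans), sep = ";")
  k2 <- paste(chain_b, chain_a, fmt(Rinv, as.numeric(tinv)), sep = ";")
  min(k1, k2)
}

#' Lattice contact interfaces of a crystal
#'
#' For every chain of the asymmetric unit, finds all contacting partner
#' copies (other ASU chains and symmetry mates of every chain) and
#' computes per-residue buried area as SASA(chain alone) minus SASA(chain
#' in the pair). Each physical contact is one record; records sharing the
#' same unordered chain pair and operator class (modulo lattice
#' translation and inversion) carry the same `unique_id`, implementing
#' redundancy screening. Chain-chain contacts within the asymmetric unit
#' are flagged `intra_asu` (the biological dimer interface) so that
#' lattice-only profiles can exclude them.
#'
#' @param chains list of `monomer_model`s forming the asymmetric unit.
#' @param form `crystal_form`.
#' @param cutoff contact cutoff in Angstrom.
#' @param probe,n_points passed to [sasa()].
#' @return list of `contact_interface` records: `chain_id`, `partner`,
#'   `unique_id`, `intra_asu`, `buried` (data frame `resno`, `area`),
#'   `total_buried`.
#' @export
lattice_interfaces <- function(chains, form, cutoff = 5.0, probe = 1.4,
                               n_points = 960) {
  stopifnot(length(chains) >= 1)
  ops <- space_group_operators(form$space_group)
  M <- orth_matrix(form); Minv <- solve(M)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  iso_sasa <- lapply(chains, sasa, probe = probe, n_points = n_points)
  out <- list()
  for (ci in seq_along(chains)) {
    A <- chains[[ci]]
    xyzA <- as.matrix(A$atoms[, c("x", "y", "z")])
    for (cj in seq_along(chains)) {
      B <- chains[[cj]]
      xyzB0 <- as.matrix(B$atoms[, c("x", "y", "z")])
      for (oi in seq_along(ops)) {
        for (si in seq_len(nrow(shifts))) {
          shift <- as.numeric(shifts[si, ])
          if (ci == cj && oi == 1 && all(shift == 0)) next
          intra <- (oi == 1 && all(shift == 0))
          xyzB <- apply_op_cartesian(xyzB0, ops[[oi]], shift, M, Minv)
          if (any(apply(xyzB, 2, min) > apply(xyzA, 2, max) + cutoff) ||
              any(apply(xyzB, 2, max) < apply(xyzA, 2, min) - cutoff))
            next
          if (!any_contact(xyzA, xyzB, cutoff)) next
          mate <- B
          mate$atoms$x <- xyzB[, 1]; mate$atoms$y <- xyzB[, 2]
          mate$atoms$z <- xyzB[, 3]
          pair_sasa <- sasa(list(A, mate), probe = probe,
                            n_points = n_points)
          pa <- pair_sasa$per_residue
          pa <- pa[pa$copy == 1L, , drop = FALSE]  # chain A is model 1
          iso <- iso_sasa[[ci]]$per_residue
          buried <- merge(iso[, c("resno", "area")],
                          pa[, c("resno", "area")], by = "resno",
                          suffixes = c("_iso", "_pair"))
          buried$area <- pmax(buried$area_iso - buried$area_pair, 0)
          op_shifted <- ops[[oi]]
          op_shifted$trans <- op_shifted$trans + shift
          out[[length(out) + 1L]] <- structure(list(
            chain_id = A$chain_id,
            partner = sprintf("%s:op%d+(%d,%d,%d)", B$chain_id, oi,
                              shift[1], shift[2], shift[3]),
            unique_id = interface_key(A$chain_id, B$chain_id,
                                      op_shifted),
            intra_asu = intra,
            buried = buried[, c("resno", "area")],
            total_buried = sum(buried$area)),
            class = "contact_interface")
        }
      }
    }
  }
  structure(out, asu_chains = vapply(chains, `[[`, character(1),
                                     "chain_id"))
}

#' Number of unique interfaces in a contact list
#' @param interfaces output of [lattice_interfaces()].
#' @export
n_unique_interfaces <- function(interfaces) {
  length(unique(vapply(interfaces, `[[`, character(1), "unique_id")))
}

#' Per-residue summed buried-surface-area profile of one chain
#'
#' Sums buried area over all of the chain's physical lattice contacts
#' (both images of a self-contact count, as both bury residues of the
#' chain), optionally excluding the intra-ASU dimer interface.
#'
#' @param interfaces output of [lattice_interfaces()].
#' @param chain_id chain to profile.
#' @param include_intra_asu include the biological (intra-ASU) interface?
#' @return data frame `resno`, `area` (Angstrom^2, >= 0; all zero when
#'   the chain has no contacts).
#' @export
burial_profile <- function(interfaces, chain_id,
                           include_intra_asu = FALSE) {
  known <- attr(interfaces, "asu_chains")
  if (!is.null(known) && !chain_id %in% known)
    stop("unknown chain '", chain_id, "'")
  mine <- Filter(function(f) f$chain_id == chain_id &&
                   (include_intra_asu || !f$intra_asu), interfaces)
  if (!length(mine))
    return(data.frame(resno = integer(0), area = numeric(0)))
  tab <- do.call(rbind, lapply(mine, `[[`, "buried"))
  out <- stats::aggregate(area ~ resno, tab, sum)
  out[order(out$resno), ]
}
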