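# ---- domain containers -------------------------------------------------

STANDARD_AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Construct a monomer model
#'
#' A monomer model is one polypeptide chain from one coordinate model,
#' the basic unit of all ensemble comparisons. Atoms are held as a flat
#' table in author residue numbering.
#'
#' @param model_id identifier of the coordinate model (e.g. "1" for the
#'   first NMR model, or a crystal form label).
#' @param chain_id one-letter chain identifier.
#' @param atoms data frame with columns `resno` (integer author numbering),
#'   `aa` (1-letter residue code), `elety` (atom name), `x`, `y`, `z`
#'   (Angstrom), `b` (B-factor, Angstrom^2), `o` (occupancy).
#' @param source free-text provenance (file + model/chain selector).
#' @return an object of class `monomer_model`.
#' @export
monomer_model <- function(model_id, chain_id, atoms, source = "") {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "aa", "elety", "x", "y", "z", "b", "o") %in%
                  names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in monomer ", model_id, "/", chain_id)
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0,1]")
  if (any(atoms$b < 0, na.rm = TRUE))
    stop("negative B-factor")
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rn <- unique(atoms$resno)
  if (is.unsorted(rn, strictly = TRUE))
    stop("residue numbers not strictly increasing")
  structure(list(model_id = as.character(model_id),
                 chain_id = as.character(chain_id),
                 atoms = atoms, source = source),
            class = "monomer_model")
}

#' @export
print.monomer_model <- function(x, ...) {
  cat(sprintf("<monomer_model %s/%s: %d residues, %d atoms>\n",
              x$model_id, x$chain_id, length(unique(x$atoms$resno)),
              nrow(x$atoms)))
  invisible(x)
}

#' Residue numbers modeled in a monomer
#' @param model a `monomer_model`.
#' @return sorted integer vector of author residue numbers.
#' @export
residue_numbers <- function(model) sort(unique(model$atoms$resno))

#' Bundle monomer models into a structure ensemble
#'
#' @param members list of `monomer_model` objects.
#' @param label short tag, e.g. `"xray"` or `"nmr"`.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(members, label = "ensemble") {
  if (length(members) < 1) stop("ensemble needs at least one member")
  stopifnot(all(vapply(members, inherits, logical(1), "monomer_model")))
  structure(list(members = members, label = label),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble '%s': %d monomers>\n", x$label,
              length(x$members)))
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$members)

#' Expected protein construct
#'
#' The full expressed sequence with its numbering offset, used to classify
#' missing residues and to compute sequence-derived constants. Affinity-tag
#' residues conventionally occupy numbers <= 0 so that the mature protein
#' keeps its own numbering.
#'
#' @param sequence 1-letter amino-acid string (20 standard residues).
#' @param first_resno author number of the first residue (may be negative).
#' @param notes free text.
#' @export
expected_construct <- function(sequence, first_resno = 1L, notes = "") {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) == 0) stop("empty construct sequence")
  aas <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aas), unname(STANDARD_AA3))
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  structure(list(sequence = sequence,
                 first_resno = as.integer(first_resno),
                 notes = notes),
            class = "expected_construct")
}

construct_resnos <- function(construct) {
  seq(construct$first_resno,
      length.out = nchar(construct$sequence))
}

# ---- reading and writing coordinates -----------------------------------

drop_nonstandard <- function(atom) {
  keep <- atom$resid %in% names(STANDARD_AA3) &
    atom$type %in% c("ATOM", NA, "")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " HETATM/non-standard atom records dropped")
  atom[keep, , drop = FALSE]
}

# altloc policy: keep highest occupancy, ties broken by file order
collapse_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  key <- paste(atom$resno, atom$insert, atom$elety, sep = "|")
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  ord <- order(key, -occ, seq_len(nrow(atom)))
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(paste(atom$resno, atom$insert, atom$elety,
                                 sep = "|")), , drop = FALSE]
  atom[order(atom$resno, seq_len(nrow(atom))), , drop = FALSE]
}

#' Read coordinate files into a structure ensemble
#'
#' Reads PDB (including multi-model NMR files) and mmCIF files and splits
#' them into one monomer per (file, model, chain). Alternate locations are
#' collapsed to the highest-occupancy copy; HETATM and non-standard residues
#' are dropped with a message; author residue numbering is preserved.
#'
#' @param paths character vector of PDB/mmCIF file paths.
#' @param chains optional chain filter (character vector); `NULL` keeps all.
#' @param models optional model-number filter (integer vector); `NULL`
#'   keeps all.
#' @param label ensemble label.
#' @return a `structure_ensemble` with one `monomer_model` per selection.
#' @export
read_ensemble <- function(paths, chains = NULL, models = NULL,
                          label = "ensemble") {
  members <- list()
  for (path in paths) {
    is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
    obj <- tryCatch(
      if (is_cif) bio3d::read.cif(path) else
        bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
      error = function(e)
        stop("cannot parse coordinate file '", path, "': ",
             conditionMessage(e), call. = FALSE))
    atom <- obj$atom
    atom$.row <- seq_len(nrow(atom))
    n_models <- if (is.matrix(obj$xyz)) nrow(obj$xyz) else 1L
    model_ids <- seq_len(n_models)
    if (!is.null(models)) model_ids <- intersect(model_ids, models)
    atom <- drop_nonstandard(atom)
    atom <- collapse_altloc(atom)
    if (nrow(atom) == 0) next
    chain_ids <- sort(unique(atom$chain))
    if (!is.null(chains)) chain_ids <- intersect(chain_ids, chains)
    for (m in model_ids) {
      if (n_models > 1) {
        xyz <- matrix(obj$xyz[m, ], ncol = 3, byrow = TRUE)
        # xyz rows follow the original atom table row order
        co <- xyz[atom$.row, , drop = FALSE]
      } else {
        co <- cbind(atom$x, atom$y, atom$z)
      }
      for (ch in chain_ids) {
        sel <- which(atom$chain == ch)
        if (!length(sel)) next
        adf <- data.frame(
          resno = as.integer(atom$resno[sel]),
          aa = unname(STANDARD_AA3[atom$resid[sel]]),
          elety = atom$elety[sel],
          x = co[sel, 1], y = co[sel, 2], z = co[sel, 3],
          b = ifelse(is.na(atom$b[sel]), 0, atom$b[sel]),
          o = ifelse(is.na(atom$o[sel]), 1, atom$o[sel]),
          stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- monomer_model(
          model_id = as.character(m), chain_id = ch, atoms = adf,
          source = sprintf("%s#model=%d,chain=%s", path, m, ch))
      }
    }
  }
  if (!length(members)) stop("no monomers selected")
  structure_ensemble(members, label = label)
}

AA1TO3 <- stats::setNames(names(STANDARD_AA3), unname(STANDARD_AA3))

#' Write an ensemble as a multi-model PDB file
#'
#' Each ensemble member becomes one MODEL block; the chain identifier is
#' taken from the member. Coordinates survive a write/read round trip to
#' the format precision (1e-3 Angstrom).
#'
#' @param ensemble a `structure_ensemble`.
#' @param path output file path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ensemble$members)) {
    mem <- ensemble$members[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    a <- mem$atoms
    name4 <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                    a$elety)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)) %% 100000, name4, AA1TO3[a$aa],
      substr(mem$chain_id, 1, 1), a$resno, a$x, a$y, a$z, a$o, a$b)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- missing-residue bookkeeping ---------------------------------------

#' Classify missing residues of a model against its construct
#'
#' Partitions residues of the expected construct that are absent from the
#' model into a leading (N-terminal) run, a trailing (C-terminal) run and
#' the internal remainder, the bookkeeping used in crystallographic tables.
#'
#' @param model a `monomer_model`.
#' @param construct an `expected_construct` covering the model's numbering.
#' @return integer vector `c(n_nterm, n_internal, n_cterm)`.
#' @export
missing_residues <- function(model, construct) {
  rng <- construct_resnos(construct)
  modeled <- residue_numbers(model)
  if (!all(modeled %in% rng))
    stop("model contains residues outside the construct numbering: ",
         paste(setdiff(modeled, rng), collapse = ","))
  absent <- setdiff(rng, modeled)
  if (!length(absent)) return(c(n_nterm = 0L, n_internal = 0L, n_cterm = 0L))
  n_nterm <- if (min(rng) %in% absent) {
    run <- rng[cumall(rng %in% absent)]
    length(run)
  } else 0L
  rev_rng <- rev(rng)
  n_cterm <- if (max(rng) %in% absent) {
    run <- rev_rng[cumall(rev_rng %in% absent)]
    length(run)
  } else 0L
  n_internal <- length(absent) - n_nterm - n_cterm
  c(n_nterm = n_nterm, n_internal = n_internal, n_cterm = n_cterm)
}

cumall <- function(x) cumprod(as.integer(x)) > 0

# ---- sequence-derived constants ----------------------------------------

# Pace extinction coefficients at 280 nm, M^-1 cm^-1
EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

#' Theoretical molar extinction coefficient at 280 nm
#'
#' Sum of Pace coefficients: 5500 per tryptophan, 1490 per tyrosine, 125
#' per cystine (disulfide-bonded cysteine pair).
#'
#' @param construct an `expected_construct` (or plain sequence string).
#' @param n_cystine number of disulfide bonds (not free cysteines).
#' @return extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(construct, n_cystine = 0L) {
  if (n_cystine < 0) stop("n_cystine must be >= 0")
  seq <- if (inherits(construct, "expected_construct"))
    construct$sequence else toupper(construct)
  aas <- strsplit(seq, "")[[1]]
  EXT_TRP * sum(aas == "W") + EXT_TYR * sum(aas == "Y") +
    EXT_CYSTINE * n_cystine
}

# average (isotope-abundance-weighted) residue masses, Da
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
MASS_WATER <- 18.0153

#' Average molecular mass of a protein construct
#'
#' Sum of average residue masses plus one water for the termini.
#'
#' @inheritParams extinction_coefficient
#' @return mass in Da.
#' @export
average_mass <- function(construct) {
  seq <- if (inherits(construct, "expected_construct"))
    construct$sequence else toupper(gsub("\\s", "", construct))
  if (nchar(seq) == 0) stop("empty sequence")
  aas <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(aas), names(AA_AVG_MASS))
  if (length(bad)) stop("unknown residue code(s): ",
                        paste(bad, collapse = ", "))
  sum(AA_AVG_MASS[aas]) + MASS_WATER
}

# ---- crystal form and Matthews analysis --------------------------------

#' Describe a crystal form
#'
#' @param cell_a,cell_b,cell_c cell edges in Angstrom.
#' @param cell_alpha,cell_beta,cell_gamma cell angles in degrees.
#' @param space_group Hermann-Mauguin symbol (supported: "P 1",
#'   "P 21 21 21", "C 2 2 21"; spaces optional).
#' @param z_asu number of asymmetric units per cell.
#' @param asu_mass total polymer mass per asymmetric unit, Da.
#' @return object of class `crystal_form`.
#' @export
crystal_form <- function(cell_a, cell_b, cell_c,
                         cell_alpha = 90, cell_beta = 90, cell_gamma = 90,
                         space_group = "P 1", z_asu = 1L, asu_mass = NA) {
  stopifnot(cell_a > 0, cell_b > 0, cell_c > 0,
            cell_alpha > 0, cell_alpha < 180,
            cell_beta > 0, cell_beta < 180,
            cell_gamma > 0, cell_gamma < 180,
            z_asu >= 1)
  structure(list(cell_a = cell_a, cell_b = cell_b, cell_c = cell_c,
                 cell_alpha = cell_alpha, cell_beta = cell_beta,
                 cell_gamma = cell_gamma,
                 space_group = normalize_sg(space_group),
                 z_asu = as.integer(z_asu), asu_mass = asu_mass),
            class = "crystal_form")
}

#' Unit cell volume (general triclinic formula)
#' @param form a `crystal_form`.
#' @return volume in Angstrom^3.
#' @export
cell_volume <- function(form) {
  ca <- cos(form$cell_alpha * pi / 180)
  cb <- cos(form$cell_beta * pi / 180)
  cg <- cos(form$cell_gamma * pi / 180)
  form$cell_a * form$cell_b * form$cell_c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Matthews coefficient and solvent content
#'
#' V_M = V_cell / (Z * asu_mass); solvent fraction = 1 - 1.23 / V_M
#' (the 1.23 constant corresponds to a protein partial specific volume of
#' 0.74 cm^3/g).
#'
#' @param form a `crystal_form` with `asu_mass` set.
#' @return list with `v_m` (Angstrom^3/Da), `solvent_fraction`, and a
#'   logical `implausible` flag set when the solvent fraction falls outside
#'   (0, 1).
#' @export
matthews <- function(form) {
  if (!is.finite(form$asu_mass) || form$asu_mass <= 0)
    stop("asu_mass must be set and positive")
  v_m <- cell_volume(form) / (form$z_asu * form$asu_mass)
  solvent <- 1 - 1.23 / v_m
  implausible <- !(solvent > 0 && solvent < 1)
  if (implausible)
    warning(sprintf("solvent fraction %.3f outside (0,1): implausible cell contents",
                    solvent))
  list(v_m = v_m, solvent_fraction = solvent, implausible = implausible)
}

# ---- B-factor profiles -------------------------------------------------

#' Per-residue mean B-factor track of an ensemble
#'
#' @param ensemble a `structure_ensemble`.
#' @param atom_set atom names averaged per residue (default backbone).
#' @return data frame: `resno`, one column per member (mean B over
#'   `atom_set`, `NA` where the residue is not modeled), plus `mean`
#'   across members.
#' @export
bfactor_profile <- function(ensemble, atom_set = c("N", "CA", "C", "O")) {
  if (!length(atom_set)) stop("atom_set must be nonempty")
  resnos <- sort(unique(unlist(lapply(ensemble$members, residue_numbers))))
  cols <- lapply(ensemble$members, function(mem) {
    a <- mem$atoms[mem$atoms$elety %in% atom_set, , drop = FALSE]
    v <- tapply(a$b, a$resno, mean)
    out <- rep(NA_real_, length(resnos))
    out[match(as.integer(names(v)), resnos)] <- v
    out
  })
  df <- data.frame(resno = resnos)
  labels <- vapply(ensemble$members,
                   function(m) paste0(m$model_id, "_", m$chain_id),
                   character(1))
  labels <- make.unique(labels)
  for (i in seq_along(cols)) df[[labels[i]]] <- cols[[i]]
  df$mean <- rowMeans(as.matrix(df[labels]), na.rm = TRUE)
  df
}

# ---- small format helpers ----------------------------------------------

#' Write a per-residue profile as TSV
#' @param df data frame whose first column is `resno`.
#' @param path output path.
#' @param comment optional unit/provenance comment written as a `#` header.
#' @export
write_profile_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(format(df, digits = 6, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as expected constructs
#' @param path FASTA file.
#' @param first_resno numbering offset applied to every record.
#' @return named list of `expected_construct`.
#' @export
read_construct_fasta <- function(path, first_resno = 1L) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records in ", path)
  ends <- c(heads[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(heads)) {
    nm <- sub("^>\\s*", "", lines[heads[i]])
    seq <- paste(lines[(heads[i] + 1L):ends[i]], collapse = "")
    out[[strsplit(nm, "\\s+")[[1]][1]]] <-
      expected_construct(seq, first_resno = first_resno, notes = nm)
  }
  out
}
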