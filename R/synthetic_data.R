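# Seeded generators for every input the pipeline consumes. The defaults
# emulate the study system: a two-chain dimeric ribonuclease toxin of 114
# residues (plus a 13-residue N-terminal purification tag occupying
# numbers <= 0), with three mobile loops (12-18, 48-54, 64-70), mono- or
# biexponential relaxation decays on the standard delay grids,
# fast-exchange titration patterns localized to the antitoxin-binding
# site, Siegert-relation DLS correlograms, and Debye-model SAXS curves.
# All randomness flows from one integer seed through R's Mersenne-Twister
# generator (pinned explicitly, so streams are platform independent).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion"))
  force(code)
}

#' Specification for the synthetic-data generators
#'
#' Holds the ground-truth parameters shared by all generators. Defaults
#' are the study conditions: 20-model ensemble, 114-residue chain, loops
#' 12-18, 48-54 and 64-70 mobile at 2.0 Angstrom versus a 0.2 Angstrom
#' core, relaxation rates typical of a 30 kDa dimer at 600 MHz with
#' loop-localized fast motion, a binding site in loop S1-S2 plus strands
#' S5/S6, a monodisperse 2.6 nm scatterer, and a 3-of-10 SAXS mixture.
#'
#' @param seed integer seed driving every generator.
#' @param n_models ensemble size.
#' @param chain_length residues per chain (numbered 1..chain_length).
#' @param mobile_loops list of `list(interval = c(lo, hi), sigma = Angstrom)`.
#' @param sigma_core coordinate noise outside the loops, Angstrom.
#' @param site_residues titration binding-site residues.
#' @param dls_components data frame `rh_nm`, `fraction` (sums to 1).
#' @param saxs_weights named numeric: true mixture weights by pool index.
#' @export
synth_spec <- function(seed = 1L,
                       n_models = 20L,
                       chain_length = 114L,
                       mobile_loops = list(
                         list(interval = c(12, 18), sigma = 2.0),
                         list(interval = c(48, 54), sigma = 2.0),
                         list(interval = c(64, 70), sigma = 2.0)),
                       sigma_core = 0.2,
                       site_residues = c(12:18, 71:77, 83:90),
                       dls_components = data.frame(rh_nm = 2.6,
                                                   fraction = 1),
                       saxs_weights = c(`1` = 0.5, `5` = 0.3,
                                        `9` = 0.2)) {
  stopifnot(abs(sum(dls_components$fraction) - 1) < 1e-9,
            sigma_core >= 0,
            all(vapply(mobile_loops, function(l) l$sigma >= 0,
                       logical(1))))
  for (l in mobile_loops)
    stopifnot(l$interval[1] >= 1, l$interval[2] <= chain_length)
  structure(list(seed = as.integer(seed), n_models = as.integer(n_models),
                 chain_length = as.integer(chain_length),
                 mobile_loops = mobile_loops, sigma_core = sigma_core,
                 site_residues = site_residues,
                 dls_components = dls_components,
                 saxs_weights = saxs_weights),
            class = "synth_spec")
}

# per-residue coordinate noise implied by a spec
sigma_profile <- function(spec) {
  sig <- rep(spec$sigma_core, spec$chain_length)
  for (l in spec$mobile_loops)
    sig[l$interval[1]:l$interval[2]] <- l$sigma
  sig
}

# smooth compact backbone template: a gently curved superhelix with
# 3.8 Angstrom CA spacing; N/C/O placed at fixed local offsets. Not
# stereochemically exact, but compact and self-avoiding, which is all
# the geometry downstream analyses require.
backbone_template <- function(n_res, straight = FALSE, bump = NULL) {
  i <- seq_len(n_res)
  if (straight) {
    ca <- cbind(0, 0, 3.8 * i)
  } else {
    r1 <- 6; turn <- 2 * pi / 10
    chord <- 2 * r1 * sin(turn / 2)
    rise <- sqrt(3.8^2 - chord^2)
    ca <- cbind(r1 * cos(turn * i), r1 * sin(turn * i), rise * i)
    # slow supercoil so the chain folds back on itself compactly
    sup <- 2 * pi * i / n_res
    ca[, 1] <- ca[, 1] + 6 * cos(sup)
    ca[, 2] <- ca[, 2] + 6 * sin(sup)
  }
  if (!is.null(bump)) {
    w <- bump$residues
    ca[w, 1] <- ca[w, 1] + bump$height *
      sin(seq(0, pi, length.out = length(w)))
  }
  d <- rbind(ca[2, ] - ca[1, ], ca[-1, , drop = FALSE] -
               ca[-n_res, , drop = FALSE])
  d <- d / sqrt(rowSums(d^2))
  perp <- cbind(-d[, 2], d[, 1], 0)
  nz <- sqrt(rowSums(perp^2)); perp <- perp / pmax(nz, 1e-6)
  list(N = ca - 1.2 * d + 0.7 * perp,
       CA = ca,
       C = ca + 1.2 * d + 0.7 * perp,
       O = ca + 1.4 * d + 1.8 * perp)
}

atoms_from_backbone <- function(bb, resnos, aa = "A", b = 20, o = 1) {
  n <- length(resnos)
  data.frame(
    resno = rep(resnos, each = 4),
    aa = aa,
    elety = rep(c("N", "CA", "C", "O"), times = n),
    x = as.vector(t(cbind(bb$N[, 1], bb$CA[, 1], bb$C[, 1], bb$O[, 1]))),
    y = as.vector(t(cbind(bb$N[, 2], bb$CA[, 2], bb$C[, 2], bb$O[, 2]))),
    z = as.vector(t(cbind(bb$N[, 3], bb$CA[, 3], bb$C[, 3], bb$O[, 3]))),
    b = b, o = o, stringsAsFactors = FALSE)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M); Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a synthetic structural ensemble with mobile loops
#'
#' Builds `n_models` copies of an idealized compact backbone, perturbs
#' each atom by isotropic Gaussian displacements whose per-residue
#' amplitude is `sigma` inside the mobile loops and `sigma_core`
#' elsewhere, and (optionally) applies a random rigid transform per model
#' so that downstream superposition actually has work to do. Loop
#' residues can be deleted from chosen models to exercise the missing-
#' residue placeholder.
#'
#' @param spec a `synth_spec`.
#' @param rigid_transforms apply a random rigid motion to each model?
#' @param deletions optional list mapping model index to residue numbers
#'   to delete, e.g. `list(`3` = 49:52)`.
#' @param b_inflate optional `list(residues =, delta =)` adding `delta`
#'   to B-factors of the named residues in every model.
#' @return list `ensemble` (a `structure_ensemble`) and `truth`
#'   (`sigma` per residue, the generator ground truth).
#' @export
make_ensemble <- function(spec, rigid_transforms = TRUE,
                          deletions = NULL, b_inflate = NULL) {
  with_seed(spec$seed, {
    sig <- sigma_profile(spec)
    resnos <- seq_len(spec$chain_length)
    bb0 <- backbone_template(spec$chain_length)
    members <- vector("list", spec$n_models)
    for (m in seq_len(spec$n_models)) {
      atoms <- atoms_from_backbone(bb0, resnos)
      per_atom_sig <- sig[match(atoms$resno, resnos)]
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, per_atom_sig)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, per_atom_sig)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, per_atom_sig)
      if (!is.null(b_inflate)) {
        hit <- atoms$resno %in% b_inflate$residues
        atoms$b[hit] <- atoms$b[hit] + b_inflate$delta
      }
      del <- deletions[[as.character(m)]]
      if (!is.null(del)) atoms <- atoms[!atoms$resno %in% del, ]
      mm <- monomer_model(model_id = as.character(m), chain_id = "A",
                          atoms = atoms, source = "synthetic")
      if (rigid_transforms)
        mm <- transform_monomer(mm, random_rotation(),
                                stats::runif(3, -20, 20))
      members[[m]] <- mm
    }
    list(ensemble = structure_ensemble(members, label = "synthetic"),
         truth = data.frame(resno = resnos, sigma = sig))
  })
}

#' Generate a toy crystal with a designed lattice contact
#'
#' Chain A is a straight backbone with the chosen loop bulging out along
#' +x; the P1 cell is sized so that exactly the +/- a translates touch
#' the bulge. Chain B (if requested) is an identical backbone without
#' the bulge, offset to the cell center, and makes no lattice contacts --
#' the contrast between a chain whose loop packs against a neighbor and
#' one that is free.
#'
#' @param spec a `synth_spec`; the contact loop is the second mobile loop
#'   (48-54) by default.
#' @param contact_loop residue interval forced into lattice contact.
#' @param gap closest approach between the bulge tip and the symmetry
#'   mate, Angstrom.
#' @param bump_height how far the loop protrudes, Angstrom.
#' @param two_chains also place the contact-free chain B?
#' @return list `chains` (list of `monomer_model`), `form`
#'   (`crystal_form`), `truth` (contact residue interval).
#' @export
make_toy_crystal <- function(spec, contact_loop = c(48, 54), gap = 4.0,
                             bump_height = 8, two_chains = TRUE) {
  n <- spec$chain_length
  bb <- backbone_template(n, straight = TRUE)
  atomsA <- atoms_from_backbone(bb, seq_len(n))
  # splay the contact loop into a +/- x "flange": its +x face meets the
  # -x face of the +a lattice image at the same z, so the designed
  # contact is confined to the loop while the rod core stays free
  h <- bump_height / 2
  in_loop <- atomsA$resno >= contact_loop[1] &
    atomsA$resno <= contact_loop[2]
  atomsA$x[in_loop & atomsA$elety == "N"] <- -h
  atomsA$x[in_loop & atomsA$elety %in% c("C", "O")] <- h
  # size the a axis so the closest approach between the chain and its +a
  # lattice image equals `gap` (bisection on the exact atom-pair minimum;
  # the geometry is deterministic, so this is reproducible)
  xyzA <- as.matrix(atomsA[, c("x", "y", "z")])
  min_gap <- function(a) {
    img <- xyzA; img[, 1] <- img[, 1] + a
    mind <- Inf
    for (i in seq_len(nrow(xyzA))) {
      d2 <- (img[, 1] - xyzA[i, 1])^2 + (img[, 2] - xyzA[i, 2])^2 +
        (img[, 3] - xyzA[i, 3])^2
      mind <- min(mind, min(d2))
    }
    sqrt(mind)
  }
  lo <- max(atomsA$x) - min(atomsA$x)
  hi <- lo + 30
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (min_gap(mid) < gap) lo <- mid else hi <- mid
  }
  cell_a <- hi
  cell_b <- 60
  cell_c <- max(atomsA$z) - min(atomsA$z) + 30
  chains <- list(monomer_model("1", "A", atomsA, source = "toy-crystal"))
  if (two_chains) {
    bbB <- backbone_template(n, straight = TRUE)
    atomsB <- atoms_from_backbone(bbB, seq_len(n))
    atomsB$y <- atomsB$y + cell_b / 2
    chains <- c(chains, list(monomer_model("1", "B", atomsB,
                                           source = "toy-crystal")))
  }
  form <- crystal_form(cell_a, cell_b, cell_c, space_group = "P 1",
                       z_asu = 1L,
                       asu_mass = length(chains) * n * 110)
  list(chains = chains, form = form,
       truth = list(contact_residues =
                      contact_loop[1]:contact_loop[2]))
}

# delay grids of the relaxation experiments (seconds)
R1_DELAYS <- c(100, 200, 300, 400, 500, 600, 700, 900, 1200, 1500) / 1000
R2_DELAYS <- c(10, 30, 50, 70, 90, 110, 130, 150, 170, 210) / 1000

#' Ground-truth relaxation profiles for the synthetic chain
#'
#' Baseline values typical of a rigid ~30 kDa dimer at 600 MHz
#' (R1 0.9 s^-1, R2 21 s^-1, NOE 0.80); mobile loops get elevated R1,
#' depressed R2 and depressed NOE, mimicking fast internal motion in
#' loops S1-S2 (12-22) and S4-S5 (61-70).
#'
#' @param spec a `synth_spec`.
#' @param flexible_residues residues with fast internal motion.
#' @return data frame `residue`, `r1`, `r2`, `noe`.
#' @export
relaxation_truth <- function(spec, flexible_residues = c(12:22, 61:70)) {
  res <- seq_len(spec$chain_length)
  r1 <- rep(0.9, length(res)); r2 <- rep(21, length(res))
  noe <- rep(0.80, length(res))
  flex <- res %in% flexible_residues
  r1[flex] <- 1.6; r2[flex] <- 12; noe[flex] <- 0.35
  # soften the termini as well
  term <- res <= 3 | res >= spec$chain_length - 2
  r1[term] <- 1.8; r2[term] <- 8; noe[term] <- 0.1
  data.frame(residue = res, r1 = r1, r2 = r2, noe = noe)
}

#' Generate synthetic relaxation decay tables
#'
#' Monoexponential decays on the standard R1 and R2 delay grids with
#' multiplicative Gaussian intensity noise, plus duplicate saturated /
#' unsaturated intensity pairs for the hetNOE.
#'
#' @param spec a `synth_spec`.
#' @param noise relative intensity noise (default 0.02).
#' @param i0 reference peak intensity.
#' @return list `r1_table`, `r2_table` (residue, delay_s, intensity),
#'   `noe_table` (residue, replicate, i_on, i_off), `truth`.
#' @export
make_relaxation <- function(spec, noise = 0.02, i0 = 100) {
  truth <- relaxation_truth(spec)
  with_seed(spec$seed + 1L, {
    mk <- function(rates, delays) {
      do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
        I <- i0 * exp(-rates[k] * delays)
        data.frame(residue = truth$residue[k], delay_s = delays,
                   intensity = I * (1 + stats::rnorm(length(I), 0,
                                                     noise)))
      }))
    }
    r1_table <- mk(truth$r1, R1_DELAYS)
    r2_table <- mk(truth$r2, R2_DELAYS)
    noe_table <- do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
      i_off <- i0 * (1 + stats::rnorm(2, 0, noise))
      i_on <- i0 * truth$noe[k] * (1 + stats::rnorm(2, 0, noise))
      data.frame(residue = truth$residue[k], replicate = 1:2,
                 i_on = i_on, i_off = i_off)
    }))
    list(r1_table = r1_table, r2_table = r2_table,
         noe_table = noe_table, truth = truth)
  })
}

#' Generate a synthetic fast-exchange titration
#'
#' Eight titration points to a final 2:1 ligand:dimer molar ratio, with
#' the fifth point (1:1) at `saturation` fractional occupancy. Site
#' residues shift by up to `max_dd_h`/`max_dd_n` ppm (scaled by a random
#' per-residue weight) and lose intensity; non-site residues keep small
#' random jitter.
#'
#' @param spec a `synth_spec` (site from `spec$site_residues`).
#' @param max_dd_h,max_dd_n full-saturation shift changes, ppm.
#' @param saturation fractional occupancy at the 1:1 point.
#' @param site_ratio,offsite_ratio intensity ratios at 1:1.
#' @param noise_ppm shift measurement noise, ppm (1H; 15N noise is
#'   5x larger).
#' @return list `free` (reference peak list), `points` (list of 8 bound
#'   peak lists), `analysis_point` (index 5), `truth`.
#' @export
make_titration <- function(spec, max_dd_h = 0.06, max_dd_n = 0.45,
                           saturation = 0.8, site_ratio = 0.35,
                           offsite_ratio = 0.85, noise_ppm = 0.002) {
  res <- seq_len(spec$chain_length)
  with_seed(spec$seed + 2L, {
    free <- data.frame(residue = res,
                       h_ppm = stats::runif(length(res), 7.0, 9.5),
                       n_ppm = stats::runif(length(res), 105, 130),
                       intensity = stats::runif(length(res), 80, 120))
    site <- res %in% spec$site_residues
    w <- ifelse(site, stats::runif(length(res), 0.5, 1), 0)
    steps <- seq_len(8)
    frac <- saturation * pmin(steps / 5, seq(1, 1.25,
                                             length.out = 8)[steps])
    points <- lapply(steps, function(s) {
      f <- frac[s]
      data.frame(
        residue = res,
        h_ppm = free$h_ppm + f * w * max_dd_h +
          stats::rnorm(length(res), 0, noise_ppm),
        n_ppm = free$n_ppm + f * w * max_dd_n +
          stats::rnorm(length(res), 0, 5 * noise_ppm),
        intensity = free$intensity *
          (1 - f * ifelse(site, 1 - site_ratio, 1 - offsite_ratio)) *
          (1 + stats::rnorm(length(res), 0, 0.02)))
    })
    list(free = free, points = points, analysis_point = 5L,
         truth = list(site_residues = spec$site_residues))
  })
}

#' Generate a synthetic DLS correlogram
#'
#' Builds g2 via the Siegert relation from the mixture of hydrodynamic
#' radii in the spec, on a log-spaced delay grid, with multiplicative
#' Gaussian noise on g2 - B.
#'
#' @param spec a `synth_spec` (`spec$dls_components`).
#' @param temperature_k sample temperature.
#' @param B,beta Siegert baseline and intercept.
#' @param noise relative noise on the decaying part.
#' @param n_tau number of delay points.
#' @return list `correlogram`, `truth` (components + instrument).
#' @export
make_correlogram <- function(spec, temperature_k = 293, B = 1, beta = 0.9,
                             noise = 0, n_tau = 200) {
  comp <- spec$dls_components
  q <- scattering_vector()
  eta <- water_viscosity(temperature_k)
  D <- KB * temperature_k / (6 * pi * eta * comp$rh_nm * 1e-9)
  gammas <- D * q^2
  tau <- exp(seq(log(1e-7), log(1), length.out = n_tau))
  g1 <- rowSums(vapply(seq_along(gammas),
                       function(i) comp$fraction[i] * exp(-gammas[i] * tau),
                       numeric(length(tau))))
  g2 <- B * (1 + beta * g1^2)
  with_seed(spec$seed + 3L, {
    if (noise > 0)
      g2 <- B + (g2 - B) * (1 + stats::rnorm(length(g2), 0, noise))
    list(correlogram = correlogram(tau, g2,
                                   temperature_k = temperature_k),
         truth = list(components = comp, gammas = gammas, B = B,
                      beta = beta, q = q))
  })
}

#' Bend a monomer about a hinge residue (conformer generator)
#'
#' Rotates all atoms C-terminal of the hinge about an axis through the
#' hinge CA, producing conformers with genuinely different global shapes
#' (and radii of gyration) -- the kind of diversity an ensemble selection
#' method needs to be able to tell models apart.
#'
#' @param model a `monomer_model`.
#' @param hinge_resno hinge residue.
#' @param angle_deg bend angle.
#' @param axis rotation axis (unit length not required).
#' @export
bend_monomer <- function(model, hinge_resno, angle_deg,
                         axis = c(1, 0, 0)) {
  a <- model$atoms
  pivot_row <- which(a$resno == hinge_resno & a$elety == "CA")[1]
  if (is.na(pivot_row)) stop("hinge residue has no CA")
  pivot <- as.numeric(a[pivot_row, c("x", "y", "z")])
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mv <- a$resno > hinge_resno
  xyz <- sweep(as.matrix(a[mv, c("x", "y", "z")]), 2, pivot)
  xyz <- sweep(xyz %*% t(R), 2, pivot, `+`)
  a$x[mv] <- xyz[, 1]; a$y[mv] <- xyz[, 2]; a$z[mv] <- xyz[, 3]
  model$atoms <- a
  model
}

#' Generate a synthetic SAXS experiment from an ensemble pool
#'
#' Builds residue-bead Debye curves for a pool of models, mixes the
#' designated members with the spec's true weights, and adds Gaussian
#' noise with a matching error column.
#'
#' @param spec a `synth_spec` (`spec$saxs_weights` names pool indices).
#' @param pool_size number of pool models.
#' @param q momentum transfer grid, Angstrom^-1.
#' @param noise relative intensity noise (default 0.01).
#' @return list `exp` (noisy mixture `scattering_curve`), `pool` (list of
#'   theoretical curves), `models`, `truth` (indices + weights).
#' @export
make_saxs <- function(spec, pool_size = 10,
                      q = seq(0.005, 0.3, by = 0.001), noise = 0.01) {
  pool_spec <- spec
  pool_spec$n_models <- as.integer(pool_size)
  ens <- make_ensemble(pool_spec, rigid_transforms = FALSE)$ensemble
  # hinge-bend each pool member by a different angle so the pool spans
  # genuinely distinct global shapes
  angles <- seq(0, 150, length.out = pool_size)
  ens$members <- Map(function(m, ang)
    bend_monomer(m, hinge_resno = spec$chain_length %/% 2,
                 angle_deg = ang), ens$members, angles)
  pool <- lapply(ens$members, debye_curve, q = q)
  w <- spec$saxs_weights
  idx <- as.integer(names(w))
  I_mix <- Reduce(`+`, Map(function(i, wt) wt * pool[[i]]$i, idx, w))
  with_seed(spec$seed + 4L, {
    sigma <- pmax(noise * I_mix, 1e-12)
    I_noisy <- I_mix + stats::rnorm(length(I_mix), 0, sigma)
    list(exp = scattering_curve(q, I_noisy, sigma), pool = pool,
         models = ens,
         truth = list(indices = idx, weights = unname(w)))
  })
}

#' Generate a synthetic electrospray charge ladder
#' @param mass_da true mass.
#' @param charges charge states present.
#' @param noise m/z noise (Da, absolute).
#' @param spec optional `synth_spec` for the seed (default seed 1).
#' @return list `mz`, `truth`.
#' @export
make_charge_ladder <- function(mass_da = 14794, charges = 10:13,
                               noise = 0, spec = NULL) {
  seed <- if (is.null(spec)) 1L else spec$seed
  with_seed(seed + 5L, {
    mz <- mass_da / charges + PROTON_MASS
    if (noise > 0) mz <- mz + stats::rnorm(length(mz), 0, noise)
    list(mz = mz, truth = list(mass_da = mass_da, charges = charges))
  })
}

#' Write the standard CSV/dat fixture files for a synthetic dataset
#'
#' Materializes relaxation tables, the titration peak lists, the
#' correlogram and the SAXS curves in the formats the readers consume,
#' together with a JSON manifest of the spec and truths.
#'
#' @param spec a `synth_spec`.
#' @param dir output directory (created).
#' @return invisibly, the manifest path.
#' @export
write_synthetic_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  relax <- make_relaxation(spec)
  utils::write.csv(relax$r1_table, file.path(dir, "r1.csv"),
                   row.names = FALSE)
  utils::write.csv(relax$r2_table, file.path(dir, "r2.csv"),
                   row.names = FALSE)
  utils::write.csv(relax$noe_table, file.path(dir, "noe.csv"),
                   row.names = FALSE)
  titr <- make_titration(spec)
  utils::write.csv(titr$free, file.path(dir, "hsqc_free.csv"),
                   row.names = FALSE)
  utils::write.csv(titr$points[[titr$analysis_point]],
                   file.path(dir, "hsqc_bound_1to1.csv"),
                   row.names = FALSE)
  corr <- make_correlogram(spec, noise = 0.01)
  utils::write.csv(data.frame(tau_s = corr$correlogram$tau,
                              g2 = corr$correlogram$g2),
                   file.path(dir, "correlogram.csv"), row.names = FALSE)
  sax <- make_saxs(spec)
  write_scattering_dat(sax$exp, file.path(dir, "saxs_exp.dat"))
  ens <- make_ensemble(spec)
  write_ensemble_pdb(ens$ensemble, file.path(dir, "ensemble.pdb"))
  manifest <- list(seed = spec$seed, n_models = spec$n_models,
                   chain_length = spec$chain_length,
                   mobile_loops = spec$mobile_loops,
                   sigma_core = spec$sigma_core,
                   site_residues = spec$site_residues,
                   relaxation_truth = relax$truth,
                   titration_truth = titr$truth,
                   dls_truth = corr$truth$components,
                   saxs_truth = sax$truth)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
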