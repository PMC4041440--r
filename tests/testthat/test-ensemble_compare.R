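test_that("Kabsch superposition recovers identity, translations and proper rotations", {
  P <- toy_cloud(10)
  m1 <- toy_monomer(P)
  fit <- kabsch_superpose(m1, m1)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  m2 <- toy_monomer(sweep(P, 2, c(5, 0, 0), `+`))
  fit2 <- kabsch_superpose(m2, m1)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$translation, c(-5, 0, 0), tolerance = 1e-8)

  R <- rotation_about_z(73)
  m3 <- toy_monomer(P %*% t(R))
  fit3 <- kabsch_superpose(m3, m1)
  expect_equal(fit3$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit3$rotation), 1, tolerance = 1e-6)

  # mirrored coordinates must NOT be matched by a reflection
  m4 <- toy_monomer(P %*% diag(c(-1, 1, 1)))
  fit4 <- kabsch_superpose(m4, m1)
  expect_gt(fit4$rmsd, 0.1)
  expect_equal(det(fit4$rotation), 1, tolerance = 1e-6)

  expect_error(kabsch_superpose(toy_monomer(P[1:2, ]), m1), "3 paired")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(toy_monomer(line), toy_monomer(line)),
               "degenerate|collinear")
})

test_that("Kabsch RMSD agrees with an SO(3) grid-search oracle", {
  # 4-atom toy: 3 atoms superposable, one displaced
  set.seed(11)
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 2))
  targ <- base
  targ[4, ] <- targ[4, ] + c(0.6, -0.5, 0.62)  # ~1 A displacement
  R <- random_proper_rotation()
  moved <- sweep(targ %*% t(R), 2, c(4, -2, 7), `+`)
  fit <- kabsch_superpose(toy_monomer(moved), toy_monomer(base))
  oracle <- grid_search_rmsd(moved, base)
  expect_lte(fit$rmsd, oracle + 1e-9)   # never worse than the oracle
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3 / max(fit$rmsd, 1))

  # a second, larger case
  P <- toy_cloud(12, seed = 8)
  Q <- P + matrix(stats::rnorm(36, sd = 0.3), ncol = 3)
  fit2 <- kabsch_superpose(toy_monomer(P), toy_monomer(Q))
  oracle2 <- grid_search_rmsd(P, Q)
  expect_equal(fit2$rmsd, oracle2, tolerance = 1e-3)
})

test_that("Kabsch RMSD agrees with an independent superposition implementation", {
  P <- toy_cloud(20, seed = 4)
  Q <- P + matrix(stats::rnorm(60, sd = 0.4), ncol = 3)
  fit <- kabsch_superpose(toy_monomer(P), toy_monomer(Q))
  xyz_p <- as.vector(t(P)); xyz_q <- as.vector(t(Q))
  fitted <- bio3d::fit.xyz(fixed = xyz_q, mobile = xyz_p,
                           fixed.inds = seq_along(xyz_q),
                           mobile.inds = seq_along(xyz_p))
  # bio3d reports RMSD rounded to 3 decimals
  expect_equal(fit$rmsd, bio3d::rmsd(fitted, xyz_q), tolerance = 1e-3)
})

test_that("reported RMSDs match a brute-force recomputation from transformed coordinates", {
  sp <- synth_spec(seed = 13, n_models = 3, chain_length = 30,
                   mobile_loops = list(list(interval = c(10, 15),
                                            sigma = 1)))
  ens <- make_ensemble(sp)$ensemble
  a <- ens$members[[1]]; b <- ens$members[[2]]
  fit <- kabsch_superpose(a, b)
  xa <- as.matrix(a$atoms[, c("x", "y", "z")])
  moved <- sweep(xa %*% t(fit$rotation), 2, fit$translation, `+`)
  xb <- as.matrix(b$atoms[, c("x", "y", "z")])
  expect_equal(fit$rmsd, sqrt(mean(rowSums((moved - xb)^2))),
               tolerance = 1e-6)
})

test_that("pairwise RMSD matrices are symmetric, zero-diagonal and rigid-motion invariant", {
  sp <- synth_spec(seed = 21, n_models = 4, chain_length = 40,
                   mobile_loops = list(list(interval = c(10, 15),
                                            sigma = 1.5)))
  ens <- make_ensemble(sp)$ensemble
  M <- pairwise_rmsd_matrix(ens)
  expect_equal(M, t(M))
  expect_equal(diag(M), stats::setNames(rep(0, 4), colnames(M)))
  expect_equal(dim(pairwise_rmsd_matrix(
    structure_ensemble(ens$members[1]),
    structure_ensemble(ens$members[1]))), c(1, 1))

  # members differing only by rigid motion give zero
  m <- ens$members[[1]]
  mt <- transform_monomer(m, rotation_about_z(40), c(3, -8, 1))
  M2 <- pairwise_rmsd_matrix(structure_ensemble(list(m, mt)))
  expect_equal(max(abs(M2)), 0, tolerance = 1e-8)

  # transforming a member changes nothing
  ens2 <- ens
  ens2$members[[2]] <- transform_monomer(ens$members[[2]],
                                         random_proper_rotation(),
                                         c(10, 2, -4))
  expect_equal(pairwise_rmsd_matrix(ens2), M, tolerance = 1e-6)
})

test_that("5-member ensembles with iid coordinate noise show mean pair RMSD near sigma*sqrt(2)", {
  set.seed(31)
  n_atoms <- 500; sigma <- 0.5  # rms 3D displacement per atom
  base <- matrix(stats::rnorm(3 * n_atoms, sd = 12), ncol = 3)
  members <- lapply(1:5, function(i)
    toy_monomer(base + matrix(stats::rnorm(3 * n_atoms,
                                           sd = sigma / sqrt(3)),
                              ncol = 3)))
  M <- pairwise_rmsd_matrix(structure_ensemble(members))
  mean_off <- mean(M[upper.tri(M)])
  expect_equal(mean_off, sigma * sqrt(2), tolerance = 0.1)
})

test_that("per-residue profiles localize mobile loops and apply the placeholder", {
  sp <- synth_spec(seed = 5, n_models = 6)
  ens <- make_ensemble(sp)$ensemble
  prof <- per_residue_profile(ens, mask = default_core_mask())
  expect_true(all(prof$min <= prof$mean + 1e-12))
  expect_true(all(prof$mean <= prof$max + 1e-12))
  loops <- prof$resno %in% c(12:18, 48:54, 64:70)
  core <- prof$resno %in% c(25:45, 75:110)
  expect_gt(mean(prof$mean[loops]), 3 * mean(prof$mean[core]))
  # no placeholder when all members model all residues
  expect_true(all(prof$n_placeholder == 0))

  # identical members give an all-zero profile
  two <- structure_ensemble(list(ens$members[[1]], ens$members[[1]]))
  p0 <- per_residue_profile(two, mask = default_core_mask())
  expect_equal(max(p0$max), 0, tolerance = 1e-10)

  # deleting residues in one member fires the 10 A placeholder exactly there
  del <- make_ensemble(synth_spec(seed = 5, n_models = 3),
                       deletions = list(`2` = 49:52))$ensemble
  pd <- per_residue_profile(del, mask = default_core_mask())
  hit <- pd$resno %in% 49:52
  expect_equal(pd$max[hit], rep(10, 4))
  expect_equal(pd$n_placeholder[hit], rep(2, 4))  # pairs (1,2), (2,3)
  expect_true(all(pd$n_placeholder[!hit] == 0))
  expect_equal(attr(pd, "placeholder"), 10)
})

test_that("cross-ensemble profiles use all ordered pairs", {
  spa <- synth_spec(seed = 6, n_models = 3, chain_length = 30,
                    mobile_loops = list(list(interval = c(8, 12),
                                             sigma = 1)))
  spb <- synth_spec(seed = 7, n_models = 2, chain_length = 30,
                    mobile_loops = list(list(interval = c(8, 12),
                                             sigma = 1)))
  ea <- make_ensemble(spa)$ensemble; eb <- make_ensemble(spb)$ensemble
  p <- per_residue_profile(ea, eb, mask = region_mask(list(c(1, 30))))
  expect_equal(attr(p, "n_pairs"), 6)
  M <- pairwise_rmsd_matrix(ea, eb, mask = region_mask(list(c(1, 30))))
  expect_equal(dim(M), c(3, 2))
})

test_that("rmsd_to_mean is zero for duplicates, symmetric for mirrored pairs", {
  m <- toy_monomer(toy_cloud(30))
  dup <- structure_ensemble(list(m, m, m))
  r <- rmsd_to_mean(dup)
  expect_equal(r$per_member, rep(0, 3), tolerance = 1e-10)

  base <- toy_cloud(30, seed = 9)
  delta <- matrix(stats::rnorm(90, sd = 0.3), ncol = 3)
  pair <- structure_ensemble(list(toy_monomer(base + delta),
                                  toy_monomer(base - delta)))
  r2 <- rmsd_to_mean(pair)
  expect_equal(r2$per_member[1], r2$per_member[2], tolerance = 1e-6)
  expect_error(rmsd_to_mean(structure_ensemble(list(m))))
})

test_that("region masks validate and restrict superposition", {
  expect_error(region_mask(list(c(1, 10), c(5, 20))), "overlap")
  m <- region_mask(list(c(56, 112), c(1, 47)))
  expect_equal(m$intervals[1, 1], 1)  # sorted
  sp <- synth_spec(seed = 8, n_models = 2)
  ens <- make_ensemble(sp)$ensemble
  fit_masked <- kabsch_superpose(ens$members[[1]], ens$members[[2]],
                                 mask = default_core_mask())
  expect_lt(fit_masked$n_atoms, 114 * 4)
})
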