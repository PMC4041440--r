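test_that("extinction coefficient follows the Pace composition rule", {
  expect_equal(extinction_coefficient("AYAYAYAY"), 4 * 1490)
  expect_equal(extinction_coefficient("GGGG"), 0)
  expect_equal(extinction_coefficient("WY"), 5500 + 1490)
  expect_equal(extinction_coefficient("WY", n_cystine = 2),
               5500 + 1490 + 250)
  expect_error(extinction_coefficient("A", n_cystine = -1))
})

test_that("average mass matches the residue-mass table plus one water", {
  expect_equal(average_mass("G"), 75.07, tolerance = 0.02 / 75)
  expect_equal(average_mass("GG"), 132.12, tolerance = 0.02 / 132)
  expect_error(average_mass(""))
  expect_error(average_mass("GXZ"))
  # water term cancels in sequence differences: the increment of any
  # residue X equals its residue mass
  s <- "GAVLK"
  for (x in c("W", "P", "H", "E")) {
    inc <- average_mass(paste0(x, s)) - average_mass(s)
    expect_equal(inc, unname(ensdyn:::AA_AVG_MASS[x]), tolerance = 1e-9)
  }
})

test_that("missing-residue partition covers N-terminal, internal and C-terminal runs", {
  cons <- expected_construct(paste(rep("A", 127), collapse = ""),
                             first_resno = -12L)
  full <- toy_monomer(toy_cloud(127), resno = -12:114)
  expect_equal(unname(missing_residues(full, cons)), c(0, 0, 0))

  modeled <- c(1:47, 53:107)
  part <- toy_monomer(toy_cloud(length(modeled)), resno = modeled)
  mr <- missing_residues(part, cons)
  expect_equal(unname(mr), c(13, 5, 7))
  # the triple always sums to construct length minus modeled count
  expect_equal(sum(mr), 127 - length(modeled))

  outside <- toy_monomer(toy_cloud(3), resno = c(1, 2, 300))
  expect_error(missing_residues(outside, cons), "outside")
})

test_that("Matthews coefficient and solvent content behave as V_cell/(Z*M)", {
  # direct arithmetic case: V_M = 2.46 gives 50% solvent
  f <- crystal_form(100, 100, 100, space_group = "P 1", z_asu = 1,
                    asu_mass = 1e6 / 2.46)
  expect_equal(matthews(f)$solvent_fraction, 1 - 1.23 / 2.46,
               tolerance = 1e-9)
  # cubic sanity: 100 A cell, Z = 1, 1e5 Da
  f2 <- crystal_form(100, 100, 100, z_asu = 1, asu_mass = 1e5)
  expect_equal(matthews(f2)$v_m, 10)
  # invariance under joint scaling of volume and mass
  f3 <- crystal_form(100 * 2^(1/3), 100 * 2^(1/3), 100 * 2^(1/3),
                     z_asu = 1, asu_mass = 2e5)
  expect_equal(matthews(f3)$v_m, matthews(f2)$v_m, tolerance = 1e-9)
  # implausible contents flagged
  f4 <- crystal_form(30, 30, 30, z_asu = 1, asu_mass = 1e5)
  expect_warning(m4 <- matthews(f4), "implausible")
  expect_true(m4$implausible)
})

test_that("ensemble write/read round-trips coordinates and selections count monomers", {
  sp <- synth_spec(seed = 2, n_models = 2, chain_length = 20,
                   mobile_loops = list(list(interval = c(5, 8),
                                            sigma = 1)))
  ens <- make_ensemble(sp)$ensemble
  # fake a second chain by relabeling a shifted copy in each model
  mem2 <- lapply(ens$members, function(m) {
    m$chain_id <- "B"; m$atoms$x <- m$atoms$x + 50; m
  })
  both <- structure_ensemble(c(ens$members, mem2))
  path <- tempfile(fileext = ".pdb")
  # writer interleaves chains per model: build per-model members
  per_model <- structure_ensemble(list(
    both$members[[1]], both$members[[3]],
    both$members[[2]], both$members[[4]]))
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)
  expect_equal(length(back), length(ens))
  a0 <- ens$members[[1]]$atoms
  a1 <- back$members[[1]]$atoms
  expect_equal(a1$x, a0$x, tolerance = 2e-3)
  expect_equal(a1$y, a0$y, tolerance = 2e-3)
  expect_equal(a1$z, a0$z, tolerance = 2e-3)
  expect_equal(a1$resno, a0$resno)

  # selection semantics on a 2-model x 2-chain file
  path2 <- tempfile(fileext = ".pdb")
  con <- file(path2, "w")
  for (m in 1:2) {
    writeLines(sprintf("MODEL     %4d", m), con)
    eleno <- 0L
    for (ch in c("A", "B")) {
      mem <- both$members[[if (ch == "A") m else m + 2]]
      a <- mem$atoms
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        eleno + seq_len(nrow(a)), sprintf(" %-3s", a$elety), "ALA", ch,
        a$resno, a$x, a$y, a$z, a$o, a$b), con)
      eleno <- eleno + nrow(a)
    }
    writeLines("ENDMDL", con)
  }
  close(con)
  expect_equal(length(read_ensemble(path2)), 4)
  expect_equal(length(read_ensemble(path2, chains = "A")), 2)
  expect_error(read_ensemble(path2, chains = "Z"), "no monomers")
  expect_error(read_ensemble(tempfile(fileext = ".pdb")), "parse")
})

test_that("B-factor profile averages backbone atoms and flags inflated loops", {
  xyz <- toy_cloud(4)
  m <- monomer_model("1", "A", data.frame(
    resno = 1L, aa = "A", elety = c("N", "CA", "C", "O"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = c(10, 20, 30, 40), o = 1))
  prof <- bfactor_profile(structure_ensemble(list(m)))
  expect_equal(prof$mean, 25)

  flat <- toy_monomer(toy_cloud(10), b = 20)
  pf <- bfactor_profile(structure_ensemble(list(flat)),
                        atom_set = "CA")
  expect_true(all(pf$mean == 20))

  sp <- synth_spec(seed = 3, n_models = 4)
  infl <- make_ensemble(sp, b_inflate = list(residues = 64:70,
                                             delta = 30))$ensemble
  bp <- bfactor_profile(infl)
  peak <- bp$resno[bp$mean > 40]
  expect_true(all(peak %in% 64:70) && length(peak) == 7)
  # absent residues are NA, never 0
  del <- make_ensemble(synth_spec(seed = 3, n_models = 2),
                       deletions = list(`1` = 10:12))$ensemble
  bd <- bfactor_profile(del)
  expect_true(all(is.na(bd[[2]][bd$resno %in% 10:12])))
})
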