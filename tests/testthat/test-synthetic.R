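test_that("designs conserve atom counts, labels and composition", {
  spec <- design_spec("PAN01", "PAN", n_core_atoms = 12, n_drug_residues = 2,
                      n_ligand_residues = 0, atoms_per_residue = 5)
  snap <- make_design(spec, seed = 1)
  expect_equal(nrow(snap), 22)
  expect_equal(sum(snap$residue_name == "PAN"), 10)
  expect_equal(sum(snap$element == "Au"), 12)
  expect_identical(make_design(spec, seed = 1), snap)
  expect_false(identical(make_design(spec, seed = 2), snap))

  gem <- make_design(design_spec("G1", "GEM", n_core_atoms = 12,
                                 n_drug_residues = 2, n_ligand_residues = 1,
                                 atoms_per_residue = 5), seed = 3)
  expect_true("F" %in% residue_subset(gem, "GEM")$element)
  ncl <- make_design(design_spec("N1", "NCL", n_core_atoms = 12,
                                 n_drug_residues = 2, n_ligand_residues = 1,
                                 atoms_per_residue = 5), seed = 3)
  expect_true("Cl" %in% residue_subset(ncl, "NCL")$element)
})

test_that("frozen dynamics reproduce the initial snapshot at every step", {
  spec <- design_spec("Z1", "ZIL", n_core_atoms = 15, n_drug_residues = 2,
                      n_ligand_residues = 1, atoms_per_residue = 5)
  init <- make_design(spec, seed = 6)
  dyn <- dynamics_spec(T = 5, collapse_rate = 0, jitter_sigma = 0,
                       detach_prob = 0, seed = 9)
  sim <- simulate_trajectory(init, dyn, sasa_params(n_sphere_points = 240))
  expect_equal(unique(sim$trajectory$timestep), 0:4)
  for (t in 1:4) {
    st <- dplyr::filter(sim$trajectory, timestep == t)
    expect_equal(st[, c("x", "y", "z")],
                 dplyr::filter(sim$trajectory, timestep == 0)[, c("x", "y", "z")])
  }
  expect_equal(diff(range(sim$sasa$sasa)), 0)
})

test_that("compaction-only dynamics give a non-increasing SASA trend", {
  spec <- design_spec("C1", "CY5", n_core_atoms = 20, n_drug_residues = 4,
                      n_ligand_residues = 3, atoms_per_residue = 5)
  init <- make_design(spec, seed = 10)
  dyn <- dynamics_spec(T = 30, collapse_rate = 0.01, jitter_sigma = 0,
                       detach_prob = 0, seed = 11)
  sim <- simulate_trajectory(init, dyn, sasa_params(n_sphere_points = 240))
  s <- sim$sasa$sasa
  # monotone after burn-in, allowing tiny quadrature wobble
  expect_true(all(diff(s[-(1:2)]) <= 1e-6))
  expect_lt(tail(s, 1), s[1])
})

test_that("determinism: identical seeds give identical trajectories", {
  spec <- design_spec("W1", "WYC", n_core_atoms = 14, n_drug_residues = 2,
                      n_ligand_residues = 2, atoms_per_residue = 5)
  init <- make_design(spec, seed = 12)
  dyn <- dynamics_spec(T = 8, seed = 13)
  p <- sasa_params(n_sphere_points = 96)
  a <- simulate_trajectory(init, dyn, p)
  b <- simulate_trajectory(init, dyn, p)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$sasa, b$sasa)
})

test_that("datasets split 80:20 with a range-stratified test set", {
  ds <- make_dataset(n_designs = 10, duration_mix = 12, seed = 3,
                     dyn_template = dynamics_spec(T = 12),
                     params = sasa_params(n_sphere_points = 96))
  expect_equal(sum(ds$manifest$split == "train"), 8)
  expect_equal(sum(ds$manifest$split == "test"), 2)
  # temporal order preserved per design
  per <- ds$sasa |> dplyr::group_by(design_id) |>
    dplyr::summarise(ok = all(diff(timestep) == 1), n = dplyr::n())
  expect_true(all(per$ok))
  expect_true(all(per$n == 12))
  # test designs span distinct strata of the SASA-range midpoints
  mids <- (ds$manifest$sasa_min + ds$manifest$sasa_max) / 2
  test_mids <- mids[ds$manifest$split == "test"]
  expect_equal(length(unique(test_mids)), 2)
  med <- stats::median(mids)
  expect_true(min(test_mids) <= med && max(test_mids) >= med)

  # manifest is byte-identical under the same seeds
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_manifest(ds, f1)
  ds2 <- make_dataset(n_designs = 10, duration_mix = 12, seed = 3,
                      dyn_template = dynamics_spec(T = 12),
                      params = sasa_params(n_sphere_points = 96))
  write_manifest(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("compaction plants a descriptor feature correlated with SASA", {
  spec <- design_spec("P2", "PAN", n_core_atoms = 20, n_drug_residues = 4,
                      n_ligand_residues = 3, atoms_per_residue = 5)
  init <- make_design(spec, seed = 20)
  dyn <- dynamics_spec(T = 20, collapse_rate = 0.008, jitter_sigma = 0,
                       detach_prob = 0, seed = 21)
  sim <- simulate_trajectory(init, dyn, sasa_params(n_sphere_points = 240))
  enc <- encode_trajectory(sim$trajectory)
  m <- as.matrix(enc[, grep("^f", names(enc))])
  r <- suppressWarnings(as.vector(cor(m, sim$sasa$sasa)))
  expect_gt(max(abs(r), na.rm = TRUE), 0.5)
})
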