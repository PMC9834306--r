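test_that("geometry, broadening and weighting follow their closed forms", {
  expect_equal(g2_inverse_distance(c(0, 0, 0), c(0, 0, 2)), 0.5)
  expect_equal(g2_inverse_distance(c(0, 0, 0), c(1, 0, 0)), 1.0)
  expect_error(g2_inverse_distance(c(1, 1, 1), c(1, 1, 1)), "coincident")
  for (seed in 1:5) {
    p <- withr::with_seed(seed, matrix(rnorm(6, sd = 3), 2, 3))
    expect_equal(g2_inverse_distance(p[1, ], p[2, ]),
                 1 / sqrt(sum((p[1, ] - p[2, ])^2)), tolerance = 1e-12)
  }

  expect_equal(gaussian_broadening(0.3, 0.3, 0.5), 1 / (0.5 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(gaussian_broadening(0.3 + 0.07, 0.3, 0.1),
               gaussian_broadening(0.3 - 0.07, 0.3, 0.1))
  xg <- seq(-3, 4, by = 1e-3)  # density integrates to one
  dens <- gaussian_broadening(xg, 0.4, 0.25)
  expect_equal(sum((dens[-1] + dens[-length(dens)]) / 2) * 1e-3, 1,
               tolerance = 1e-4)

  expect_equal(pair_weight(1e-9), 1, tolerance = 1e-6)
  d_cut <- log(1 / 0.01) / 0.75
  expect_gt(pair_weight(d_cut - 1e-6), 0)
  expect_equal(pair_weight(d_cut + 1e-6), 0)
  d <- seq(0.1, d_cut - 0.01, length.out = 50)
  expect_true(all(diff(pair_weight(d)) < 0))
})

test_that("feature layout matches the pair-count formula", {
  expect_identical(feature_count(8, 2), 72L)
  expect_identical(feature_count(1, 1), 1L)
  expect_identical(feature_count(6, 3), 63L)
  info <- mbtr_feature_info(mbtr_config())
  expect_equal(nrow(info), 72)
  # blocks ordered lexicographically by atomic number, H-H first, Au-Au last
  expect_equal(info$pair[1], "H-H")
  expect_equal(info$pair[nrow(info)], "Au-Au")
  expect_equal(length(unique(info$pair)), 36)
})

test_that("single-pair snapshot matches its closed form", {
  snap <- tibble::tibble(element = c("C", "H"), residue_name = "LIG",
                         residue_id = 1L, x = 0, y = 0, z = c(0, 2))
  cfg <- mbtr_config()
  v <- encode_snapshot(snap, cfg)
  info <- mbtr_feature_info(cfg)
  expected <- exp(-0.75 * 2) * gaussian_broadening(c(0, 1), 0.5, 0.1)
  hc <- info$feature[info$pair == "H-C"]
  expect_equal(unname(v[hc]), expected, tolerance = 1e-12)
  expect_true(all(v[setdiff(names(v), hc)] == 0))
})

test_that("encoding equals the scalar brute-force reference", {
  for (seed in 1:6) {
    n <- withr::with_seed(seed, sample(10:50, 1))
    snap <- random_snapshot(n, seed = seed + 100)
    cfg <- mbtr_config()
    expect_equal(unname(encode_snapshot(snap, cfg)),
                 mbtr_brute_force(snap, cfg), tolerance = 1e-9)
  }
  # non-default configuration exercised too
  cfg3 <- mbtr_config(n_grid = 4, sigma2 = 0.2, normalize = TRUE)
  snap <- random_snapshot(25, seed = 9)
  expect_equal(unname(encode_snapshot(snap, cfg3)),
               mbtr_brute_force(snap, cfg3), tolerance = 1e-9)
})

test_that("encoding is invariant under permutation and rigid motion", {
  snap <- random_snapshot(30, seed = 21)
  cfg <- mbtr_config()
  v <- encode_snapshot(snap, cfg)
  perm <- withr::with_seed(1, snap[sample.int(nrow(snap)), ])
  expect_identical(unname(encode_snapshot(perm, cfg)), unname(v))
  moved <- rigid_motion(snap)
  expect_equal(unname(encode_snapshot(moved, cfg)), unname(v),
               tolerance = 1e-10)
})

test_that("pulling a pair apart never increases its block mass", {
  # on a grid fine and wide enough that the broadened density is fully
  # captured, the block mass tracks the (decreasing) pair weight; coarse
  # grids subsample the density and need not be monotone
  base <- tibble::tibble(element = c("C", "H"), residue_name = "LIG",
                         residue_id = 1L, x = 0, y = 0, z = c(0, 1.2))
  cfg <- mbtr_config(grid_min = -1, grid_max = 2, n_grid = 601)
  info <- mbtr_feature_info(cfg)
  hc <- info$feature[info$pair == "H-C"]
  masses <- sapply(seq(1.2, 8, by = 0.4), function(d) {
    s <- base
    s$z[2] <- d
    sum(encode_snapshot(s, cfg)[hc])
  })
  expect_true(all(diff(masses) <= 1e-12))
  expect_equal(masses[length(masses)], 0)  # beyond the weight cutoff
})

test_that("correlation scoring and grid selection behave as specified", {
  sasa <- c(5, 4.5, 4, 3, 2.8, 2, 1.5, 1, 0.7, 0.2)
  m <- cbind(sasa, sasa, sasa)
  expect_equal(grid_correlation_score(m, sasa), 100)
  expect_equal(grid_correlation_score(matrix(1, 10, 4), sasa), 0)
  m2 <- cbind(sasa, -sasa)
  expect_equal(grid_correlation_score(m2, sasa), 100)
  # hand-computed: one perfectly correlated column, one uncorrelated-ish
  noise <- withr::with_seed(4, rnorm(10))
  m3 <- cbind(sasa, noise)
  expect_equal(grid_correlation_score(m3, sasa),
               100 * (1 + abs(cor(noise, sasa))) / 2, tolerance = 1e-12)
  expect_error(grid_correlation_score(m[1:2, ], sasa[1:2]), "3 timesteps")

  # planted signal: SASA a linear function of geometry via compaction
  spec <- design_spec("GEM01", "GEM", n_core_atoms = 20,
                      n_drug_residues = 3, n_ligand_residues = 2,
                      atoms_per_residue = 5)
  init <- make_design(spec, seed = 2)
  sim <- simulate_trajectory(init, dynamics_spec(T = 15, jitter_sigma = 0,
                                                 detach_prob = 0, seed = 5),
                             sasa_params(n_sphere_points = 240))
  sel <- select_n_grid(sim$trajectory, sim$sasa, candidates = c(2, 3))
  expect_equal(nrow(sel$scores), 2)
  expect_true(all(sel$scores$score > 0))
  expect_true(sel$n_grid %in% c(2L, 3L))
  # single candidate trivially chosen; duplicated candidates tie toward the
  # smallest grid by the documented rule
  one <- select_n_grid(sim$trajectory, sim$sasa, candidates = 2)
  expect_identical(one$n_grid, 2L)
  dup <- select_n_grid(sim$trajectory, sim$sasa, candidates = c(3, 3))
  expect_identical(dup$n_grid, 3L)
})
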