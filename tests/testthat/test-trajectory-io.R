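test_that("PDB records parse to atoms with normalised elements", {
  line <- "ATOM      1  C1  PAN A   1       1.000   2.000   3.000  1.00  0.00           C"
  snap <- read_pdb_snapshot(c(line, sub(" C$", " H", sub("  1 ", "  2 ", line))))
  expect_equal(nrow(snap), 2)
  expect_equal(unname(unlist(snap[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(snap$residue_name[1], "PAN")

  au <- "HETATM    1 AU1  AUC A   1       0.000   0.000   0.000  1.00  0.00          AU"
  h <- "ATOM      2  H1  LIG A   2       2.000   0.000   0.000  1.00  0.00           H"
  snap2 <- read_pdb_snapshot(c(au, h))
  expect_equal(snap2$element, c("Au", "H"))
})

test_that("element inference falls back to the atom name, two-letter first", {
  # no element columns at all
  mk <- function(name) sprintf(
    "ATOM      1 %-4s LIG A   1       0.000   0.000   0.000  1.00  0.00",
    name)
  snap <- read_pdb_snapshot(c(mk("AU1"), mk("CL2"), mk("CA"), mk("HB1")))
  expect_equal(snap$element, c("Au", "Cl", "C", "H"))
})

test_that("malformed records and foreign elements raise informative errors", {
  good <- "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00           C"
  bad <- "ATOM      2  C2  LIG A   1       1.0x0   2.000   3.000  1.00  0.00           C"
  expect_error(read_pdb_snapshot(c(good, bad)), "line 2")
  xe <- "ATOM      2  XE  LIG A   1       1.000   2.000   3.000  1.00  0.00          XE"
  expect_error(read_pdb_snapshot(c(good, xe)), "XE")
  expect_error(read_pdb_snapshot("REMARK nothing here"), "ATOM")
})

test_that("PDB write/read round-trips snapshots to coordinate precision", {
  snap <- random_snapshot(20, seed = 11)
  back <- read_pdb_snapshot(write_pdb_snapshot(snap))
  expect_equal(back$element, snap$element)
  expect_equal(back$residue_name, snap$residue_name)
  expect_equal(back$residue_id, snap$residue_id)
  expect_equal(back$x, snap$x, tolerance = 1e-3)
  expect_equal(back$y, snap$y, tolerance = 1e-3)
  expect_equal(back$z, snap$z, tolerance = 1e-3)

  origin <- snap
  origin$x[1] <- 0; origin$y[1] <- 0; origin$z[1] <- 0
  expect_match(write_pdb_snapshot(origin)[1], "0.000   0.000   0.000")

  far <- snap
  far$x[1] <- 10500
  expect_error(write_pdb_snapshot(far), "overflow")
  empty_res <- snap
  empty_res$residue_name[1] <- " "
  expect_error(write_pdb_snapshot(empty_res), "residue")
})

test_that("written PDB files agree with an independent reader", {
  skip_if_not_installed("bio3d")
  snap <- random_snapshot(15, seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_snapshot(snap, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE),
               unname(as.matrix(snap[, c("x", "y", "z")])),
               tolerance = 1e-3)
  expect_equal(toupper(ref$atom$elesy), toupper(snap$element))
})

test_that("trajectories assemble from ordered files and reject mismatches", {
  snap <- random_snapshot(10, seed = 5)
  paths <- purrr::map_chr(1:3, function(i) {
    p <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame(3))
    write_pdb_snapshot(snap, p)
    p
  })
  traj <- load_trajectory(paths, design_id = "D1")
  expect_equal(unique(traj$timestep), 0:2)
  expect_equal(nrow(traj), 30)

  bigger <- dplyr::bind_rows(snap, snap[1, ])
  p4 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_snapshot(bigger, p4)
  expect_error(load_trajectory(c(paths, p4), "D1"), "atom count")
  expect_error(load_trajectory(paths, "D1", timesteps = c(0, 1, 3)),
               "consecutive|gap")
})

test_that("descriptor and SASA tables round-trip through CSV", {
  tbl <- toy_mbtr_table("A", T = 30, n_features = 72, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mbtr_table(tbl, path)
  back <- read_mbtr_table(path)
  expect_equal(ncol(back), 74)  # design_id, timestep, 72 features
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tbl[, -(1:2)]),
               tolerance = 1e-9)

  empty <- tbl[0, ]
  write_mbtr_table(empty, path)
  expect_equal(nrow(read_mbtr_table(path)), 0)
  expect_equal(length(readLines(path)), 1)  # header only

  sasa <- tibble::tibble(design_id = "A", timestep = 0:4, sasa = runif(5) * 1e4)
  ps <- withr::local_tempfile(fileext = ".csv")
  write_sasa_table(sasa, ps)
  expect_equal(read_sasa_table(ps), sasa, tolerance = 1e-9)
})
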