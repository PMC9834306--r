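# Seeded generator of nanoparticle-like trajectories. A gold core carries
# surface-anchored drug and ligand residues; toy dynamics (radial compaction
# of mobile residues, thermal jitter, occasional detachment) produce SASA
# series that predominantly decrease over time, giving every downstream
# stage learnable structure without any external data. This is not a force
# field: it emulates the shape of compaction dynamics, not their physics.

#' Drug-forming residue catalogue
#'
#' The nine drug residue codes with their element compositions and relative
#' hydrophobicity used to build synthetic designs.
#'
#' @return Tibble `residue`, `identity`, `hydrophobic`, `elements`
#'   (list-column of element symbols).
#' @export
drug_residues <- function() {
  tibble::tibble(
    residue = c("CY5", "DOX", "GEM", "NCL", "NHQ", "PAN", "WYC", "ZIL", "ZOR"),
    identity = c("CY5", "Doxorubicine", "Gemcitabine", "Niclosamide",
                 "Quinolinol", "Panobinostat", "Wyc-215", "Zileuton", "Zorac"),
    hydrophobic = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    elements = list(c("O", "C", "H", "N"), c("O", "C", "H", "N"),
                    c("O", "C", "H", "N", "F"), c("O", "C", "H", "Cl", "N"),
                    c("O", "C", "H", "N"), c("O", "C", "H", "N"),
                    c("N", "H", "C", "O", "S"), c("O", "C", "N", "H", "S"),
                    c("N", "H", "C", "O", "S")))
}

#' Specification of one nanoparticle design
#'
#' @param design_id Design identifier string.
#' @param drug_residue One of the nine [drug_residues()] codes.
#' @param n_core_atoms Number of gold core atoms.
#' @param n_drug_residues,n_ligand_residues Number of drug / ligand residue
#'   groups placed on the core surface.
#' @param atoms_per_residue Atoms per residue group (>= number of distinct
#'   elements in the drug's composition).
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(design_id, drug_residue = "PAN",
                        n_core_atoms = 60, n_drug_residues = 8,
                        n_ligand_residues = 10, atoms_per_residue = 6) {
  cat_tbl <- drug_residues()
  if (!drug_residue %in% cat_tbl$residue) {
    abort(paste0("unknown drug residue code: ", drug_residue))
  }
  stopifnot(n_core_atoms >= 12, n_drug_residues >= 1, n_ligand_residues >= 0,
            atoms_per_residue >= 1)
  comp <- cat_tbl$elements[[match(drug_residue, cat_tbl$residue)]]
  if (atoms_per_residue < length(comp)) {
    abort("atoms_per_residue smaller than the drug's element composition")
  }
  structure(list(design_id = design_id, drug_residue = drug_residue,
                 composition = comp,
                 hydrophobic = cat_tbl$hydrophobic[match(drug_residue,
                                                         cat_tbl$residue)],
                 n_core_atoms = as.integer(n_core_atoms),
                 n_drug_residues = as.integer(n_drug_residues),
                 n_ligand_residues = as.integer(n_ligand_residues),
                 atoms_per_residue = as.integer(atoms_per_residue)),
            class = "design_spec")
}

#' Toy dynamics specification
#'
#' @param T Number of timesteps (one per nanosecond); defaults to 120, with
#'   200 and 300 used in larger mixes.
#' @param collapse_rate Per-step inward radial drift fraction of attached
#'   mobile residues (compaction; drives SASA down).
#' @param jitter_sigma Thermal positional noise, Angstrom, applied afresh to
#'   non-gold atoms at each step (non-accumulating).
#' @param detach_prob Per-residue per-step probability of switching to
#'   outward diffusion.
#' @param seed RNG seed; trajectories are fully deterministic given it.
#' @return Object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(T = 120, collapse_rate = 0.004,
                          jitter_sigma = 0.05, detach_prob = 0.002,
                          seed = 1L) {
  stopifnot(T >= 1, collapse_rate >= 0, collapse_rate <= 1,
            jitter_sigma >= 0, detach_prob >= 0, detach_prob <= 1)
  structure(list(T = as.integer(T), collapse_rate = collapse_rate,
                 jitter_sigma = jitter_sigma, detach_prob = detach_prob,
                 seed = as.integer(seed)),
            class = "dynamics_spec")
}

#' Build the initial snapshot of a design
#'
#' Gold atoms sit on a spherical lattice (residue `AUC`); drug and ligand
#' residue groups (`LIG`: a thiol-anchored C/H/O cluster) are small clusters
#' anchored just outside the core surface in well-separated directions. Each
#' drug residue contains every element of its composition at least once.
#' Deterministic given the seed.
#'
#' @param spec A [design_spec()].
#' @param seed RNG seed.
#' @param max_retries Attempts to place a residue without atom overlap
#'   before raising a packing error.
#' @return Snapshot tibble with `design_id` and `timestep = 0`.
#' @export
make_design <- function(spec, seed = 1L, max_retries = 50L) {
  stopifnot(inherits(spec, "design_spec"))
  withr::local_seed(seed)

  core_r <- 1.45 * sqrt(spec$n_core_atoms)
  core <- sphere_points(spec$n_core_atoms) * core_r
  atoms <- tibble::tibble(
    element = "Au", residue_name = "AUC", residue_id = 1L,
    x = core[, 1], y = core[, 2], z = core[, 3])

  n_res <- spec$n_drug_residues + spec$n_ligand_residues
  lattice <- sphere_points(max(n_res, 12))
  anchors <- lattice[round(seq(1, nrow(lattice), length.out = n_res)), ,
                     drop = FALSE]
  kinds <- c(rep("drug", spec$n_drug_residues),
             rep("ligand", spec$n_ligand_residues))
  kinds <- sample(kinds)  # interleave drug and ligand positions

  residue_atoms <- function(kind, rid, anchor) {
    comp <- if (kind == "drug") spec$composition else c("S", "C", "H", "O")
    nm <- if (kind == "drug") spec$drug_residue else "LIG"
    k <- spec$atoms_per_residue
    els <- c(comp, sample(comp, max(0, k - length(comp)), replace = TRUE))
    els <- els[seq_len(k)]
    for (try in seq_len(max_retries)) {
      center <- anchor * (core_r + 3.0 + runif(1, 0, 1.5))
      off <- matrix(rnorm(3 * k, sd = 0.9), ncol = 3)
      pos <- sweep(off, 2, center, "+")
      dmin <- min(dist(pos))
      if (k == 1 || dmin > 0.8) {
        return(tibble::tibble(element = els, residue_name = nm,
                              residue_id = rid,
                              x = pos[, 1], y = pos[, 2], z = pos[, 3]))
      }
    }
    abort(paste0("packing error: residue ", rid,
                 " could not be placed without overlap"))
  }

  res <- purrr::imap(kinds, function(kind, i) {
    residue_atoms(kind, rid = i + 1L, anchor = anchors[i, ])
  })
  snap <- dplyr::bind_rows(atoms, dplyr::bind_rows(res))
  snap <- dplyr::mutate(snap, design_id = spec$design_id, timestep = 0L,
                        .before = 1)
  validate_snapshot(snap)
  snap
}

#' Simulate a toy trajectory with planted compaction dynamics
#'
#' At each step, every attached non-gold residue drifts radially inward by
#' `collapse_rate` (rigidly, toward the particle center), or — once detached
#' with probability `detach_prob` per step — random-walks outward. Fresh
#' Gaussian jitter of width `jitter_sigma` is added to all non-gold atoms of
#' the emitted snapshot. SASA is computed by the Shrake-Rupley oracle at
#' every step. Fully deterministic given `dyn$seed`.
#'
#' @param initial Snapshot from [make_design()] (timestep 0).
#' @param dyn A [dynamics_spec()].
#' @param params [sasa_params()] used for the ground-truth series.
#' @return List with `trajectory` (long atom tibble, timesteps `0..T-1`) and
#'   `sasa` (tibble `design_id`, `timestep`, `sasa`).
#' @export
simulate_trajectory <- function(initial, dyn = dynamics_spec(),
                                params = sasa_params()) {
  stopifnot(inherits(dyn, "dynamics_spec"))
  validate_snapshot(initial)
  withr::local_seed(dyn$seed)

  base <- initial
  center <- c(mean(base$x[base$element == "Au"]),
              mean(base$y[base$element == "Au"]),
              mean(base$z[base$element == "Au"]))
  mobile_ids <- unique(base$residue_id[base$element != "Au"])
  detached <- setNames(rep(FALSE, length(mobile_ids)), mobile_ids)

  emit <- function(b, t) {
    s <- b
    if (dyn$jitter_sigma > 0) {
      nm <- s$element != "Au"
      s$x[nm] <- s$x[nm] + rnorm(sum(nm), sd = dyn$jitter_sigma)
      s$y[nm] <- s$y[nm] + rnorm(sum(nm), sd = dyn$jitter_sigma)
      s$z[nm] <- s$z[nm] + rnorm(sum(nm), sd = dyn$jitter_sigma)
    }
    s$timestep <- as.integer(t)
    s
  }

  snaps <- vector("list", dyn$T)
  snaps[[1]] <- emit(base, 0L)
  if (dyn$T > 1) {
    for (t in seq(1L, dyn$T - 1L)) {
      for (rid in mobile_ids) {
        sel <- base$residue_id == rid & base$element != "Au"
        pos <- as.matrix(base[sel, c("x", "y", "z")])
        cen <- colMeans(pos)
        if (!detached[as.character(rid)] && runif(1) < dyn$detach_prob) {
          detached[as.character(rid)] <- TRUE
        }
        if (detached[as.character(rid)]) {
          dir <- cen - center
          dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
          shift <- dir * 0.3 + rnorm(3, sd = 0.1)
        } else {
          shift <- -(cen - center) * dyn$collapse_rate
        }
        moved <- sweep(pos, 2, shift, "+")
        base$x[sel] <- moved[, 1]
        base$y[sel] <- moved[, 2]
        base$z[sel] <- moved[, 3]
      }
      snaps[[t + 1L]] <- emit(base, t)
    }
  }
  trajectory <- dplyr::bind_rows(snaps)
  list(trajectory = trajectory, sasa = sasa_series(trajectory, params))
}

#' Generate a seeded multi-design dataset with a stratified split
#'
#' Designs cycle over the nine drug types with varied core and shell sizes;
#' each is simulated with [simulate_trajectory()]. The train/test split
#' preserves temporal order within designs (whole designs are assigned to
#' one side) and the test designs are chosen by stratifying on the midpoint
#' of each design's `(min, max)` SASA range so the test set spans the
#' observed SASA ranges.
#'
#' @param n_designs Number of designs (>= 5).
#' @param duration_mix Vector of trajectory lengths cycled over designs; the
#'   default keeps every design at 120 steps. Pass `c(300, 200, 120)` for a
#'   production-shaped mix of long and short trajectories.
#' @param seed Master seed; all per-design seeds derive from it.
#' @param test_frac Fraction of designs held out (default 0.2).
#' @param dyn_template [dynamics_spec()] whose rates apply to every design.
#' @param params [sasa_params()] for ground truth.
#' @return Object of class `np_dataset`: list with `trajectory` (long atom
#'   tibble, all designs), `sasa`, and `manifest` (tibble `design_id`,
#'   `drug`, `T`, `seed`, `n_atoms`, `sasa_min`, `sasa_max`, `split`).
#' @export
make_dataset <- function(n_designs = 12, duration_mix = 120, seed = 1L,
                         test_frac = 0.2, dyn_template = dynamics_spec(),
                         params = sasa_params()) {
  stopifnot(n_designs >= 5)
  drugs <- drug_residues()$residue
  withr::local_seed(seed)
  sizes <- tibble::tibble(
    design_id = sprintf("%s%02d", drugs[(seq_len(n_designs) - 1) %% 9 + 1],
                        seq_len(n_designs)),
    drug = drugs[(seq_len(n_designs) - 1) %% 9 + 1],
    T = duration_mix[(seq_len(n_designs) - 1) %% length(duration_mix) + 1],
    n_core = sample(c(40, 60, 80), n_designs, replace = TRUE),
    n_drug = sample(6:10, n_designs, replace = TRUE),
    n_ligand = sample(8:12, n_designs, replace = TRUE),
    seed = seed + 1000L * seq_len(n_designs))

  sims <- purrr::pmap(sizes, function(design_id, drug, T, n_core, n_drug,
                                      n_ligand, seed) {
    spec <- design_spec(design_id, drug_residue = drug, n_core_atoms = n_core,
                        n_drug_residues = n_drug, n_ligand_residues = n_ligand)
    init <- make_design(spec, seed = seed)
    dyn <- dyn_template
    dyn$T <- as.integer(T)
    dyn$seed <- seed + 1L
    simulate_trajectory(init, dyn, params)
  })

  trajectory <- dplyr::bind_rows(purrr::map(sims, "trajectory"))
  sasa <- dplyr::bind_rows(purrr::map(sims, "sasa"))

  ranges <- sasa |>
    dplyr::group_by(.data$design_id) |>
    dplyr::summarise(sasa_min = min(.data$sasa), sasa_max = max(.data$sasa),
                     .groups = "drop")
  manifest <- dplyr::left_join(sizes, ranges, by = "design_id") |>
    dplyr::mutate(n_atoms = .data$n_core +
                    (.data$n_drug + .data$n_ligand) * 6L)

  # stratified test choice: bin range midpoints, pick one design per stratum
  n_test <- max(1L, round(test_frac * n_designs))
  mid <- (manifest$sasa_min + manifest$sasa_max) / 2
  strata <- if (n_test == 1L) rep(1L, n_designs) else {
    cut(rank(mid, ties.method = "first"), breaks = n_test, labels = FALSE)
  }
  test_ids <- purrr::map_chr(seq_len(n_test), function(b) {
    ids <- manifest$design_id[strata == b]
    ids[ceiling(length(ids) / 2)]
  })
  manifest$split <- ifelse(manifest$design_id %in% test_ids, "test", "train")

  structure(list(trajectory = trajectory, sasa = sasa,
                 manifest = dplyr::select(manifest, "design_id", "drug", "T",
                                          "n_core", "n_drug", "n_ligand",
                                          "seed", "n_atoms", "sasa_min",
                                          "sasa_max", "split")),
            class = "np_dataset")
}

#' @export
print.np_dataset <- function(x, ...) {
  cat("<np_dataset> ", nrow(x$manifest), " designs (",
      sum(x$manifest$split == "train"), " train / ",
      sum(x$manifest$split == "test"), " test), ",
      nrow(x$sasa), " snapshots\n", sep = "")
  invisible(x)
}

#' Write a dataset manifest as JSON
#'
#' Byte-identical output for identical seeds, so runs are auditable.
#'
#' @param dataset An `np_dataset`.
#' @param path JSON file path.
#' @return The manifest tibble, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  jsonlite::write_json(dataset$manifest, path, digits = NA, pretty = TRUE)
  invisible(dataset$manifest)
}
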