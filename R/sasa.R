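# Shrake-Rupley solvent-accessible surface area. A deterministic
# golden-spiral point lattice is rolled over each atom's probe-expanded
# sphere; points shadowed by any neighbour's expanded sphere are
# inaccessible. The compiled inner loop lives in src/sasa.cpp.

#' SASA computation parameters
#'
#' @param probe_radius Solvent probe radius, Angstrom (water = 1.4).
#' @param n_sphere_points Number of test points per atom (>= 12); more points
#'   give smaller quadrature error.
#' @param vdw_radii Named vector of van der Waals radii (Angstrom) per
#'   element.
#' @return Object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4,
                        n_sphere_points = 960,
                        vdw_radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                                      S = 1.80, F = 1.47, Cl = 1.75,
                                      Au = 1.66)) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 12, all(vdw_radii > 0))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 vdw_radii = vdw_radii),
            class = "sasa_params")
}

#' Deterministic near-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice: point k sits at height
#' `z = 1 - 2(k + 0.5)/n` and azimuth `k` times the golden angle. Fully
#' deterministic, so SASA values are exactly reproducible.
#'
#' @param n Number of points, >= 12.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 12)
  k <- seq_len(n) - 1
  z <- 1 - 2 * (k + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Rotate/translate coordinates into a canonical pose (centroid at the
# origin, principal axes of the coordinate covariance aligned with the lab
# axes, signs fixed deterministically). The test-point lattice is fixed in
# the lab frame, so without this step a rigid rotation of the molecule
# could shift individual points across occlusion boundaries; in canonical
# pose the computation — and hence the SASA value — is identical for every
# rigid placement of the same structure (up to degenerate principal axes).
.canonical_pose <- function(coords) {
  coords <- sweep(coords, 2, colMeans(coords))
  if (nrow(coords) < 2) return(coords)
  ev <- eigen(crossprod(coords), symmetric = TRUE)
  R <- ev$vectors
  for (j in 1:3) {
    k <- which.max(abs(R[, j]))
    if (R[k, j] < 0) R[, j] <- -R[, j]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  coords %*% R
}

#' Total solvent-accessible surface area of a snapshot
#'
#' Shrake-Rupley: each atom's sphere of radius `r_vdw + probe` is sampled at
#' `n_sphere_points` lattice points; a point is accessible iff it lies
#' outside every other atom's expanded sphere. Per-atom SASA is
#' `4 pi (r_vdw + probe)^2` times the accessible fraction.
#'
#' @param snapshot Valid snapshot table (see [validate_snapshot()]).
#' @param params A [sasa_params()].
#' @return List of class `sasa_value`: `total` (Angstrom^2) and `per_atom`
#'   (vector, one value per atom, summing to `total`).
#' @examples
#' snap <- tibble::tibble(
#'   element = c("C", "C"), residue_name = "LIG", residue_id = 1L,
#'   x = c(0, 100), y = 0, z = 0)
#' total_sasa(snap, sasa_params())$total # two disjoint spheres
#' @export
total_sasa <- function(snapshot, params = sasa_params()) {
  validate_snapshot(snapshot, vocabulary = names(params$vdw_radii),
                    min_atoms = 1)
  radii <- params$vdw_radii[snapshot$element]
  if (anyNA(radii)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(snapshot$element[is.na(radii)]), collapse = ", ")))
  }
  pts <- sphere_points(params$n_sphere_points)
  coords <- .canonical_pose(as.matrix(snapshot[, c("x", "y", "z")]))
  per_atom <- sasa_atom_areas(coords, unname(radii), params$probe_radius,
                              pts)
  structure(list(total = sum(per_atom), per_atom = per_atom),
            class = "sasa_value")
}

#' @export
print.sasa_value <- function(x, ...) {
  cat("<sasa_value> total ", format(x$total, digits = 8), " A^2 over ",
      length(x$per_atom), " atoms\n", sep = "")
  invisible(x)
}

#' SASA series of a trajectory
#'
#' @param trajectory Long atom table (see [load_trajectory()]).
#' @param params A [sasa_params()].
#' @return Tibble `design_id`, `timestep`, `sasa`.
#' @export
sasa_series <- function(trajectory, params = sasa_params()) {
  trajectory |>
    dplyr::group_by(.data$design_id, .data$timestep) |>
    dplyr::group_modify(function(atoms, key) {
      tibble::tibble(sasa = total_sasa(atoms, params)$total)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$design_id, .data$timestep)
}

#' Subset a snapshot to one residue type
#'
#' Keeps exactly the atoms whose `residue_name` matches, preserving order;
#' used to encode and model each residue separately for attribution.
#'
#' @param snapshot Snapshot (or long trajectory) table.
#' @param residue_name Residue code, e.g. `"PAN"`.
#' @return Filtered table of the same shape.
#' @export
residue_subset <- function(snapshot, residue_name) {
  out <- dplyr::filter(snapshot, .data$residue_name == !!residue_name)
  if (nrow(out) == 0) {
    abort(paste0("residue '", residue_name, "' absent from snapshot"))
  }
  out
}
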