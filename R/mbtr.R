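# Two-body MBTR descriptor: broadened inverse-distance distributions per
# element pair, exponentially down-weighted with distance, evaluated on a
# fixed grid and concatenated in a canonical pair order.

# atomic numbers for the supported element vocabulary
.element_z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, S = 16, Cl = 17, Au = 79)

#' Default element vocabulary
#'
#' The eight chemical elements occurring in gold-core drug-carrier
#' nanoparticle designs: a gold core, sulfur anchors, and H/C/O/N plus the
#' halogens F and Cl found in some drug residues. The vocabulary is fixed
#' across designs so that every descriptor vector lives in the same feature
#' space even when a particular design uses only 6-7 of the elements.
#'
#' @return Character vector of element symbols.
#' @export
mbtr_vocabulary <- function() {
  c("Au", "S", "H", "C", "O", "N", "F", "Cl")
}

#' MBTR descriptor configuration
#'
#' Parameters of the two-body many-body tensor representation. Pairwise
#' inverse distances (1/Angstrom) are broadened with a Gaussian kernel of
#' width `sigma2`, weighted by `exp(-weight_scale * distance)` (weights below
#' `weight_cutoff` are set to zero), and evaluated at `n_grid` points evenly
#' spaced on `[grid_min, grid_max]`.
#'
#' @param element_vocabulary Ordered element symbols; all atoms must use these.
#' @param n_grid Number of grid discretization points per element pair (>= 2).
#' @param grid_min,grid_max Grid range in 1/Angstrom; the default `[0, 1]`
#'   covers inverse distances for separations of 1 Angstrom and beyond.
#' @param sigma2 Gaussian broadening width (1/Angstrom), > 0.
#' @param weight_scale Exponential decay rate of the pair weight per Angstrom.
#' @param weight_cutoff Weights below this value are zeroed, truncating the
#'   descriptor to a finite neighbourhood (about 6.14 Angstrom at defaults).
#' @param normalize If `TRUE`, scale each descriptor vector to unit Euclidean
#'   norm.
#' @return An object of class `mbtr_config`.
#' @examples
#' cfg <- mbtr_config()
#' feature_count(length(cfg$element_vocabulary), cfg$n_grid)
#' @export
mbtr_config <- function(element_vocabulary = mbtr_vocabulary(),
                        n_grid = 2,
                        grid_min = 0,
                        grid_max = 1,
                        sigma2 = 0.1,
                        weight_scale = 0.75,
                        weight_cutoff = 1e-2,
                        normalize = FALSE) {
  if (!all(element_vocabulary %in% names(.element_z))) {
    abort(paste0("unsupported element(s) in vocabulary: ",
                 paste(setdiff(element_vocabulary, names(.element_z)),
                       collapse = ", ")))
  }
  if (anyDuplicated(element_vocabulary)) abort("duplicate vocabulary symbols")
  stopifnot(n_grid >= 2, grid_min < grid_max, sigma2 > 0,
            weight_scale > 0, weight_cutoff > 0, weight_cutoff < 1)
  structure(
    list(element_vocabulary = element_vocabulary, n_grid = as.integer(n_grid),
         grid_min = grid_min, grid_max = grid_max, sigma2 = sigma2,
         weight_scale = weight_scale, weight_cutoff = weight_cutoff,
         normalize = isTRUE(normalize)),
    class = "mbtr_config")
}

#' @export
print.mbtr_config <- function(x, ...) {
  cat("<mbtr_config> ", length(x$element_vocabulary), " elements, n_grid = ",
      x$n_grid, " on [", x$grid_min, ", ", x$grid_max, "] 1/A, sigma2 = ",
      x$sigma2, ", w2 = exp(-", x$weight_scale, " d), cutoff ",
      x$weight_cutoff, if (x$normalize) ", unit-norm" else "", "\n", sep = "")
  invisible(x)
}

mbtr_grid <- function(cfg) {
  seq(cfg$grid_min, cfg$grid_max, length.out = cfg$n_grid)
}

#' Canonical element-pair table for a vocabulary
#'
#' Unordered element pairs (Z1 <= Z2) ordered lexicographically by atomic
#' number; descriptor features are laid out in this block order.
#'
#' @param element_vocabulary Element symbols.
#' @return Tibble with columns `pair`, `el1`, `el2`, `z1`, `z2`, `block`.
#' @export
element_pairs <- function(element_vocabulary = mbtr_vocabulary()) {
  z <- .element_z[element_vocabulary]
  els <- element_vocabulary[order(z)]
  zs <- sort(unname(z))
  n <- length(els)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble::tibble(
    block = seq_len(nrow(idx)),
    el1 = els[idx[, "row"]], el2 = els[idx[, "col"]],
    z1 = zs[idx[, "row"]], z2 = zs[idx[, "col"]],
    pair = paste0(els[idx[, "row"]], "-", els[idx[, "col"]]))
}

#' Per-feature metadata of an MBTR configuration
#'
#' Maps each descriptor feature (in emitted order) to its element pair and
#' grid point. Feature names follow the columnar table convention `f0`,
#' `f1`, ...
#'
#' @param cfg An [mbtr_config()].
#' @return Tibble with one row per feature: `feature`, `pair`, `el1`, `el2`,
#'   `grid_index`, `grid_x`.
#' @export
mbtr_feature_info <- function(cfg = mbtr_config()) {
  pairs <- element_pairs(cfg$element_vocabulary)
  grid <- mbtr_grid(cfg)
  out <- tidyr::crossing(pairs, grid_index = seq_along(grid) - 1L) |>
    dplyr::arrange(.data$block, .data$grid_index)
  out$grid_x <- grid[out$grid_index + 1L]
  out$feature <- paste0("f", seq_len(nrow(out)) - 1L)
  dplyr::select(out, "feature", "pair", "el1", "el2", "grid_index", "grid_x")
}

#' Number of MBTR features
#'
#' `n_elements * (n_elements + 1) / 2` unordered element pairs, each
#' discretized at `n_grid` points. At the defaults (8 elements, 2 grid
#' points) this is 72.
#'
#' @param n_elements Number of elements in the vocabulary.
#' @param n_grid Grid discretization points per pair.
#' @return Integer feature count.
#' @examples
#' feature_count(8, 2) # 72
#' @export
feature_count <- function(n_elements, n_grid) {
  stopifnot(n_elements >= 1, n_grid >= 1)
  as.integer(n_elements * (n_elements + 1) / 2 * n_grid)
}

#' Inverse-distance geometry function
#'
#' The two-body geometry term: the reciprocal Euclidean distance between two
#' atoms, in 1/Angstrom.
#'
#' @param rl,rm Length-3 Cartesian coordinates (Angstrom).
#' @return Scalar 1/Angstrom.
#' @export
g2_inverse_distance <- function(rl, rm) {
  stopifnot(length(rl) == 3, length(rm) == 3)
  d <- sqrt(sum((rl - rm)^2))
  if (d == 0) abort("coincident atoms: inverse distance undefined")
  1 / d
}

#' Gaussian broadening kernel
#'
#' Evaluates a normal density with mean `center` and standard deviation
#' `sigma2` at each grid point; used to smear a scalar inverse distance over
#' the descriptor grid.
#'
#' @param x_grid Numeric grid (1/Angstrom).
#' @param center Scalar center (1/Angstrom).
#' @param sigma2 Broadening width, > 0.
#' @return Numeric vector, same length as `x_grid`.
#' @export
gaussian_broadening <- function(x_grid, center, sigma2) {
  stopifnot(sigma2 > 0)
  exp(-(x_grid - center)^2 / (2 * sigma2^2)) / (sigma2 * sqrt(2 * pi))
}

#' Exponential pair weight
#'
#' `exp(-s * distance)`, truncated to exactly zero once it falls below
#' `cutoff`. This confines the descriptor to a finite neighbourhood; at the
#' defaults (s = 0.75, cutoff = 1e-2) pairs farther apart than
#' `log(1/cutoff)/s ~ 6.14` Angstrom contribute nothing.
#'
#' @param distance Interatomic distance(s), Angstrom, > 0.
#' @param s Decay rate per Angstrom.
#' @param cutoff Truncation threshold in (0, 1).
#' @return Weight(s) in `[0, 1)`.
#' @export
pair_weight <- function(distance, s = 0.75, cutoff = 1e-2) {
  stopifnot(all(distance > 0))
  w <- exp(-s * distance)
  w[w < cutoff] <- 0
  w
}

# block index (into element_pairs order) for two element symbols
.pair_block_index <- function(e1, e2, vocab) {
  z <- .element_z[vocab]
  els <- vocab[order(z)]
  r1 <- match(e1, els)
  r2 <- match(e2, els)
  lo <- pmin(r1, r2)
  hi <- pmax(r1, r2)
  n <- length(els)
  # row-major position of (lo, hi) in the upper triangle incl. diagonal:
  # rows 1..lo-1 hold (n - r + 1) entries each
  (lo - 1L) * (n + 1L) - (lo - 1L) * lo / 2 + hi - lo + 1L
}

#' Encode a snapshot as a two-body MBTR vector
#'
#' For every unordered atom pair within the weight cutoff, the inverse
#' distance is broadened over the grid and added, weighted by
#' [pair_weight()], into the feature block of its unordered element pair.
#' Blocks are concatenated in the canonical [element_pairs()] order, grid
#' points varying fastest within a block. The encoding is invariant under
#' atom permutation and rigid motion by construction.
#'
#' @param snapshot Atom table: a data frame with columns `element`, `x`, `y`,
#'   `z` (one timestep; see [read_pdb_snapshot()]).
#' @param cfg An [mbtr_config()].
#' @return Named numeric vector of length
#'   `feature_count(n_elements, n_grid)`; names `f0` ... `f(n-1)`.
#' @examples
#' snap <- tibble::tibble(
#'   element = c("C", "H"), residue_name = "LIG", residue_id = 1L,
#'   x = c(0, 0), y = c(0, 0), z = c(0, 2))
#' encode_snapshot(snap, mbtr_config())
#' @export
encode_snapshot <- function(snapshot, cfg = mbtr_config()) {
  validate_snapshot(snapshot, vocabulary = cfg$element_vocabulary)
  vocab <- cfg$element_vocabulary
  # canonical atom order makes the floating-point accumulation, and hence
  # the emitted vector, exactly invariant under input permutation
  snapshot <- snapshot[order(match(snapshot$element, vocab), snapshot$x,
                             snapshot$y, snapshot$z), ]
  n_feat <- feature_count(length(vocab), cfg$n_grid)
  grid <- mbtr_grid(cfg)
  n_blocks <- length(vocab) * (length(vocab) + 1) / 2
  acc <- matrix(0, nrow = n_blocks, ncol = cfg$n_grid)

  coords <- as.matrix(snapshot[, c("x", "y", "z")])
  d <- as.matrix(dist(coords))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  dij <- d[ut]
  if (any(dij == 0)) abort("coincident atoms in snapshot")
  w <- pair_weight(dij, cfg$weight_scale, cfg$weight_cutoff)
  keep <- w > 0
  if (any(keep)) {
    ut <- ut[keep, , drop = FALSE]
    g2 <- 1 / dij[keep]
    w <- w[keep]
    blk <- .pair_block_index(snapshot$element[ut[, 1]],
                             snapshot$element[ut[, 2]], vocab)
    # npairs x n_grid broadened densities, weighted, summed into blocks
    dens <- vapply(grid, function(x) gaussian_broadening(x, g2, cfg$sigma2),
                   numeric(length(g2)))
    dens <- matrix(dens, nrow = length(g2)) * w
    sums <- rowsum(dens, group = blk)
    acc[as.integer(rownames(sums)), ] <- sums
  }
  v <- as.vector(t(acc))
  if (cfg$normalize) {
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  stopifnot(length(v) == n_feat)
  names(v) <- paste0("f", seq_len(n_feat) - 1L)
  v
}

#' Encode every snapshot of a trajectory table
#'
#' @param trajectory Long atom table with columns `design_id`, `timestep`,
#'   `element`, `x`, `y`, `z` (see [load_trajectory()]).
#' @param cfg An [mbtr_config()].
#' @return Tibble with columns `design_id`, `timestep`, `f0` ... `f(n-1)`,
#'   one row per snapshot, ordered by design then timestep.
#' @export
encode_trajectory <- function(trajectory, cfg = mbtr_config()) {
  trajectory |>
    dplyr::group_by(.data$design_id, .data$timestep) |>
    dplyr::group_modify(function(atoms, key) {
      tibble::as_tibble(as.list(encode_snapshot(atoms, cfg)))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$design_id, .data$timestep)
}

#' Correlation score between a descriptor series and SASA
#'
#' Mean absolute Pearson correlation between each descriptor feature and the
#' SASA series, expressed in percent. Constant feature columns contribute 0.
#'
#' @param mbtr_series Numeric matrix or descriptor tibble (feature columns
#'   `f*`), timesteps in rows.
#' @param sasa_series Numeric SASA vector, one value per row.
#' @return Scalar percent in `[0, 100]`.
#' @export
grid_correlation_score <- function(mbtr_series, sasa_series) {
  m <- .feature_matrix(mbtr_series)
  if (nrow(m) != length(sasa_series)) {
    abort("mbtr_series rows and sasa_series length differ")
  }
  if (nrow(m) < 3) abort("need at least 3 timesteps to correlate")
  r <- suppressWarnings(as.vector(cor(m, sasa_series)))
  r[is.na(r)] <- 0
  100 * mean(abs(r))
}

.feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  cols <- grep("^f[0-9]+$", names(x), value = TRUE)
  if (length(cols) == 0) abort("no feature columns f0..f(n-1) found")
  as.matrix(x[, cols])
}

#' Select the descriptor grid resolution by correlation with SASA
#'
#' Encodes every design at each candidate `n_grid`, scores each candidate by
#' the per-design [grid_correlation_score()] averaged over designs, and
#' returns the candidate with the highest score, breaking ties toward the
#' smallest grid (the smallest representation).
#'
#' @param trajectory Long atom table covering one or more designs.
#' @param sasa_table Tibble `design_id`, `timestep`, `sasa` matching the
#'   trajectory.
#' @param candidates Integer vector of candidate `n_grid` values.
#' @param cfg Base [mbtr_config()]; `n_grid` is overridden per candidate.
#' @return List with `n_grid` (chosen value) and `scores` (tibble `n_grid`,
#'   `score`).
#' @export
select_n_grid <- function(trajectory, sasa_table, candidates,
                          cfg = mbtr_config()) {
  stopifnot(length(candidates) >= 1)
  scores <- purrr::map_dbl(candidates, function(ng) {
    cfg_ng <- cfg
    cfg_ng$n_grid <- as.integer(ng)
    enc <- encode_trajectory(trajectory, cfg_ng)
    per_design <- enc |>
      dplyr::inner_join(sasa_table, by = c("design_id", "timestep")) |>
      dplyr::group_by(.data$design_id) |>
      dplyr::group_map(function(d, key) {
        grid_correlation_score(.feature_matrix(d), d$sasa)
      })
    mean(unlist(per_design))
  })
  tbl <- tibble::tibble(n_grid = as.integer(candidates), score = scores)
  best <- max(tbl$score)
  chosen <- min(tbl$n_grid[tbl$score == best])
  list(n_grid = chosen, scores = tbl)
}
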