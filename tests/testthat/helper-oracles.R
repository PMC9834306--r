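# Independent oracles and fixture builders. These deliberately avoid the
# package's vectorised code paths: the descriptor oracle is a scalar triple
# loop straight from the defining formulas, and the SASA oracle is a Monte
# Carlo estimate with random (not lattice) directions.

random_snapshot <- function(n_atoms, seed, box = 10,
                            vocabulary = mbtr_vocabulary()) {
  withr::with_seed(seed, {
    tibble::tibble(
      element = sample(vocabulary, n_atoms, replace = TRUE),
      residue_name = sample(c("PAN", "LIG", "AUC"), n_atoms, replace = TRUE),
      residue_id = sample(1:5, n_atoms, replace = TRUE),
      x = runif(n_atoms, 0, box),
      y = runif(n_atoms, 0, box),
      z = runif(n_atoms, 0, box))
  })
}

# O(N^2) scalar reference for the two-body descriptor
mbtr_brute_force <- function(snap, cfg) {
  pairs <- element_pairs(cfg$element_vocabulary)
  grid <- seq(cfg$grid_min, cfg$grid_max, length.out = cfg$n_grid)
  out <- numeric(nrow(pairs) * cfg$n_grid)
  n <- nrow(snap)
  for (l in seq_len(n - 1)) {
    for (m in seq(l + 1, n)) {
      d <- sqrt((snap$x[l] - snap$x[m])^2 + (snap$y[l] - snap$y[m])^2 +
                  (snap$z[l] - snap$z[m])^2)
      w <- exp(-cfg$weight_scale * d)
      if (w < cfg$weight_cutoff) w <- 0
      g2 <- 1 / d
      b <- which((pairs$el1 == snap$element[l] &
                    pairs$el2 == snap$element[m]) |
                   (pairs$el1 == snap$element[m] &
                      pairs$el2 == snap$element[l]))
      for (g in seq_along(grid)) {
        dens <- exp(-(grid[g] - g2)^2 / (2 * cfg$sigma2^2)) /
          (cfg$sigma2 * sqrt(2 * pi))
        out[(b - 1) * cfg$n_grid + g] <- out[(b - 1) * cfg$n_grid + g] +
          w * dens
      }
    }
  }
  if (cfg$normalize) {
    nr <- sqrt(sum(out^2))
    if (nr > 0) out <- out / nr
  }
  out
}

# Monte Carlo Shrake-Rupley with random directions
sasa_mc_reference <- function(snap, params, n_dirs = 3000, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(snap)
    coords <- as.matrix(snap[, c("x", "y", "z")])
    radii <- unname(params$vdw_radii[snap$element]) + params$probe_radius
    total <- 0
    for (i in seq_len(n)) {
      u <- matrix(rnorm(3 * n_dirs), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * radii[i], 2, coords[i, ], "+")
      acc <- rep(TRUE, n_dirs)
      for (j in setdiff(seq_len(n), i)) {
        dd <- rowSums(sweep(pts, 2, coords[j, ], "-")^2)
        acc <- acc & dd >= radii[j]^2
      }
      total <- total + 4 * pi * radii[i]^2 * mean(acc)
    }
    total
  })
}

# small synthetic descriptor table with smooth per-feature dynamics
toy_mbtr_table <- function(design_ids, T, n_features = 72, seed = 1,
                           noise_sd = 0.01) {
  withr::with_seed(seed, {
    purrr::map(design_ids, function(id) {
      t <- seq_len(T) - 1
      m <- sapply(seq_len(n_features), function(f) {
        sin(t / 15 + f / 3) + 0.002 * f * t / T + rnorm(T, sd = noise_sd)
      })
      colnames(m) <- paste0("f", seq_len(n_features) - 1)
      dplyr::bind_cols(tibble::tibble(design_id = id, timestep = t),
                       tibble::as_tibble(m))
    }) |> dplyr::bind_rows()
  })
}

rigid_motion <- function(snap, angles = c(0.3, -1.1, 0.7),
                         shift = c(5, -3, 12)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  R <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  xyz <- as.matrix(snap[, c("x", "y", "z")]) %*% t(R)
  snap$x <- xyz[, 1] + shift[1]
  snap$y <- xyz[, 2] + shift[2]
  snap$z <- xyz[, 3] + shift[3]
  snap
}
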