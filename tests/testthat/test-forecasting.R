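test_that("window construction counts samples and guards leakage", {
  tbl <- toy_mbtr_table(c("A", "B", "C"), T = 50, n_features = 5, seed = 1)
  ws <- build_window_dataset(tbl, 10)
  expect_equal(nrow(ws), 3 * 40)
  expect_true(all(ws$target_timestep >= 10))
  # windows end right before their target, never crossing designs
  i <- which(ws$design_id == "B")[1]
  expect_equal(nrow(ws$window[[i]]), 10)
  expect_equal(ws$target_timestep[i], 10L)

  one <- build_window_dataset(dplyr::filter(tbl, design_id == "A"), 10)
  expect_equal(nrow(one), 40)
  expect_error(build_window_dataset(dplyr::filter(tbl, design_id == "A"), 50),
               "A")
})

test_that("ensemble trains one model per feature and is deterministic", {
  tbl <- toy_mbtr_table(c("A", "B"), T = 40, n_features = 8, seed = 2)
  ws <- build_window_dataset(tbl, 6)
  b1 <- train_ensemble(ws, ensemble_spec(nrounds = 25), seed = 5)
  expect_length(b1$models, 8)
  expect_equal(nrow(b1$report), 8)
  p1 <- predict_next(b1, ws$window[[3]])
  expect_length(p1, 8)
  b2 <- train_ensemble(ws, ensemble_spec(nrounds = 25), seed = 5)
  expect_identical(p1, predict_next(b2, ws$window[[3]]))
  expect_error(predict_next(b1, ws$window[[1]][1:3, ]), "window")
})

test_that("constant features are learned exactly and windows memorised", {
  t <- 0:29
  tbl <- dplyr::bind_cols(
    tibble::tibble(design_id = "K", timestep = t),
    tibble::as_tibble(matrix(rep(c(2.5, -1, 0), each = 30), 30, 3,
                             dimnames = list(NULL, paste0("f", 0:2)))))
  ws <- build_window_dataset(tbl, 5)
  b <- train_ensemble(ws, ensemble_spec(nrounds = 10), seed = 1)
  p <- predict_next(b, ws$window[[1]])
  expect_equal(p, c(2.5, -1, 0), tolerance = 1e-6)
  ro <- rollout(b, ws$window[[1]], t = 30)
  expect_true(all(abs(sweep(as.matrix(ro$predicted[, -1]), 2,
                            c(2.5, -1, 0))) < 1e-6))

  # memorisation: a heavily trained ensemble reproduces training targets
  tbl2 <- toy_mbtr_table("M", T = 25, n_features = 4, seed = 3)
  ws2 <- build_window_dataset(tbl2, 5)
  b2 <- train_ensemble(ws2, ensemble_spec(nrounds = 150), seed = 1)
  got <- predict_next(b2, ws2$window[[7]])
  expect_equal(got, unname(ws2$target[[7]]), tolerance = 0.05)
})

test_that("per-feature models commute with feature permutation", {
  tbl <- toy_mbtr_table("A", T = 30, n_features = 4, seed = 4)
  ws <- build_window_dataset(tbl, 5)
  b <- train_ensemble(ws, ensemble_spec(nrounds = 20), seed = 2)
  w <- ws$window[[2]]
  perm <- c(3, 1, 4, 2)
  bp <- b
  bp$models <- b$models[perm]
  expect_equal(predict_next(bp, w[, perm]), predict_next(b, w)[perm],
               tolerance = 1e-12)
})

test_that("recovery on planted linear trends beats the noise floor", {
  sigma <- 0.05
  t <- 0:59
  m <- withr::with_seed(7, sapply(1:6, function(f) {
    0.02 * f * t + f + rnorm(60, sd = sigma)
  }))
  colnames(m) <- paste0("f", 0:5)
  tbl <- dplyr::bind_cols(tibble::tibble(design_id = "L", timestep = t),
                          tibble::as_tibble(m))
  ws <- build_window_dataset(tbl, 8)
  # interleaved split: tree models interpolate within the observed range
  idx <- withr::with_seed(9, sort(sample.int(nrow(ws), 40)))
  b <- train_ensemble(ws[idx, ], seed = 1, eval_samples = ws[-idx, ])
  expect_lt(mean(b$report$mae), 2 * sigma)
})

test_that("mae matches hand summation and enforces shapes", {
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(1:5 + 3, 1:5), 3)
  a <- withr::with_seed(1, matrix(rnorm(12), 3, 4))
  b <- withr::with_seed(2, matrix(rnorm(12), 3, 4))
  hand <- 0
  for (i in 1:3) for (j in 1:4) hand <- hand + abs(a[i, j] - b[i, j])
  expect_equal(mae(a, b), hand / 12, tolerance = 1e-12)
  expect_error(mae(1:4, 1:5), "shape")
  expect_error(mae(a, b[, 1:3]), "shape")
})

test_that("encoder gradients match finite differences", {
  spec <- encoder_spec(n_heads = 2, head_size = 3, dropout = 0,
                       ff_conv_filters = c(4, 1), epochs = 1)
  n <- 5
  w <- 4
  params <- withr::with_seed(3, nanosasa:::.enc_init(spec, n))
  X <- withr::with_seed(4, matrix(rnorm(w * n), w, n))
  y <- withr::with_seed(5, rnorm(n))
  loss <- function(p) {
    out <- nanosasa:::.enc_forward(p, spec, X)$out
    sum((out - y)^2)
  }
  cache <- nanosasa:::.enc_forward(params, spec, X)
  grads <- nanosasa:::.enc_backward(params, spec, cache,
                                    2 * (cache$out - y))
  eps <- 1e-6
  for (nm in c("Wo", "g1", "b2", "Wc1", "Wc2", "Wd", "bd")) {
    p <- params[[nm]]
    idx <- if (length(p) > 4) c(1, length(p)) else seq_along(p)
    for (k in idx) {
      pp <- params
      pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params
      pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4)
    }
  }
  for (h in 1:2) {
    for (nm in c("Wq", "Wk", "Wv")) {
      pp <- params
      pp[[nm]][[h]][1, 1] <- pp[[nm]][[h]][1, 1] + eps
      pm <- params
      pm[[nm]][[h]][1, 1] <- pm[[nm]][[h]][1, 1] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(grads[[nm]][[h]][1, 1], num, tolerance = 1e-4)
    }
  }
})

test_that("encoder trains, shrinks its loss, and trails the ensemble", {
  tbl <- toy_mbtr_table(c("A", "B"), T = 30, n_features = 6, seed = 6)
  ws <- build_window_dataset(tbl, 5)
  spec <- encoder_spec(n_heads = 2, head_size = 8, dropout = 0.1,
                       epochs = 12, lr = 2e-3)
  enc <- train_encoder_forecaster(ws, spec, seed = 4)
  expect_length(predict_next(enc, ws$window[[1]]), 6)
  expect_lt(mean(tail(enc$loss_trace, 3)), enc$loss_trace[1])

  ens <- train_ensemble(ws, ensemble_spec(nrounds = 60), seed = 4)
  expect_lt(one_step_mae(ens, ws), one_step_mae(enc, ws))
})
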