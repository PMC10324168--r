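test_that("victims output 2-class probabilities on the simplex", {
  for (head in c("maxpool", "temporal_conv", "lstm", "mixed_lstm")) {
    m <- fx_tiny_victim(head)
    set.seed(1)
    x <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
    p <- predict_proba(m, x)
    expect_equal(dim(p), c(1L, 2L))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("paper-shaped specs accept the canonical inputs", {
  mb <- build_victim(architecture_spec("maxpool", "beam"), seed = 1)
  p <- predict_proba(mb, array(0, c(5, 4, 22, 22)))
  expect_equal(rowSums(p), 1)
  me <- build_victim(architecture_spec("maxpool", "eeg"), seed = 1)
  p <- predict_proba(me, array(0, c(5, 22, 256)))
  expect_equal(rowSums(p), 1)
  # the beam stack stops at 32 channels; the eeg stack reaches 128
  expect_null(mb$params$cw7)
  expect_equal(ncol(me$params$cw7), 128L)
  expect_equal(ncol(mb$params$cw4), 32L)
  # shape validation
  expect_error(predict_proba(mb, array(0, c(5, 22, 256))), "shape mismatch")
})

test_that("batched and single predictions agree", {
  m <- fx_tiny_victim("mixed_lstm")
  set.seed(2)
  x <- array(rnorm(6 * 3 * 2 * 8 * 8), c(6, 3, 2, 8, 8))
  pb <- predict_proba(m, x, batch_size = 4)
  for (i in c(1, 4, 6)) {
    ps <- predict_proba(m, array(x[i, , , , ], c(3, 2, 8, 8)))
    expect_equal(unname(pb[i, ]), unname(ps[1, ]), tolerance = 1e-6)
  }
  expect_equal(predict_label(m, x), max.col(pb, ties.method = "first"))
})

test_that("input gradients match central finite differences", {
  for (head in c("maxpool", "lstm")) {
    m <- fx_tiny_victim(head)
    set.seed(3)
    x <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
    g <- loss_gradient(m, x, 2L)
    expect_equal(dim(g), dim(x))
    loss_at <- function(xx) {
      fw <- beamattack:::forward_victim(m, xx)
      beamattack:::xent_loss(fw$logits, 2L)$loss
    }
    set.seed(4)
    for (i in sample(length(x), 5)) {
      h <- 1e-5
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      fd <- (loss_at(xp) - loss_at(xm)) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-3)
    }
  }
})

test_that("a zero-weight head gives constant output and zero input gradient", {
  m <- fx_tiny_victim("maxpool")
  m$params$fw2 <- m$params$fw2 * 0
  m$params$fb2 <- c(0, 0)
  set.seed(5)
  x1 <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  x2 <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  expect_equal(predict_proba(m, x1), predict_proba(m, x2))
  expect_equal(max(abs(loss_gradient(m, x1, 1L))), 0)
})

test_that("training descends, is seed-reproducible, and records curves", {
  ds <- generate_dataset(synthetic_config(n_per_class = 10, t_slices = 3,
                                          n_channels = 8, seed = 6,
                                          spatial_focus = c("FP1", "F7", "F3")))
  spec <- architecture_spec("maxpool", "beam", t_slices = 3,
                            input_shape = c(8L, 8L, 4L), fc_width = 32L)
  mont <- build_montage(channels = chbmit_channels()[1:8])
  grd <- build_grid(mont, 8, 8)
  xb <- beams_of_samples(ds$x, mont, grd)
  cfg <- train_config(epochs = 4, seed = 7, patience = 0, batch_size = 8)
  m1 <- train_victim(build_victim(spec, seed = 7), list(x = xb, y = ds$y), cfg)
  expect_true(m1$trained)
  expect_equal(nrow(m1$metrics), 4L)
  expect_lt(m1$metrics$train_loss[4], m1$metrics$train_loss[1])
  # identical seeds and config give identical weights
  m2 <- train_victim(build_victim(spec, seed = 7), list(x = xb, y = ds$y), cfg)
  expect_identical(m1$params, m2$params)
  # broom-style accessors
  expect_s3_class(tidy(m1), "tbl_df")
  g <- glance(m1)
  expect_equal(g$epochs_run, 4L)
  expect_equal(g$head, "maxpool")
})

test_that("an untrained victim scores at chance on a balanced test set", {
  fresh <- build_victim(architecture_spec("maxpool", "beam"), seed = 99)
  ds <- generate_dataset(synthetic_config(n_per_class = 50, seed = 8))
  xb <- beams_of_samples(ds$x, fx_montage(), fx_grid())
  acc <- accuracy(predict_label(fresh, xb), as.integer(ds$y))
  # binomial 99% band around 0.5 at n = 100
  expect_gt(acc, 0.5 - 2.58 * sqrt(0.25 / 100) - 1e-9)
  expect_lt(acc, 0.5 + 2.58 * sqrt(0.25 / 100) + 1e-9)
})

test_that("victim checkpoints survive a JSON save/load round trip", {
  m <- fx_tiny_victim("temporal_conv")
  path <- tempfile(fileext = ".json")
  save_victim(m, path)
  m2 <- load_victim(path)
  set.seed(9)
  x <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  expect_equal(predict_proba(m2, x), predict_proba(m, x), tolerance = 1e-12)
})
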