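test_that("success rate and accuracy are simple ratios with guards", {
  expect_equal(success_rate(rep(FALSE, 100)), 0)
  expect_equal(success_rate(rep(TRUE, 10)), 1)
  # the reference test-set size: 702 of 1404 flips
  expect_equal(success_rate(rep(c(TRUE, FALSE), 702)), 0.5)
  expect_error(success_rate(logical(0)), "empty")
  expect_equal(accuracy(c(1, 1, 2), c(1, 1, 2)), 1)
  expect_equal(accuracy(c(1, 1), c(2, 2)), 0)
  expect_equal(accuracy(c(rep(1, 46), rep(2, 4)), rep(1, 50)), 0.92)
  expect_error(accuracy(integer(0), integer(0)), "empty")
  # order independence
  set.seed(21)
  f <- runif(50) > 0.5
  expect_equal(success_rate(f), success_rate(rev(f)))
})

test_that("distortion is the mean per-sample RMSE", {
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(distortion(x, x), 0)
  # single sample with element differences (3, 4): sqrt(12.5)
  expect_equal(distortion(c(3, 4), c(0, 0)), sqrt(12.5))
  # homogeneity: scaling differences by k scales DL by |k|
  y <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(distortion(x + 3 * y, x), 3 * distortion(x + y, x),
               tolerance = 1e-12)
  # symmetry
  expect_equal(distortion(x, y), distortion(y, x))
  # per-sample vector matches manual computation
  v <- distortion(x, y, per_sample = TRUE)
  expect_length(v, 3)
  expect_equal(v[2], sqrt(mean((x[2, , ] - y[2, , ])^2)))
})

test_that("the Gaussian baseline reports the empirical noise RMSE", {
  m <- fx_tiny_victim()
  set.seed(22)
  beams <- array(rnorm(8 * 3 * 2 * 8 * 8), c(8, 3, 2, 8, 8))  # ~1e4 elements
  y <- rep(1:2, 4)
  # at >= 1e5 elements the empirical RMSE is within 2% of sigma
  big <- array(rnorm(40 * 3 * 2 * 8 * 8), c(40, 3, 2, 8, 8))
  gb <- gaussian_baseline(m, big, rep(1:2, 20), sigma = 0.5, seed = 1)
  expect_equal(gb$report$dl_b, 0.5, tolerance = 0.02)
  expect_equal(dim(gb$perturbed), dim(big))
  # sigma = 0 degenerates to the clean evaluation
  gb0 <- gaussian_baseline(m, beams, y, sigma = 0, seed = 1)
  expect_equal(gb0$report$dl_b, 0)
  expect_equal(gb0$report$sr_flip, 0)
  expect_equal(gb0$report$acc, accuracy(predict_label(m, beams), y))
  # different seeds draw different noise at comparable RMSE
  gb1 <- gaussian_baseline(m, beams, y, sigma = 0.5, seed = 1)
  gb2 <- gaussian_baseline(m, beams, y, sigma = 0.5, seed = 2)
  expect_false(identical(gb1$perturbed, gb2$perturbed))
  expect_equal(gb1$report$dl_b, gb2$report$dl_b, tolerance = 0.1)
})

test_that("eval_report aggregates attack results tidily", {
  mk <- function(success, flip, dlb, dle) {
    structure(list(success = success, label_flip = flip, y_true = 1L,
                   pred_before = 1L, pred_after = if (success) 2L else 1L,
                   dl_b = dlb, dl_e = dle, method = "gpbeam"),
              class = "adversarial_result")
  }
  rep_ <- eval_report(list(mk(TRUE, TRUE, 0.3, 0.01), mk(FALSE, FALSE, 0.3, 0.02)))
  g <- glance(rep_)
  expect_equal(g$sr, 0.5)
  expect_equal(g$acc, 0.5)
  expect_equal(g$dl_b, 0.3)
  expect_equal(g$dl_e, 0.015)
  expect_equal(nrow(tidy(rep_)), 2)
})

test_that("transfer evaluation is exact for self-transfer and clean inputs", {
  m <- fx_small_trained_victim()
  te <- generate_dataset(synthetic_config(n_per_class = 4, seed = 36))
  y <- as.integer(te$y)
  # clean samples presented as "adversarial": no prediction can change
  tab <- transfer_eval(te$x, te$x, y, list(beam_self = m),
                       fx_montage(), fx_grid())
  expect_equal(tab$sr, 0)
  expect_equal(tab$input_kind, "beam")
  # sr for a genuinely perturbed set equals direct recomputation
  res <- lapply(1:4, function(i)
    attack_gpbeam(m, array(te$x[i, , , ], dim(te$x)[2:4]), y[i],
                  perturbation_config(epsilon = 0.5), fx_montage(), fx_grid()))
  adv <- array(0, dim(te$x[1:4, , , , drop = FALSE]))
  for (i in 1:4) adv[i, , , ] <- res[[i]]$adversarial_eeg
  tab2 <- transfer_eval(adv, te$x[1:4, , , , drop = FALSE], y[1:4],
                        list(source = m), fx_montage(), fx_grid())
  expect_equal(tab2$sr, mean(vapply(res, function(r) r$label_flip, TRUE)))
  expect_equal(tab2$sr_vs_truth, mean(vapply(res, function(r) r$success, TRUE)))
})
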