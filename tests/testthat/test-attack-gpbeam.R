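test_that("the frequency-domain imposition matches hand-derived values", {
  # single bin F = 3 + 4i: component shares 9/25 and 16/25
  F <- array(complex(real = 3, imaginary = 4), c(1, 1, 1, 1))
  Dp <- impose_on_frequency(F, array(1, c(1, 1, 1)))
  expect_equal(Re(Dp[1]), 3.36, tolerance = 1e-12)
  expect_equal(Im(Dp[1]), 4.64, tolerance = 1e-12)
  Dm <- impose_on_frequency(F, array(-1, c(1, 1, 1)))
  expect_equal(Re(Dm[1]), 2.64, tolerance = 1e-12)
  expect_equal(Im(Dm[1]), 3.36, tolerance = 1e-12)
})

test_that("zero perturbation leaves spectra exactly unchanged", {
  set.seed(13)
  F <- array(complex(real = rnorm(2 * 4 * 3 * 16),
                     imaginary = rnorm(2 * 4 * 3 * 16)), c(2, 4, 3, 16))
  F[1, 1, 1, 1:4] <- 0   # zero bins must be skipped, not NaN'd
  D <- impose_on_frequency(F, array(0, c(2, 4, 3)))
  expect_identical(D, F)
  # negative component signs are restored, not flipped
  F2 <- array(complex(real = -3, imaginary = 4), c(1, 1, 1, 1))
  D2 <- impose_on_frequency(F2, array(1, c(1, 1, 1)))
  expect_equal(Re(D2[1]), -3.36, tolerance = 1e-12)
  expect_error(impose_on_frequency(F, array(0, c(3, 4, 3))), "shape")
})

test_that("fgsm perturbations have the stated range and identity at eps 0", {
  m <- fx_small_trained_victim()
  te <- generate_dataset(synthetic_config(n_per_class = 2, seed = 30))
  s <- array(te$x[1, , , ], dim(te$x)[2:4])
  beams <- build_beams(decompose_sample(s)$power, fx_montage(), fx_grid())
  eta0 <- gen_beam_perturbation(m, beams, 1L, perturbation_config(epsilon = 0))
  expect_equal(eta0, array(0, dim(beams$values)))
  eta <- gen_beam_perturbation(m, beams, 1L, perturbation_config(epsilon = 0.3))
  expect_true(all(eta %in% c(-0.3, 0, 0.3)))
  # gradient-sign step increases the loss (first-order ascent)
  p0 <- predict_proba(m, beams$values)[1, 1]
  p1 <- predict_proba(m, beams$values +
                        gen_beam_perturbation(m, beams, 1L,
                          perturbation_config(epsilon = 0.05)))[1, 1]
  expect_lt(p1, p0 + 1e-9)
  # iterative variants stay inside the epsilon ball
  for (meth in c("ifgsm", "mifgsm", "pgd")) {
    cfg <- perturbation_config(meth, epsilon = 0.2, iterations = 3)
    e <- gen_beam_perturbation(m, beams, 1L, cfg)
    expect_lte(max(abs(e)), 0.2 + 1e-12)
  }
  expect_error(gen_beam_perturbation(m, beams, 1L,
                                     perturbation_config("nope")), "unknown")
})

test_that("a registered custom perturbation method is dispatched", {
  register_attack_method("half_eps", function(model, beam, y, cfg)
    array(cfg$epsilon / 2, dim(beam)))
  m <- fx_tiny_victim()
  set.seed(14)
  beam <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  e <- gen_beam_perturbation(m, beam, 1L,
                             perturbation_config("half_eps", epsilon = 0.4))
  expect_equal(e, array(0.2, dim(beam)))
})

test_that("reconstruct_eeg is the exact inverse on unperturbed spectra", {
  set.seed(15)
  x <- array(rnorm(5 * 22 * 256), c(5, 22, 256))
  dec <- decompose_sample(x)
  out <- reconstruct_eeg(x, dec$freq)
  expect_equal(dim(out), c(5L, 22L, 256L))
  expect_lt(max(abs(out - x)), 1e-6)
  expect_lt(attr(out, "imag_residue"), 1e-8)
})

test_that("attack_gpbeam composes the pipeline end to end", {
  m <- fx_small_trained_victim()
  te <- generate_dataset(synthetic_config(n_per_class = 3, seed = 31))
  y <- as.integer(te$y)
  s <- array(te$x[1, , , ], dim(te$x)[2:4])
  # eps = 0: the sample survives unchanged; success iff already misclassified
  r0 <- attack_gpbeam(m, s, y[1], perturbation_config(epsilon = 0),
                      fx_montage(), fx_grid())
  expect_lt(max(abs(r0$adversarial_eeg - s)), 1e-6)
  expect_equal(r0$success, r0$pred_before != y[1])
  expect_equal(r0$dl_e, 0, tolerance = 1e-10)
  # fgsm with no zero-gradient elements: RMSE of eta_beam is exactly eps
  r <- attack_gpbeam(m, s, y[1], perturbation_config(epsilon = 0.3),
                     fx_montage(), fx_grid())
  if (all(r$eta_beam != 0)) expect_equal(r$dl_b, 0.3, tolerance = 1e-12)
  expect_equal(dim(r$adversarial_eeg), c(5L, 22L, 256L))
  expect_s3_class(r, "adversarial_result")
})

test_that("the modified attack degenerates correctly at zero budgets", {
  mb <- fx_small_trained_victim()
  me <- build_victim(architecture_spec("maxpool", "eeg"), seed = 3)
  te <- generate_dataset(synthetic_config(n_per_class = 2, seed = 32))
  s <- array(te$x[2, , , ], dim(te$x)[2:4])
  # eps_e = 0 reduces to the plain dense attack
  r1 <- attack_modified(mb, me, s, 1L, eps_b = 0.3, eps_e = 0,
                        montage = fx_montage(), grid = fx_grid())
  r2 <- attack_gpbeam(mb, s, 1L, perturbation_config(epsilon = 0.3),
                      fx_montage(), fx_grid())
  expect_lt(max(abs(r1$adversarial_eeg - r2$adversarial_eeg)), 1e-6)
  # eps_b = 0 reduces to the pure EEG-space attack (carrier passes through)
  r3 <- attack_modified(mb, me, s, 1L, eps_b = 0, eps_e = 0.05,
                        montage = fx_montage(), grid = fx_grid())
  g <- loss_gradient(me, s, 1L)
  e_adv <- s + 0.05 * sign(g)
  expect_lt(max(abs(r3$adversarial_eeg - e_adv)), 1e-6)
  expect_error(attack_modified(me, me, s, 1L), "model kind mismatch")
})

test_that("identity chain and distortion respond monotonically to epsilon", {
  m <- fx_small_trained_victim()
  te <- generate_dataset(synthetic_config(n_per_class = 2, seed = 33))
  s <- array(te$x[3, , , ], dim(te$x)[2:4])
  dls <- vapply(c(0.1, 0.3, 0.5), function(eps) {
    attack_gpbeam(m, s, 2L, perturbation_config(epsilon = eps),
                  fx_montage(), fx_grid())$dl_e
  }, 1)
  expect_true(all(diff(dls) >= -1e-12))
})
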