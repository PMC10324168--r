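test_that("population initialization respects every gene range", {
  cfg <- de_config(NP = 50, N = 4, epsilon = 0.3, r = 100, overflow = FALSE)
  set.seed(16)
  pop <- init_population(cfg, t_slices = 5, n_channels = 22, n_bands = 4)
  expect_equal(dim(pop), c(50L, 4L, 6L))
  expect_true(all(pop[, , 1] >= 1 & pop[, , 1] <= 5))
  expect_true(all(pop[, , 2] >= 1 & pop[, , 2] <= 22))
  vmax <- round(0.3 * 100)
  expect_true(all(abs(pop[, , 3:6]) <= vmax))
  expect_true(all(pop == round(pop)))
  # overflow widens the value range by delta = C
  cfg_o <- de_config(NP = 50, N = 4, epsilon = 0.3, r = 100, overflow = TRUE)
  set.seed(16)
  pop_o <- init_population(cfg_o, 5, 22, 4)
  expect_true(max(abs(pop_o[, , 3:6])) > vmax)
  expect_true(all(abs(pop_o[, , 3:6]) <= vmax * 22))
  # same seed, same population
  set.seed(16)
  expect_identical(pop_o, init_population(cfg_o, 5, 22, 4))
})

test_that("individuals expand to sparse perturbations with last-wins overlap", {
  cfg <- de_config(N = 1, epsilon = 0.3, r = 100, overflow = FALSE)
  # zero genes -> zero array
  expect_equal(individual_to_eta(matrix(0L, 0, 6), cfg, 5, 22, 4),
               array(0, c(5, 4, 22)))
  # one gene at (t = 2, c = 5)
  ind <- matrix(c(2L, 5L, 10L, -10L, 0L, 10L), 1)
  eta <- individual_to_eta(ind, cfg, 5, 22, 4)
  expect_equal(eta[2, , 5], c(0.1, -0.1, 0, 0.1))
  expect_equal(sum(eta != 0), 3L)
  # duplicate (t, c): the later gene wins
  ind2 <- rbind(ind, matrix(c(2L, 5L, 20L, 0L, 0L, 0L), 1))
  eta2 <- individual_to_eta(ind2, cfg, 5, 22, 4)
  expect_equal(eta2[2, , 5], c(0.2, 0, 0, 0))
  # range bound |eta| <= eps * delta
  cfg_o <- de_config(N = 2, epsilon = 0.1, r = 100, overflow = TRUE)
  vmax <- round(0.1 * 100 * 22)
  ind3 <- matrix(c(1L, 1L, vmax, -vmax, vmax, vmax), 1)
  expect_lte(max(abs(individual_to_eta(ind3, cfg_o, 5, 22, 4))), 0.1 * 22)
})

test_that("perturbation overflow redistributes the hand-computed excess", {
  # C = 4, eps = 0.1, eta' = (0.18, 0, 0, 0), signs (+, +, -, +)
  eta_p <- array(c(0.18, 0, 0, 0), c(1, 1, 4))
  signs <- array(c(1, 1, -1, 1), c(1, 1, 4))
  out <- apply_overflow(eta_p, signs, 0.1, 4)
  expect_equal(as.numeric(out), c(0.1, 0.02, -0.02, 0.02))
  # no excess: clip is the identity on in-range input
  eta_s <- array(c(0.05, -0.1, 0, 0.02), c(1, 1, 4))
  expect_equal(apply_overflow(eta_s, signs, 0.1, 4), eta_s)
  # sup-norm bound always holds
  set.seed(17)
  for (i in 1:20) {
    e <- array(rnorm(5 * 4 * 22, sd = 0.5), c(5, 4, 22))
    s <- array(sign(rnorm(5 * 4 * 22)), c(5, 4, 22))
    expect_lte(max(abs(apply_overflow(e, s, 0.3, 22))), 0.3)
  }
})

test_that("selection is greedy: per-slot fitness never decreases", {
  cfg <- de_config(NP = 12, N = 3, epsilon = 0.3, r = 100, CR = 0.7,
                   overflow = FALSE, seed = 1)
  set.seed(18)
  pop <- init_population(cfg, 5, 22, 4)
  # cheap deterministic fitness: favours large total |v|
  fit_fn <- function(p) apply(abs(p[, , 3:6, drop = FALSE]), 1, sum) / 1000
  fit <- fit_fn(pop)
  for (g in 1:20) {
    st <- evolve_step(pop, fit, fit_fn, cfg, 5, 22)
    expect_true(all(st$fit >= fit - 1e-12))
    pop <- st$pop; fit <- st$fit
    expect_true(all(pop[, , 1] >= 1 & pop[, , 1] <= 5))
    expect_true(all(pop[, , 2] >= 1 & pop[, , 2] <= 22))
    expect_true(all(abs(pop[, , 3:6]) <= round(0.3 * 100)))
    expect_true(all(pop == round(pop)))
  }
})

test_that("CR = 0 makes evolution a population no-op", {
  cfg <- de_config(NP = 8, N = 3, epsilon = 0.3, r = 100, CR = 0,
                   overflow = FALSE)
  set.seed(19)
  pop <- init_population(cfg, 5, 22, 4)
  fit <- rep(0.5, 8)
  st <- evolve_step(pop, fit, function(p) rep(1, dim(p)[1]), cfg, 5, 22)
  # trials equal parents, so no replacement can change any genome
  expect_equal(unclass(st$pop)[], unclass(pop)[], ignore_attr = TRUE)
  expect_error(evolve_step(pop[1:3, , , drop = FALSE], fit[1:3],
                           function(p) rep(0, 3), cfg), "NP")
})

test_that("the DE attack terminates, is seeded, and bounds its output", {
  m <- fx_small_trained_victim()
  te <- generate_dataset(synthetic_config(n_per_class = 2, seed = 34))
  y <- as.integer(te$y)
  s <- array(te$x[3, , , ], dim(te$x)[2:4])
  cfg <- de_config(NP = 8, N = 3, epsilon = 0.3, max_generations = 4,
                   seed = 7)
  r1 <- attack_gpbeam_de(m, s, y[3], cfg, fx_montage(), fx_grid())
  expect_s3_class(r1, "adversarial_result")
  expect_lte(r1$generations, 4L)
  expect_lte(max(abs(r1$eta_p)), 0.3 + 1e-12)
  # deterministic rerun
  r2 <- attack_gpbeam_de(m, s, y[3], cfg, fx_montage(), fx_grid())
  expect_equal(r1$eta_p, r2$eta_p)
  expect_equal(r1$generations, r2$generations)
  expect_equal(r1$success, r2$success)
  # fitness trace is monotone in the best individual
  if (nrow(r1$trace) > 1) {
    expect_true(all(diff(r1$trace$best_fitness) >= -1e-12))
  }
})

test_that("an already-misclassified sample succeeds at generation zero", {
  m <- fx_small_trained_victim()
  te <- generate_dataset(synthetic_config(n_per_class = 2, seed = 35))
  s <- array(te$x[1, , , ], dim(te$x)[2:4])
  beams <- build_beams(decompose_sample(s)$power, fx_montage(), fx_grid())
  wrong <- 3L - predict_label(m, beams$values)   # label the clean pred misses
  r <- attack_gpbeam_de(m, s, wrong, de_config(NP = 8, N = 2, epsilon = 0.3),
                        fx_montage(), fx_grid())
  expect_true(r$success)
  expect_equal(r$generations, 0L)
  expect_equal(r$eta_p, array(0, dim(r$eta_p)))
  expect_equal(r$adversarial_eeg, s)
})

test_that("without overflow at most N*B power entries are perturbed", {
  cfg <- de_config(NP = 6, N = 5, epsilon = 0.3, r = 100, overflow = FALSE)
  set.seed(20)
  pop <- init_population(cfg, 5, 22, 4)
  for (i in 1:6) {
    eta <- individual_to_eta(matrix(pop[i, , ], 5), cfg, 5, 22, 4)
    expect_lte(sum(eta != 0), 5L * 4L)
  }
})
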