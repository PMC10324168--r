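#' Differential evolution attack configuration
#'
#' The sparse attack evolves a population of NP individuals, each a set of N
#' genes; a gene is an integer vector (t, c, v1..vB): one time slice, one
#' electrode, and B integer rhythm-power perturbations on the grid
#' `[-round(eps*r*delta), round(eps*r*delta)]`, divided by the amplification
#' factor r when applied. With perturbation overflow enabled the gene range
#' is widened by `delta = C` and any excess over epsilon is redistributed to
#' all electrodes with the sign pattern of the dense attack's perturbation,
#' then clipped to the epsilon-ball.
#'
#' @param NP Population size (>= 4).
#' @param N Genes per individual.
#' @param F Mutation scaling factor in \[0, 2\].
#' @param CR Crossover probability in \[0, 1\]. Note the update rule is
#'   implemented exactly as stated (no forced-crossover index), so `CR = 0`
#'   makes every generation a no-op.
#' @param r Integer amplification factor; `epsilon * r >= 1` required.
#' @param epsilon Perturbation budget.
#' @param overflow Enable perturbation overflow.
#' @param delta Gene range widening; defaults to C (22) with overflow, else 1.
#' @param overflow_in_fitness Apply overflow before fitness evaluation
#'   (default), or only when emitting the final perturbation.
#' @param max_generations Generation cap.
#' @param seed RNG seed.
#' @return A `de_config` list.
#' @export
de_config <- function(NP = 40L, N = 5L, F = 0.5, CR = 0.6, r = 100,
                      epsilon = 0.3, overflow = TRUE, delta = NULL,
                      overflow_in_fitness = TRUE, max_generations = 50L,
                      seed = 1L) {
  stopifnot(NP >= 4, N >= 0, F >= 0, F <= 2, CR >= 0, CR <= 1,
            epsilon >= 0, max_generations >= 1)
  if (r * epsilon < 1) stop("r * epsilon must be >= 1 (degenerate integer grid)")
  structure(list(NP = as.integer(NP), N = as.integer(N), F = F, CR = CR,
                 r = r, epsilon = epsilon, overflow = overflow,
                 delta = delta, overflow_in_fitness = overflow_in_fitness,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "de_config")
}

de_delta <- function(config, C) {
  config$delta %||% (if (config$overflow) C else 1)
}

de_vmax <- function(config, C) round(config$epsilon * config$r * de_delta(config, C))

#' Initialize a DE population
#'
#' Every field of every gene is drawn uniformly over its valid range:
#' t in \[1, T\], c in \[1, C\], v in `[-round(eps*r*delta),
#' round(eps*r*delta)]`.
#'
#' @param config A [de_config()].
#' @param t_slices,n_channels,n_bands Problem dimensions (T, C, B).
#' @return Integer array NP x N x (2 + B), class `de_population`.
#' @export
init_population <- function(config, t_slices = 5L, n_channels = 22L,
                            n_bands = 4L) {
  vmax <- de_vmax(config, n_channels)
  NP <- config$NP; N <- config$N; B <- n_bands
  pop <- array(0L, c(NP, N, 2L + B))
  pop[, , 1] <- sample.int(t_slices, NP * N, replace = TRUE)
  pop[, , 2] <- sample.int(n_channels, NP * N, replace = TRUE)
  pop[, , 2 + seq_len(B)] <- sample.int(2L * vmax + 1L, NP * N * B,
                                        replace = TRUE) - vmax - 1L
  structure(pop, class = "de_population",
            dims = c(T = t_slices, C = n_channels, B = B))
}

#' Expand one individual into a sparse rhythm-power perturbation
#'
#' Zeros everywhere except the genes' (t, , c) rows, which receive v / r.
#' When two genes address the same (t, c) pair the later gene wins.
#'
#' @param ind Integer matrix N x (2 + B) (one individual).
#' @param config A [de_config()].
#' @param t_slices,n_channels,n_bands Dimensions.
#' @return Numeric array T x B x C.
#' @export
individual_to_eta <- function(ind, config, t_slices = 5L, n_channels = 22L,
                              n_bands = 4L) {
  eta <- array(0, c(t_slices, n_bands, n_channels))
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = 1)
  for (g in seq_len(nrow(ind))) {
    eta[ind[g, 1], , ind[g, 2]] <- ind[g, 2 + seq_len(n_bands)] / config$r
  }
  eta
}

#' Redistribute perturbation overflow
#'
#' Within each (slice, band) row, the excess above epsilon summed over the
#' row's electrodes is divided by C and added to every electrode of that row
#' with the sign pattern of the dense attack's perturbation, then everything
#' is clipped to `[-epsilon, epsilon]`. Rows without any over-budget entry
#' are left unchanged (up to the clip), so the footprint of the overflow
#' scales with the number of rows the genes touch.
#'
#' @param eta_prime Sparse perturbation T x B x C.
#' @param eta_gpbeam Dense-attack perturbation T x B x C (the sign template).
#' @param epsilon Budget.
#' @param C Number of electrodes.
#' @return Numeric array T x B x C with sup-norm <= epsilon.
#' @export
apply_overflow <- function(eta_prime, eta_gpbeam, epsilon, C) {
  d <- dim(eta_prime)
  excess <- pmax(abs(eta_prime) - epsilon, 0)
  row_excess <- apply(excess, c(1, 2), sum)          # T x B
  out <- eta_prime + (array(row_excess, d) / C) * sign(eta_gpbeam)
  pmin(pmax(out, -epsilon), epsilon)
}

# batched fitness: returns list(fitness, pred) for every individual
de_eval_population <- function(pop, model_beam, P, ops, config, eta_gpbeam,
                               grid) {
  d <- attr(pop, "dims") %||% c(T = dim(P)[1], C = dim(P)[3], B = dim(P)[2])
  NP <- dim(pop)[1]
  Tn <- dim(P)[1]; B <- dim(P)[2]; C <- dim(P)[3]
  beams <- array(0, c(NP, Tn, B, grid$H, grid$W))
  for (i in seq_len(NP)) {
    eta <- individual_to_eta(matrix(pop[i, , ], dim(pop)[2]), config, Tn, C, B)
    if (config$overflow && config$overflow_in_fitness) {
      eta <- apply_overflow(eta, eta_gpbeam, config$epsilon, C)
    }
    Pm <- matrix(aperm(P + eta, c(3, 1, 2)), nrow = C)
    V <- ops$fwd %*% Pm
    beams[i, , , , ] <- aperm(array(V, c(grid$H, grid$W, Tn, B)), c(3, 4, 1, 2))
  }
  probs <- predict_proba(model_beam, beams)
  list(fitness = 1 - apply(probs, 1, max), pred = max.col(probs, ties.method = "first"))
}

de_valid_int <- function(v, t_slices, n_channels, vmax) {
  # round, then redraw uniformly within range on violation
  v <- round(v)
  N <- nrow(v)
  fix <- function(col, lo, hi) {
    bad <- v[, col] < lo | v[, col] > hi
    if (any(bad)) v[bad, col] <<- sample(seq.int(lo, hi), sum(bad),
                                         replace = TRUE)
  }
  fix(1, 1, t_slices)
  fix(2, 1, n_channels)
  for (b in 3:ncol(v)) fix(b, -vmax, vmax)
  v
}

#' One DE generation (mutation, crossover, greedy selection)
#'
#' For each slot i a donor `V = valid_int(X_r1 + F (X_r2 - X_r3))` is built
#' from three distinct other individuals; each gene of the trial vector U is
#' taken from V with probability CR, else from X_i; U replaces X_i only when
#' its fitness is strictly larger.
#'
#' @param pop A `de_population`.
#' @param fit Numeric vector of current fitnesses (parallel to `pop`).
#' @param fitness_fn Function(pop_array) -> numeric fitness vector,
#'   evaluating a whole candidate population.
#' @param config A [de_config()].
#' @param t_slices,n_channels Dimensions for the validity repair.
#' @return List with the next `pop`, its `fit`, and `replaced` flags.
#' @export
evolve_step <- function(pop, fit, fitness_fn, config, t_slices = 5L,
                        n_channels = 22L) {
  NP <- dim(pop)[1]
  if (NP < 4) stop("NP must be >= 4 (three distinct donors per target)")
  vmax <- de_vmax(config, n_channels)
  trial <- pop
  for (i in seq_len(NP)) {
    donors <- sample(setdiff(seq_len(NP), i), 3)
    V <- matrix(pop[donors[1], , ], dim(pop)[2]) +
      config$F * (matrix(pop[donors[2], , ], dim(pop)[2]) -
                  matrix(pop[donors[3], , ], dim(pop)[2]))
    V <- de_valid_int(V, t_slices, n_channels, vmax)
    U <- matrix(pop[i, , ], dim(pop)[2])
    take <- stats::runif(config$N) <= config$CR    # per-gene crossover
    U[take, ] <- V[take, ]
    trial[i, , ] <- U
  }
  fit_u <- fitness_fn(trial)
  replaced <- fit_u > fit
  out <- pop
  out[replaced, , ] <- trial[replaced, , ]
  list(pop = out, fit = ifelse(replaced, fit_u, fit), replaced = replaced)
}

#' Sparse differential-evolution attack on one EEG sample
#'
#' Evolves sparse integer perturbations of the rhythm power array against a
#' beam-input victim. Fitness of an individual is one minus the victim's
#' top-class probability on BEAMs built from the perturbed power array (with
#' overflow applied when enabled). Evolution stops as soon as any individual
#' flips the prediction away from the true label, or at the generation cap.
#' On success the winning perturbation is pushed through the frequency-
#' domain imposition and wavelet reconstruction to emit the adversarial EEG.
#'
#' Success follows the evolutionary stopping rule: the attack succeeds when
#' some individual's perturbed power array, mapped to BEAMs, flips the
#' victim's prediction away from the true label (`pred_after` is that
#' in-loop prediction, and `dl_b` the RMSE of the corresponding BEAM
#' change). The emitted adversarial EEG is additionally re-evaluated end to
#' end; its prediction is stored as `pred_after_emitted`.
#'
#' @param model_beam A trained beam-input `victim_model`.
#' @param sample Numeric array T x C x S.
#' @param y_true True class index.
#' @param config A [de_config()].
#' @param montage,grid Geometry.
#' @return An `adversarial_result` with extra fields `generations`,
#'   `trace` (per-generation fitness tibble), `individual` and
#'   `pred_after_emitted`.
#' @export
attack_gpbeam_de <- function(model_beam, sample, y_true, config = de_config(),
                             montage = build_montage(),
                             grid = build_grid(montage)) {
  dec <- decompose_sample(sample)
  P <- dec$power
  Tn <- dim(P)[1]; B <- dim(P)[2]; C <- dim(P)[3]
  ops <- beam_operators(montage, grid)
  beams <- build_beams(P, montage, grid)
  pred_clean <- predict_label(model_beam, beams$values)
  mk_result <- function(eta, adv, pred_after, pred_emitted, generations,
                        trace, ind) {
    structure(
      list(adversarial_eeg = adv, raw_eeg = sample, eta_beam = NULL,
           eta_p = eta,
           success = pred_after != y_true, label_flip = pred_after != pred_clean,
           pred_before = pred_clean, pred_after = pred_after,
           pred_after_emitted = pred_emitted, y_true = y_true,
           dl_b = rmse(beams$values -
                         build_beams(dec$power + eta, montage, grid)$values),
           dl_e = rmse(adv - sample),
           generations = generations, trace = trace, individual = ind,
           config = config, method = "gpbeam_de"),
      class = "adversarial_result"
    )
  }
  if (pred_clean != y_true) {
    # already misclassified: zero perturbation succeeds at generation 0
    return(mk_result(array(0, c(Tn, B, C)), sample, pred_clean, pred_clean,
                     0L, tibble::tibble(), NULL))
  }
  eta_gpbeam <- if (config$overflow) {
    eb <- gen_beam_perturbation(model_beam, beams, y_true,
                                perturbation_config("fgsm",
                                                    epsilon = config$epsilon))
    sample_perturbation(eb, montage, grid, method = "tps")
  } else NULL
  emit <- function(ind, pred_after, generations, trace) {
    eta <- individual_to_eta(ind, config, Tn, C, B)
    if (config$overflow) eta <- apply_overflow(eta, eta_gpbeam,
                                               config$epsilon, C)
    D <- impose_on_frequency(dec$freq, eta)
    adv <- reconstruct_eeg(sample, D)
    adv_beams <- build_beams(decompose_sample(adv)$power, montage, grid)
    pred_emitted <- predict_label(model_beam, adv_beams$values)
    mk_result(eta, adv, pred_after, pred_emitted, generations, trace, ind)
  }
  with_local_seed(config$seed, {
    pop <- init_population(config, Tn, C, B)
    ev <- de_eval_population(pop, model_beam, P, ops, config, eta_gpbeam, grid)
    fit <- ev$fitness
    pred <- ev$pred
    trace <- list(tibble::tibble(generation = 0L, best_fitness = max(fit),
                                 mean_fitness = mean(fit)))
    gen <- 0L
    while (!any(pred != y_true) && gen < config$max_generations) {
      gen <- gen + 1L
      last_eval <- NULL
      fitness_fn <- function(cand) {
        attr(cand, "dims") <- attr(pop, "dims")
        last_eval <<- de_eval_population(cand, model_beam, P, ops, config,
                                         eta_gpbeam, grid)
        last_eval$fitness
      }
      st <- evolve_step(pop, fit, fitness_fn, config, Tn, C)
      pred[st$replaced] <- last_eval$pred[st$replaced]
      pop <- st$pop; fit <- st$fit
      trace[[gen + 1L]] <- tibble::tibble(generation = gen,
                                          best_fitness = max(fit),
                                          mean_fitness = mean(fit))
    }
    flipped <- which(pred != y_true)
    tr <- dplyr::bind_rows(trace)
    best <- if (length(flipped) > 0) flipped[which.max(fit[flipped])]
            else which.max(fit)
    emit(matrix(pop[best, , ], dim(pop)[2]), pred[best], gen, tr)
  })
}
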