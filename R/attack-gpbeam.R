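#' Perturbation generator configuration
#'
#' @param method Perturbation generation algorithm: `"fgsm"` (one-step
#'   gradient sign), `"ifgsm"`, `"mifgsm"`, `"pgd"`, or any name registered
#'   with [register_attack_method()].
#' @param epsilon Perturbation budget (sup-norm), >= 0.
#' @param iterations Steps for the iterative methods.
#' @param step Per-iteration step size; default `epsilon / iterations`.
#' @param momentum Decay factor of the momentum method.
#' @param seed Seed (used by methods with random initialization, e.g. PGD).
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(method = "fgsm", epsilon = 0.3,
                                iterations = 10L, step = NULL,
                                momentum = 1.0, seed = 1L) {
  stopifnot(epsilon >= 0, iterations >= 1)
  structure(list(method = method, epsilon = epsilon,
                 iterations = as.integer(iterations),
                 step = step %||% (epsilon / iterations),
                 momentum = momentum, seed = as.integer(seed)),
            class = "perturbation_config")
}

.attack_registry <- new.env(parent = emptyenv())

#' Register a BEAM-space perturbation method
#'
#' The perturbation generation step is pluggable: any function
#' `f(model, beam, y_true, config)` returning a perturbation shaped like
#' `beam` can be registered under a method name and selected through
#' [perturbation_config()].
#'
#' @param name Method name.
#' @param fn Generator function.
#' @export
register_attack_method <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .attack_registry[[name]] <- fn
  invisible(name)
}

attack_method <- function(name) {
  fn <- .attack_registry[[name]]
  if (is.null(fn)) stop("unknown perturbation method: ", name)
  fn
}

fgsm_fn <- function(model, beam, y_true, config) {
  g <- loss_gradient(model, beam, y_true)
  config$epsilon * sign(g)
}

iterative_sign_fn <- function(use_momentum, random_start) {
  function(model, beam, y_true, config) {
    eps <- config$epsilon
    adv <- beam
    if (random_start && eps > 0) {
      adv <- adv + with_local_seed(config$seed,
        array(stats::runif(length(beam), -eps, eps), dim(beam)))
    }
    mom <- 0
    for (it in seq_len(config$iterations)) {
      g <- loss_gradient(model, adv, y_true)
      if (use_momentum) {
        mom <- config$momentum * mom + g / max(mean(abs(g)), 1e-12)
        g <- mom
      }
      adv <- adv + config$step * sign(g)
      adv <- pmin(pmax(adv, beam - eps), beam + eps)   # project to eps-ball
    }
    adv - beam
  }
}

register_attack_method("fgsm", fgsm_fn)
register_attack_method("ifgsm", iterative_sign_fn(FALSE, FALSE))
register_attack_method("mifgsm", iterative_sign_fn(TRUE, FALSE))
register_attack_method("pgd", iterative_sign_fn(FALSE, TRUE))

#' Generate a BEAM-space perturbation
#'
#' White-box perturbation of the BEAM tensor against a BEAM-input victim:
#' for FGSM, eta = epsilon * sign of the input gradient of the cross-entropy
#' loss at the true label; iterative variants take repeated sign steps
#' projected to the epsilon-ball.
#'
#' @param model A beam-input `victim_model`.
#' @param beam A `beam_tensor` or plain T x B x H x W array.
#' @param y_true True class index (1 or 2).
#' @param config A [perturbation_config()].
#' @return Perturbation array T x B x H x W; FGSM entries lie in
#'   `{-epsilon, 0, +epsilon}`.
#' @export
gen_beam_perturbation <- function(model, beam, y_true, config) {
  if (model$spec$input_kind != "beam") {
    stop("model is not a beam-input victim")
  }
  if (config$epsilon < 0) stop("epsilon must be >= 0")
  vals <- if (inherits(beam, "beam_tensor")) beam$values else beam
  if (config$epsilon == 0) return(array(0, dim(vals)))
  attack_method(config$method)(model, vals, y_true, config)
}

#' Impose a rhythm-power perturbation on frequency-domain rhythms
#'
#' Adds the power perturbation to each frequency bin of the corresponding
#' rhythm spectrum, splitting it between the real and imaginary components in
#' proportion to their squared magnitudes. The update operates on component
#' magnitudes: signed increments `sign(eta) * eta^2 * m^2 / (mR^2 + mI^2)`
#' are added to `mR = |Re F|` and `mI = |Im F|`, the results are clamped at
#' zero, and the original component signs are restored, so that `eta = 0`
#' leaves the spectrum exactly unchanged. Bins with both components zero are
#' left untouched.
#'
#' @param F Complex array T x B x C x S of rhythm spectra.
#' @param eta_p Numeric array T x B x C.
#' @return Complex array T x B x C x S (the perturbed spectra D).
#' @export
impose_on_frequency <- function(F, eta_p) {
  d <- dim(F)
  if (!all(dim(eta_p) == d[1:3])) stop("shape mismatch between F and eta_p")
  FR <- Re(F); FI <- Im(F)
  mR <- abs(FR); mI <- abs(FI)
  denom <- mR^2 + mI^2
  eta4 <- array(eta_p, d)                      # recycled along S (last axis)
  inc <- sign(eta4) * eta4^2
  zero <- denom == 0
  denom[zero] <- 1
  addR <- inc * mR^2 / denom; addR[zero] <- 0
  addI <- inc * mI^2 / denom; addI[zero] <- 0
  newR <- pmax(mR + addR, 0)
  newI <- pmax(mI + addI, 0)
  out <- sign(FR) * newR + 1i * sign(FI) * newI
  array(out, d)
}

#' Reconstruct an EEG sample from perturbed frequency rhythms
#'
#' The inverse half of the pipeline: each perturbed rhythm spectrum is taken
#' back to the time domain (inverse DFT), wavelet-packet decomposed, and its
#' in-band leaves are spliced into the decomposition of the raw slice; the
#' out-of-band leaves (DC and > 30 Hz) of the raw signal survive. The
#' spliced decomposition is inverted to give the adversarial EEG.
#'
#' @param raw Numeric array T x C x S, the raw EEG sample.
#' @param D Complex array T x B x C x S of (perturbed) rhythm spectra.
#' @param sample_rate,level,bands Transform configuration.
#' @return Numeric array T x C x S with attribute `imag_residue`, the largest
#'   imaginary part discarded after the inverse DFT (~1e-12 for spectra
#'   derived from real signals and real perturbations).
#' @export
reconstruct_eeg <- function(raw, D, sample_rate = 256, level = 8L,
                            bands = rhythm_bands()) {
  d <- dim(raw)
  Tn <- d[1]; C <- d[2]; S <- d[3]
  stopifnot(all(dim(D)[c(1, 3, 4)] == d), dim(D)[2] == nrow(bands))
  W <- wpt_matrix(S, level)
  flat <- matrix(aperm(raw, c(3, 1, 2)), nrow = S)      # S x (T*C)
  leaves <- W %*% flat
  residue <- 0
  for (b in seq_len(nrow(bands))) {
    Db <- matrix(aperm(D[, b, , , drop = FALSE], c(4, 1, 3, 2)), nrow = S)
    rhy <- stats::mvfft(Db, inverse = TRUE) / S
    residue <- max(residue, max(abs(Im(rhy))))
    lb <- W %*% Re(rhy)
    idx <- band_leaf_indices(bands$band[b], sample_rate, level, bands)
    leaves[idx, ] <- lb[idx, ]
  }
  out <- crossprod(W, leaves)
  res <- aperm(array(out, c(S, Tn, C)), c(2, 3, 1))
  attr(res, "imag_residue") <- residue
  res
}

rmse <- function(x) sqrt(mean(x^2))

#' Dense BEAM-space attack on one EEG sample
#'
#' The full dense attack: decompose the raw sample into rhythms and powers,
#' build its BEAMs, generate a white-box BEAM perturbation against the victim
#' (gradient sign by default), sample the perturbation back to
#' the electrodes, impose it on the frequency-domain rhythms, and
#' reconstruct the adversarial EEG. Success is evaluated by rebuilding BEAMs
#' from the adversarial EEG and passing them through the victim.
#'
#' @param model_beam A trained beam-input `victim_model`.
#' @param sample Numeric array T x C x S.
#' @param y_true True class index (1 or 2).
#' @param config A [perturbation_config()].
#' @param montage,grid Geometry (defaults: 22-electrode montage, 22 x 22
#'   grid).
#' @param sampling Grid-to-electrode resampling method for the perturbation
#'   image, see [sample_perturbation()]. The default `"tps"` is the literal
#'   reading (interpolate the grid image at each electrode); `"consistent"`
#'   uses the exact left inverse instead.
#' @return An `adversarial_result`: list with `adversarial_eeg` (T x C x S),
#'   `eta_beam`, `eta_p`, `success` (prediction after attack differs from
#'   `y_true`), `label_flip` (differs from the clean prediction),
#'   `pred_before`, `pred_after`, `dl_b` (RMSE of the BEAM perturbation),
#'   `dl_e` (RMSE of the EEG perturbation), and the configuration.
#' @export
attack_gpbeam <- function(model_beam, sample, y_true,
                          config = perturbation_config(),
                          montage = build_montage(), grid = build_grid(montage),
                          sampling = "tps") {
  dec <- decompose_sample(sample)
  beams <- build_beams(dec$power, montage, grid)
  pred_before <- predict_label(model_beam, beams$values)
  eta_beam <- gen_beam_perturbation(model_beam, beams, y_true, config)
  eta_p <- sample_perturbation(eta_beam, montage, grid, method = sampling)
  D <- impose_on_frequency(dec$freq, eta_p)
  adv <- reconstruct_eeg(sample, D)
  adv_beams <- build_beams(decompose_sample(adv)$power, montage, grid)
  pred_after <- predict_label(model_beam, adv_beams$values)
  structure(
    list(adversarial_eeg = adv, raw_eeg = sample, eta_beam = eta_beam,
         eta_p = eta_p,
         success = pred_after != y_true, label_flip = pred_after != pred_before,
         pred_before = pred_before, pred_after = pred_after, y_true = y_true,
         dl_b = rmse(eta_beam), dl_e = rmse(adv - sample),
         config = config, method = "gpbeam"),
    class = "adversarial_result"
  )
}

#' @export
print.adversarial_result <- function(x, ...) {
  cat("<adversarial_result> ", x$method,
      if (isTRUE(x$success)) " SUCCESS" else " no flip",
      "  pred ", x$pred_before, " -> ", x$pred_after,
      "  DL_B = ", signif(x$dl_b, 3), "  DL_E = ", signif(x$dl_e, 3),
      "\n", sep = "")
  invisible(x)
}

#' Dual-target (modified) dense attack
#'
#' Fuses an EEG-space adversarial sample with the BEAM-space attack so the
#' result is aggressive to both victim families: a gradient-sign attack
#' against the eeg-input victim produces the carrier signal E_adv, the
#' rhythm-power perturbation is computed by the dense BEAM attack (from the
#' raw sample by default), and the reconstruction splices the perturbed
#' rhythms into E_adv instead of the raw EEG, so E_adv's out-of-band content
#' survives.
#'
#' @param model_beam,model_eeg Trained victims of the two families.
#' @param sample Numeric array T x C x S.
#' @param y_true True class index.
#' @param eps_b BEAM-space budget (the dense attack's epsilon).
#' @param eps_e EEG-space budget for the carrier attack.
#' @param config Base [perturbation_config()]; its epsilon is overridden by
#'   `eps_b`.
#' @param montage,grid Geometry.
#' @param recompute_on_adv If `TRUE`, rhythm powers and the BEAM perturbation
#'   are recomputed from E_adv instead of the raw sample.
#' @return An `adversarial_result` with additional fields `pred_after_eeg`
#'   and `success_eeg` for the eeg-input victim.
#' @export
attack_modified <- function(model_beam, model_eeg, sample, y_true,
                            eps_b = 0.3, eps_e = 0.02,
                            config = perturbation_config(),
                            montage = build_montage(),
                            grid = build_grid(montage),
                            recompute_on_adv = FALSE) {
  if (model_beam$spec$input_kind != "beam" ||
      model_eeg$spec$input_kind != "eeg") {
    stop("model kind mismatch: need one beam-input and one eeg-input victim")
  }
  # carrier: EEG-space gradient-sign attack on the raw sample
  e_adv <- if (eps_e > 0) {
    g <- loss_gradient(model_eeg, sample, y_true)
    sample + eps_e * sign(g)
  } else sample
  carrier <- if (recompute_on_adv) e_adv else sample
  dec <- decompose_sample(carrier)
  beams <- build_beams(dec$power, montage, grid)
  cfg <- config
  cfg$epsilon <- eps_b
  cfg$step <- config$step %||% (eps_b / config$iterations)
  eta_beam <- gen_beam_perturbation(model_beam, beams, y_true, cfg)
  eta_p <- sample_perturbation(eta_beam, montage, grid, method = "tps")
  # impose on the carrier's own frequency rhythms and rebuild from E_adv
  dec_adv <- decompose_sample(e_adv)
  D <- impose_on_frequency(dec_adv$freq, eta_p)
  adv <- reconstruct_eeg(e_adv, D)
  adv_beams <- build_beams(decompose_sample(adv)$power, montage, grid)
  pred_before <- predict_label(model_beam,
                               build_beams(decompose_sample(sample)$power,
                                           montage, grid)$values)
  pred_after <- predict_label(model_beam, adv_beams$values)
  pred_after_eeg <- predict_label(model_eeg, adv)
  structure(
    list(adversarial_eeg = adv, raw_eeg = sample, eta_beam = eta_beam,
         eta_p = eta_p,
         success = pred_after != y_true, label_flip = pred_after != pred_before,
         pred_before = pred_before, pred_after = pred_after,
         pred_after_eeg = pred_after_eeg, success_eeg = pred_after_eeg != y_true,
         y_true = y_true, dl_b = rmse(eta_beam), dl_e = rmse(adv - sample),
         config = cfg, eps_e = eps_e, method = "modified_gpbeam"),
    class = "adversarial_result"
  )
}
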