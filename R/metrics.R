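#' Attack success rate
#'
#' Fraction of samples whose attack changed the prediction: R / S.
#'
#' @param flips Logical vector of per-sample success flags.
#' @return Scalar in \[0, 1\].
#' @export
success_rate <- function(flips) {
  if (length(flips) < 1) stop("empty success-flag set")
  mean(as.logical(flips))
}

#' Classification accuracy
#'
#' @param preds,labels Integer class indices (or factors with equal levels).
#' @return A / S, the fraction predicted correctly.
#' @export
accuracy <- function(preds, labels) {
  if (length(preds) < 1) stop("empty prediction set")
  stopifnot(length(preds) == length(labels))
  mean(as.integer(preds) == as.integer(labels))
}

#' Distortion level (mean per-sample RMSE)
#'
#' `DL = (1/S) * sum_s sqrt( (1/N) * sum_n (adv - raw)^2 )`: the root mean
#' squared element difference of each sample, averaged over samples. Applied
#' to BEAM tensors it is DL_B, to EEG samples DL_E.
#'
#' @param adv,raw Arrays with samples on the first axis (or two single
#'   samples of identical shape).
#' @param per_sample Return the per-sample RMSEs instead of their mean.
#' @return Non-negative scalar (or vector).
#' @export
distortion <- function(adv, raw, per_sample = FALSE) {
  stopifnot(length(adv) == length(raw), all(dim(adv) == dim(raw)))
  d <- adv - raw
  v <- if (is.null(dim(d))) rmse(d) else
    sqrt(rowMeans(matrix(d, nrow = dim(d)[1])^2))
  if (per_sample) v else mean(v)
}

#' Summarize a set of attack results
#'
#' @param results List of `adversarial_result` objects.
#' @return An `eval_report`; [tidy()] gives the per-sample records, and
#'   [glance()] the one-row summary (SR both against the true label and
#'   relative to the clean prediction, accuracy after attack, mean DL_B,
#'   mean DL_E).
#' @export
eval_report <- function(results) {
  per <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tibble::tibble(
      sample = i, method = r$method, y_true = r$y_true,
      pred_before = r$pred_before, pred_after = r$pred_after,
      success = r$success, label_flip = r$label_flip,
      dl_b = r$dl_b, dl_e = r$dl_e,
      generations = r$generations %||% NA_integer_
    )
  }))
  structure(list(per_sample = per), class = "eval_report")
}

#' @export
tidy.eval_report <- function(x, ...) x$per_sample

#' @export
glance.eval_report <- function(x, ...) {
  p <- x$per_sample
  tibble::tibble(
    n_samples = nrow(p),
    sr = mean(p$success),
    sr_flip = mean(p$label_flip),
    acc = mean(p$pred_after == p$y_true),
    dl_b = mean(p$dl_b, na.rm = TRUE),
    dl_e = mean(p$dl_e, na.rm = TRUE)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Gaussian-noise baseline on BEAM tensors
#'
#' The dense attack's baseline: element-wise N(0, sigma) noise added to the
#' BEAMs, evaluated through the victim. The reported DL_B is the empirical
#' RMSE of the noise actually drawn.
#'
#' @param model A beam-input `victim_model`.
#' @param beams Array N x T x B x H x W of clean BEAM samples.
#' @param y_true Integer class indices, length N.
#' @param sigma Noise standard deviation (the reference setting is 0.5).
#' @param seed RNG seed.
#' @return List with `perturbed` (same shape as `beams`) and `report`
#'   (one-row tibble: acc, sr, sr_flip, dl_b).
#' @export
gaussian_baseline <- function(model, beams, y_true, sigma = 0.5, seed = 1L) {
  stopifnot(sigma >= 0)
  noise <- with_local_seed(seed,
    array(stats::rnorm(length(beams), 0, sigma), dim(beams)))
  pert <- beams + noise
  pred_clean <- predict_label(model, beams)
  pred_noise <- predict_label(model, pert)
  y <- as.integer(rep_len(y_true, dim(beams)[1]))
  report <- tibble::tibble(
    sigma = sigma,
    acc = accuracy(pred_noise, y),
    sr = mean(pred_noise != y),
    sr_flip = mean(pred_noise != pred_clean),
    dl_b = distortion(pert, beams)
  )
  list(perturbed = pert, report = report)
}

#' BEAM tensors of a batch of EEG samples
#'
#' Convenience wrapper: rhythm decomposition and topographic interpolation of
#' every sample in a batch.
#'
#' @param x Array N x T x C x S of EEG samples.
#' @param montage,grid Geometry.
#' @return Array N x T x B x H x W.
#' @export
beams_of_samples <- function(x, montage = build_montage(),
                             grid = build_grid(montage)) {
  d <- dim(x)
  N <- d[1]
  ops <- beam_operators(montage, grid)
  first <- decompose_sample(array(x[1, , , ], d[2:4]))
  B <- dim(first$power)[2]
  out <- array(0, c(N, d[2], B, grid$H, grid$W))
  for (i in seq_len(N)) {
    P <- if (i == 1) first$power else
      decompose_sample(array(x[i, , , ], d[2:4]))$power
    Pm <- matrix(aperm(P, c(3, 1, 2)), nrow = d[3])
    V <- ops$fwd %*% Pm
    out[i, , , , ] <- aperm(array(V, c(grid$H, grid$W, d[2], B)), c(3, 4, 1, 2))
  }
  out
}

#' Transferability of adversarial EEG samples across victims
#'
#' Applies adversarial EEG samples crafted against a source model to a set of
#' target victims, each through its own input pipeline: beam-input targets
#' see the BEAMs rebuilt from the adversarial EEG, eeg-input targets see the
#' raw adversarial EEG. The success rate counts label changes relative to
#' each target's own clean prediction; `sr_vs_truth` counts flips away from
#' the true label.
#'
#' @param adv Array N x T x C x S of adversarial EEG samples.
#' @param raw Matching array of the raw samples.
#' @param y_true Integer class indices, length N.
#' @param targets Named list of `victim_model`s.
#' @param montage,grid Geometry.
#' @return Tibble with one row per target: `target`, `input_kind`, `acc`,
#'   `sr`, `sr_vs_truth`.
#' @export
transfer_eval <- function(adv, raw, y_true, targets,
                          montage = build_montage(),
                          grid = build_grid(montage)) {
  y <- as.integer(rep_len(y_true, dim(adv)[1]))
  need_beams <- any(vapply(targets, function(m) m$spec$input_kind == "beam",
                           logical(1)))
  if (need_beams) {
    adv_b <- beams_of_samples(adv, montage, grid)
    raw_b <- beams_of_samples(raw, montage, grid)
  }
  rows <- lapply(names(targets), function(nm) {
    m <- targets[[nm]]
    if (m$spec$input_kind == "beam") {
      pc <- predict_label(m, raw_b); pa <- predict_label(m, adv_b)
    } else {
      pc <- predict_label(m, raw); pa <- predict_label(m, adv)
    }
    tibble::tibble(target = nm, input_kind = m$spec$input_kind,
                   acc = accuracy(pa, y), sr = mean(pa != pc),
                   sr_vs_truth = mean(pa != y))
  })
  dplyr::bind_rows(rows)
}
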