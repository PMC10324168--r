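#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a BEAM tensor as a grid of topographic heat maps
#'
#' One tile per (time slice, rhythm), grey-masked outside the electrode hull
#' when `mask_hull = TRUE`.
#'
#' @param object A `beam_tensor`.
#' @param slices Time slices to show (default all).
#' @param mask_hull Blank the cells outside the electrode convex hull.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beam_tensor <- function(object, slices = NULL, mask_hull = FALSE,
                                 ...) {
  d <- dim(object$values)
  slices <- slices %||% seq_len(d[1])
  bands <- rhythm_bands()$band
  df <- purrr::map_dfr(slices, function(t) {
    purrr::map_dfr(seq_len(d[2]), function(b) {
      tibble::tibble(
        slice = t, band = bands[b],
        row = rep(seq_len(d[3]), times = d[4]),
        col = rep(seq_len(d[4]), each = d[3]),
        value = as.vector(object$values[t, b, , ]),
        inside = object$grid$inside_hull
      )
    })
  })
  if (mask_hull) df$value[!df$inside] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(band ~ slice,
                        labeller = ggplot2::labeller(
                          slice = function(x) paste("slice", x))) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "power")
}

#' Plot raw vs adversarial EEG traces of an attack result
#'
#' Overlays the raw and adversarial signal of one electrode (all slices
#' concatenated) and annotates the maximum absolute difference.
#'
#' @param object An `adversarial_result`.
#' @param electrode Electrode label (with `montage`) or channel index.
#' @param montage Optional `beam_montage` used to resolve the label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adversarial_result <- function(object, electrode = 1L,
                                        montage = NULL, ...) {
  c_idx <- electrode
  if (is.character(electrode)) {
    montage <- montage %||% build_montage()
    c_idx <- match(toupper(electrode), montage$names)
    if (is.na(c_idx)) stop("unknown electrode label: ", electrode)
  }
  d <- dim(object$raw_eeg)
  raw <- as.vector(t(object$raw_eeg[, c_idx, ]))
  adv <- as.vector(t(object$adversarial_eeg[, c_idx, ]))
  tt <- seq_along(raw) / d[3]
  df <- tibble::tibble(
    time = rep(tt, 2),
    value = c(raw, adv),
    signal = rep(c("raw", "adversarial"), each = length(raw))
  )
  lab <- if (is.character(electrode)) electrode else paste("channel", c_idx)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.9) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (z-units)",
      title = paste0(lab, ": max |difference| = ", {
        md <- max(abs(raw - adv))
        signif(if (md < 1e-12) 0 else md, 3)
      }),
      colour = NULL
    )
}

#' Training curves of a victim model
#'
#' @param model A trained `victim_model`.
#' @return A ggplot object of loss and accuracy per epoch.
#' @export
plot_training <- function(model) {
  m <- model$metrics
  if (is.null(m)) stop("model has no recorded training metrics")
  df <- tidyr::pivot_longer(m, -"epoch", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
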