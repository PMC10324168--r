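#' Experiment configuration
#'
#' A single structured description of a desk-scale experiment: synthetic
#' dataset sizes, victim architecture(s), attack settings and an epsilon
#' grid, all seeded. Can be read from / written to JSON so runs are
#' reproducible from a config file.
#'
#' @param n_train_per_class,n_test_per_class Synthetic dataset sizes.
#' @param data_seed,train_seed Seeds for generation and training.
#' @param victim_head,victim_input Victim architecture.
#' @param epochs Training epoch cap.
#' @param attack `"gpbeam"` or `"gpbeam_de"`.
#' @param method Perturbation method for the dense attack.
#' @param epsilons Epsilon grid.
#' @param n_attack Number of test samples attacked per epsilon.
#' @param attack_seed Seed for attack randomness.
#' @param gaussian_sigma Baseline noise level (NULL skips the baseline).
#' @param de Optional list of [de_config()] overrides for the sparse attack.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_train_per_class = 50L, n_test_per_class = 15L,
                              data_seed = 1L, train_seed = 1L,
                              victim_head = "maxpool", victim_input = "beam",
                              epochs = 8L, attack = "gpbeam", method = "fgsm",
                              epsilons = c(0.1, 0.3, 0.5), n_attack = 10L,
                              attack_seed = 1L, gaussian_sigma = 0.5,
                              de = list()) {
  structure(as.list(environment()), class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file written by [write_experiment_config()].
#' @export
read_experiment_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- experiment_config()
  for (k in intersect(names(obj), names(cfg))) cfg[[k]] <- obj[[k]]
  cfg
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a desk-scale attack experiment
#'
#' The end-to-end harness: generate the synthetic dataset, train the victim,
#' run the configured attack over the epsilon grid on held-out samples,
#' optionally run the Gaussian-noise baseline, and write the metric tables
#' (CSV), the config and a manifest (JSON) to `out_dir`.
#'
#' @param config An [experiment_config()] or the path of its JSON file.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return List with `victim`, `results` (per-epsilon tibble), `baseline`,
#'   and `per_sample` records, invisibly writable to disk.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  montage <- build_montage()
  grid <- build_grid(montage)
  train <- stage("dataset", generate_dataset(synthetic_config(
    n_per_class = config$n_train_per_class, seed = config$data_seed)))
  test <- stage("dataset", generate_dataset(synthetic_config(
    n_per_class = config$n_test_per_class, seed = config$data_seed + 1L)))
  victim <- stage("victim", {
    spec <- architecture_spec(config$victim_head, config$victim_input)
    ds <- if (config$victim_input == "beam") {
      list(x = beams_of_samples(train$x, montage, grid), y = train$y)
    } else list(x = train$x, y = train$y)
    train_victim(build_victim(spec, seed = config$train_seed), ds,
                 train_config(epochs = config$epochs,
                              seed = config$train_seed))
  })
  n_test <- dim(test$x)[1]
  idx <- seq_len(min(config$n_attack, n_test))
  y <- as.integer(test$y)
  rows <- list(); per <- list()
  for (eps in config$epsilons) {
    res <- stage("attack", lapply(idx, function(i) {
      s <- array(test$x[i, , , ], dim(test$x)[2:4])
      if (config$attack == "gpbeam_de") {
        dc <- do.call(de_config, utils::modifyList(
          list(epsilon = eps, seed = config$attack_seed), config$de))
        attack_gpbeam_de(victim, s, y[i], dc, montage, grid)
      } else {
        attack_gpbeam(victim, s, y[i],
                      perturbation_config(config$method, epsilon = eps,
                                          seed = config$attack_seed),
                      montage, grid)
      }
    }))
    rep <- eval_report(res)
    g <- glance(rep)
    rows[[length(rows) + 1L]] <- dplyr::mutate(g, epsilon = eps,
                                               .before = 1)
    per[[length(per) + 1L]] <- dplyr::mutate(tidy(rep), epsilon = eps,
                                             .before = 1)
  }
  results <- dplyr::bind_rows(rows)
  baseline <- NULL
  if (!is.null(config$gaussian_sigma) && config$victim_input == "beam") {
    baseline <- stage("baseline", {
      bt <- beams_of_samples(test$x[idx, , , , drop = FALSE], montage, grid)
      gaussian_baseline(victim, bt, y[idx], sigma = config$gaussian_sigma,
                        seed = config$attack_seed)$report
    })
  }
  out <- list(victim = victim, results = results,
              per_sample = dplyr::bind_rows(per), baseline = baseline,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(out$per_sample, file.path(out_dir, "per_sample.csv"),
                     row.names = FALSE)
    if (!is.null(baseline)) {
      utils::write.csv(baseline, file.path(out_dir, "baseline.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(victim$metrics, file.path(out_dir, "training.csv"),
                     row.names = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(package = as.character(utils::packageVersion("beamattack")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           seeds = list(data = config$data_seed, train = config$train_seed,
                        attack = config$attack_seed)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(out)
}

#' Comparison plots for one attack result
#'
#' Writes (or returns) the visual comparison of a raw and adversarial
#' sample: overlaid EEG traces for one electrode and, when geometry is
#' supplied, the raw vs perturbed BEAM heat maps.
#'
#' @param result An `adversarial_result`.
#' @param electrode Electrode label or index for the trace view.
#' @param montage,grid Geometry (for the BEAM view; `NULL` skips it).
#' @param out_dir If non-NULL, PNGs are written there and paths returned.
#' @return Named list of ggplot objects (or written file paths).
#' @export
inspect_sample <- function(result, electrode = "FCZ",
                           montage = build_montage(),
                           grid = build_grid(montage), out_dir = NULL) {
  stopifnot(inherits(result, "adversarial_result"))
  plots <- list(
    eeg = autoplot(result, electrode = electrode, montage = montage)
  )
  if (!is.null(montage) && !is.null(grid)) {
    raw_b <- build_beams(decompose_sample(result$raw_eeg)$power, montage, grid)
    adv_b <- build_beams(decompose_sample(result$adversarial_eeg)$power,
                         montage, grid)
    plots$beam_raw <- autoplot(raw_b) + ggplot2::ggtitle("raw BEAMs")
    plots$beam_adv <- autoplot(adv_b) + ggplot2::ggtitle("adversarial BEAMs")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(names(plots), function(nm) {
      p <- file.path(out_dir, paste0(nm, ".png"))
      ggplot2::ggsave(p, plots[[nm]], width = 8, height = 5, dpi = 120)
      p
    }, "")
    return(paths)
  }
  plots
}
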