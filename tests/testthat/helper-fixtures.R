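# Shared fixtures. Everything is generated in code; the expensive trained
# victims are built once per test run and cached so the acceptance criteria
# can share them.

.fx <- new.env(parent = emptyenv())

fx_montage <- function() {
  if (is.null(.fx$montage)) .fx$montage <- build_montage()
  .fx$montage
}

fx_grid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- build_grid(fx_montage())
  .fx$grid
}

# small beam-input victim for mechanics tests (fast to build, untrained)
fx_tiny_spec <- function(head = "maxpool", kind = "beam") {
  architecture_spec(head, kind, t_slices = 3L,
                    input_shape = if (kind == "beam") c(8L, 8L, 2L)
                                  else c(16L, 32L, 1L),
                    fc_width = 16L, lstm_hidden = 8L, tconv_filters = 4L)
}

fx_tiny_victim <- function(head = "maxpool", kind = "beam", seed = 42L) {
  build_victim(fx_tiny_spec(head, kind), seed = seed)
}

# paper-shaped victim trained on a small synthetic set: enough to be a
# meaningful gradient source without the full acceptance-scale cost
fx_small_trained_victim <- function() {
  if (!is.null(.fx$small_victim)) return(.fx$small_victim)
  ds <- generate_dataset(synthetic_config(n_per_class = 40, seed = 5))
  xb <- beams_of_samples(ds$x, fx_montage(), fx_grid())
  m <- train_victim(build_victim(architecture_spec("maxpool", "beam"),
                                 seed = 5),
                    list(x = xb, y = ds$y),
                    train_config(epochs = 6, seed = 5, patience = 0))
  .fx$small_victim <- m
  m
}

# ---- acceptance-scale fixtures (shared across criteria 8-10) ---------------

fx_acc_train <- function() {
  if (is.null(.fx$acc_train)) {
    .fx$acc_train <- generate_dataset(synthetic_config(n_per_class = 400,
                                                       seed = 11))
  }
  .fx$acc_train
}

fx_acc_test <- function() {
  if (is.null(.fx$acc_test)) {
    .fx$acc_test <- generate_dataset(synthetic_config(n_per_class = 100,
                                                      seed = 12))
  }
  .fx$acc_test
}

fx_acc_test_beams <- function() {
  if (is.null(.fx$acc_test_beams)) {
    .fx$acc_test_beams <- beams_of_samples(fx_acc_test()$x, fx_montage(),
                                           fx_grid())
  }
  .fx$acc_test_beams
}

fx_acc_victim <- function() {
  if (!is.null(.fx$acc_victim)) return(.fx$acc_victim)
  tr <- fx_acc_train()
  xb <- beams_of_samples(tr$x, fx_montage(), fx_grid())
  m <- train_victim(build_victim(architecture_spec("maxpool", "beam"),
                                 seed = 1),
                    list(x = xb, y = tr$y),
                    train_config(epochs = 12, seed = 1, patience = 3))
  .fx$acc_victim <- m
  m
}

# eeg-input victim at reduced training size (transfer/modified criteria).
# The eeg conv stack is ~20x the flops of the beam stack, so it trains on a
# small set (which it overfits): confident on clean inputs yet adversarially
# fragile, the regime the transfer criteria probe, at desk-scale cost.
fx_acc_eeg_victim <- function() {
  if (!is.null(.fx$acc_eeg_victim)) return(.fx$acc_eeg_victim)
  tr <- generate_dataset(synthetic_config(n_per_class = 24, seed = 21))
  m <- train_victim(build_victim(architecture_spec("maxpool", "eeg"),
                                 seed = 2),
                    list(x = tr$x, y = tr$y),
                    train_config(epochs = 12, seed = 2, patience = 0,
                                 batch_size = 4))
  .fx$acc_eeg_victim <- m
  m
}

# minimal EDF writer for reader tests: plain EDF, int16 little-endian
write_mini_edf <- function(path, data, fs = 256, record_s = 1,
                           labels = paste0("CH", seq_len(nrow(data)))) {
  ns <- nrow(data)
  spr <- as.integer(fs * record_s)
  ndr <- ncol(data) %/% spr
  pad <- function(x, n) {
    s <- formatC(as.character(x), width = n, flag = "-")
    substr(s, 1, n)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  wr("0", 8); wr("patient", 80); wr("recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(ndr, 8); wr(record_s, 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  pmin_ <- -1000; pmax_ <- 1000; dmin_ <- -32768; dmax_ <- 32767
  for (i in seq_len(ns)) wr(pmin_, 8)
  for (i in seq_len(ns)) wr(pmax_, 8)
  for (i in seq_len(ns)) wr(dmin_, 8)
  for (i in seq_len(ns)) wr(dmax_, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round((data - pmin_) * (dmax_ - dmin_) / (pmax_ - pmin_) + dmin_)
  for (r in seq_len(ndr)) {
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, ((r - 1) * spr + 1):(r * spr)]),
               con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
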