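# Shared model caches so expensive training happens once per test run.

.model_cache <- new.env(parent = emptyenv())

# Tiny two-stage model for unit-level contracts (seconds to train; not
# expected to show the full behavioral phenomenology).
tiny_config <- function(epochs = 40) {
  rnn_config(n_hidden = 16, n_timesteps = 14, motion_onset = 3,
             motion_offset = 10, readout_window = 3, n_candidates = 12,
             task = task_config(coherences = c(0.5, 1)),
             n_train = 128, batch_size = 64, epochs = epochs, val_n = 64,
             mt_mae_gate = 60, dlpfc_r_gate = 0.5)
}

get_tiny_model <- function(seed = 1) {
  key <- paste0("tiny", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- suppressWarnings(
      train_two_stage(tiny_config(), seed = seed)
    )
  }
  .model_cache[[key]]
}

# Full default-scale model used by the acceptance suite.
get_full_model <- function(seed = 1) {
  key <- paste0("full", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- suppressWarnings(
      train_two_stage(rnn_config(), seed = seed)
    )
  }
  .model_cache[[key]]
}

# Hand-built module with known structure: unit i responds to input channel
# j with weight w; no recurrence.
manual_module <- function(U, Z, leak = 0.5, nonlinearity = "tanh") {
  H <- nrow(U)
  structure(
    list(W = matrix(0, H, H), U = U, Z = Z, b = numeric(H),
         c = numeric(nrow(Z)), leak = leak, n_in = ncol(U), n_hidden = H,
         n_out = nrow(Z), nonlinearity = nonlinearity, frozen = FALSE,
         training_log = NULL, converged = TRUE, tag = "manual"),
    class = "rnn_module"
  )
}

# Model whose MT unit 1 is cosine-tuned to direction 0 and unit 2 is
# untuned; the decision module just relays constant output.
manual_model <- function() {
  cfg <- tiny_config()
  U <- matrix(0, 4, 6)
  U[1, 1] <- 2            # unit 1 driven by cos(motion): prefers 0 deg
  U[3, 2] <- 2            # unit 3 prefers 90 deg
  U[4, 1] <- -2           # unit 4 prefers 180 deg
  mt <- manual_module(U, Z = diag(1, 6, 4), leak = cfg$leak)
  dl <- manual_module(matrix(0, 4, 6),
                      Z = matrix(0, cfg$n_candidates, 4), leak = cfg$leak)
  dl$tag <- "dlpfc_like"; mt$tag <- "mt_like"
  structure(list(mt = mt, dlpfc = dl, config = cfg, seed = 0),
            class = "popformat_model")
}
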