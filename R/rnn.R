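#' Configuration of the two-stage recurrent model
#'
#' Architecture, task interface, and training hyperparameters for the
#' sensory (MT-like) and decision (dlPFC-like) recurrent modules. Inputs
#' are 6 channels: the motion direction as a (cos, sin) pair scaled by
#' coherence with additive per-timestep Gaussian noise (SD =
#' `noise_sd_scale * (1 - coherence)`), and the increased- and
#' decreased-reward centers as noise-free (cos, sin) pairs. Reward-center
#' channels are on for the whole trial; motion channels are on during the
#' stimulus epoch `[motion_onset, motion_offset]`, mirroring target-ring
#' onset preceding motion onset and a post-stimulus delay before the
#' choice. The sensory module is trained to report motion and centers at
#' the end of the stimulus epoch (stimulus-locked); the decision module is
#' trained to report expected reward at the end of the trial, across the
#' delay, so that it must maintain the decision in its recurrent dynamics.
#'
#' The default scale (64 hidden units per module, 40 timesteps) is chosen
#' so that multi-seed training studies run at desk scale; all constants are
#' configurable.
#'
#' @param n_hidden Hidden units per module.
#' @param n_timesteps Trial length in timesteps.
#' @param leak Leak rate alpha in (0, 1] of the discrete-time dynamics.
#' @param motion_onset First timestep with motion input.
#' @param motion_offset Last timestep with motion input.
#' @param readout_window Number of timesteps averaged for each module's
#'   readout (ending at `motion_offset` for the sensory module and at
#'   `n_timesteps` for the decision module).
#' @param noise_sd_scale Motion-channel noise SD per unit of (1-coherence).
#' @param n_candidates Number of candidate choice directions K (>= 8).
#' @param task A [task_config()]; its coherence set is used for training.
#' @param n_train Training trials per epoch.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs per module.
#' @param lr Adam learning rate.
#' @param val_n Held-out validation trials.
#' @param mt_mae_gate Validation circular MAE (degrees) defining MT
#'   convergence.
#' @param dlpfc_r_gate Median held-out Pearson r defining dlPFC
#'   convergence.
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(n_hidden = 64, n_timesteps = 40, leak = 0.1,
                       motion_onset = 6, motion_offset = 30,
                       readout_window = 5,
                       noise_sd_scale = 0.5, n_candidates = 36,
                       task = task_config(coherences = c(0.2, 0.5, 1)),
                       n_train = 512, batch_size = 128, epochs = 400,
                       lr = 2e-3, val_n = 256, l2_act = 1e-3, l2_w = 1e-4,
                       l2_out = 2e-2, nonlinearity = c("tanh", "relu"),
                       mt_mae_gate = 10, dlpfc_r_gate = 0.9) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_hidden >= 2, n_timesteps > motion_onset, leak > 0, leak <= 1,
            motion_offset > motion_onset, motion_offset <= n_timesteps,
            readout_window >= 1, readout_window <= n_timesteps,
            n_candidates >= 8)
  structure(
    list(n_hidden = n_hidden, n_timesteps = n_timesteps, leak = leak,
         motion_onset = motion_onset, motion_offset = motion_offset,
         readout_window = readout_window,
         noise_sd_scale = noise_sd_scale, n_candidates = n_candidates,
         candidate_dirs = seq(0, 360 - 360 / n_candidates,
                              by = 360 / n_candidates),
         task = task, n_train = n_train, batch_size = batch_size,
         epochs = epochs, lr = lr, val_n = val_n,
         l2_act = l2_act, l2_w = l2_w, l2_out = l2_out,
         nonlinearity = nonlinearity,
         mt_mae_gate = mt_mae_gate, dlpfc_r_gate = dlpfc_r_gate),
    class = "rnn_config"
  )
}

new_rnn_module <- function(n_in, n_hidden, n_out, leak, tag,
                           nonlinearity = "tanh") {
  structure(
    list(
      W = matrix(stats::rnorm(n_hidden^2, sd = 1.2 / sqrt(n_hidden)),
                 n_hidden),
      U = matrix(stats::rnorm(n_hidden * n_in, sd = 1 / sqrt(n_in)),
                 n_hidden),
      Z = matrix(stats::rnorm(n_out * n_hidden, sd = 1 / sqrt(n_hidden)),
                 n_out),
      b = numeric(n_hidden), c = numeric(n_out),
      leak = leak, n_in = n_in, n_hidden = n_hidden, n_out = n_out,
      nonlinearity = nonlinearity, frozen = FALSE,
      training_log = NULL, converged = NA, tag = tag
    ),
    class = "rnn_module"
  )
}

apply_nonlin <- function(a, module) {
  switch(module$nonlinearity,
         identity = a,
         relu = pmax(a, 0),
         tanh(a))
}

# derivative of the nonlinearity expressed through its output
nonlin_deriv <- function(h, module) {
  switch(module$nonlinearity,
         identity = 1,
         relu = (h > 0) * 1,
         1 - h^2)
}

#' One step of the leaky recurrent dynamics
#'
#' `x' = (1 - alpha) * x + alpha * f(W x + U u + b)` with `f = tanh`
#' (an `"identity"` nonlinearity is supported for linear test modules).
#' Deterministic given its inputs.
#'
#' @param x State: vector of length `n_hidden` or batch x hidden matrix.
#' @param u Input: vector of length `n_in` or batch x input matrix.
#' @param module An `rnn_module`.
#' @return Next state, same shape as `x`.
#' @export
step_dynamics <- function(x, u, module) {
  stopifnot(inherits(module, "rnn_module"))
  vec <- is.null(dim(x))
  x <- rbind(x); u <- rbind(u)
  if (ncol(x) != module$n_hidden || ncol(u) != module$n_in ||
      nrow(x) != nrow(u)) {
    stop("state/input dimensions do not match the module")
  }
  a <- x %*% t(module$W) + u %*% t(module$U) +
    matrix(module$b, nrow(x), module$n_hidden, byrow = TRUE)
  out <- (1 - module$leak) * x + module$leak * apply_nonlin(a, module)
  if (vec) drop(out) else out
}

# Build per-timestep input matrices for a batch of trials.
# Returns a list of length n_timesteps of (B x 6) matrices.
make_inputs <- function(trials, config, noise = TRUE, perturb_none = NULL) {
  B <- nrow(trials)
  m <- deg2rad(trials$motion_deg)
  ic <- deg2rad(trials$inc_center_deg)
  dc <- deg2rad(trials$dec_center_deg)
  coh <- trials$coherence
  base_motion <- cbind(coh * cos(m), coh * sin(m))
  centers <- cbind(cos(ic), sin(ic), cos(dc), sin(dc))
  sds <- config$noise_sd_scale * (1 - coh)
  lapply(seq_len(config$n_timesteps), function(t) {
    mo <- if (t >= config$motion_onset && t <= config$motion_offset) {
      if (noise && any(sds > 0)) {
        base_motion + cbind(stats::rnorm(B, sd = sds), stats::rnorm(B, sd = sds))
      } else base_motion
    } else matrix(0, B, 2)
    cbind(mo, centers)
  })
}

# Forward pass over a batch. Returns final state, all states/outputs if
# requested, and per-timestep outputs for the requested channels.
# perturb: NULL or list(unit, strength, epoch = c(from, to)).
rnn_forward <- function(module, inputs, keep = FALSE, perturb = NULL) {
  T_ <- length(inputs)
  B <- nrow(inputs[[1]])
  H <- module$n_hidden
  alpha <- module$leak
  X <- matrix(0, B, H)
  states <- if (keep) vector("list", T_) else NULL
  tanhs <- if (keep) vector("list", T_) else NULL
  outs <- vector("list", T_)
  bmat <- matrix(module$b, B, H, byrow = TRUE)
  for (t in seq_len(T_)) {
    A <- X %*% t(module$W) + inputs[[t]] %*% t(module$U) + bmat
    if (!is.null(perturb) && t >= perturb$epoch[1] && t <= perturb$epoch[2]) {
      A[, perturb$unit] <- A[, perturb$unit] + perturb$strength
    }
    Ht <- apply_nonlin(A, module)
    X <- (1 - alpha) * X + alpha * Ht
    if (keep) { states[[t]] <- X; tanhs[[t]] <- Ht }
    outs[[t]] <- X %*% t(module$Z) +
      matrix(module$c, B, module$n_out, byrow = TRUE)
  }
  list(final_state = X, states = states, tanhs = tanhs, outputs = outs)
}

# Readout timesteps for each module: the sensory module reports at the
# end of the stimulus epoch, the decision module at the end of the trial.
readout_steps <- function(config, module = c("mt", "dlpfc")) {
  module <- match.arg(module)
  end <- if (module == "mt") config$motion_offset else config$n_timesteps
  (end - config$readout_window + 1):end
}

# Average of outputs over a set of readout timesteps.
readout_mean <- function(outs, steps) {
  Reduce(`+`, outs[steps]) / length(steps)
}

adam_new <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

adam_step <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# One BPTT gradient step on a batch (MSE loss over the readout window,
# plus L2 penalties on hidden activity and on the weight matrices; the
# regularizers pull training toward distributed, population-vector-like
# solutions in which a unit's readout contribution aligns with its
# tuning). Returns updated module + adam states + batch loss.
bptt_step <- function(module, inputs, targets, rw, adam, lr, step_t,
                      clip = 1, l2_act = 1e-3, l2_w = 1e-4, l2_out = 2e-2) {
  if (isTRUE(module$frozen)) stop("module is frozen; weight updates rejected")
  T_ <- length(inputs)
  B <- nrow(inputs[[1]])
  alpha <- module$leak
  fw <- rnn_forward(module, inputs, keep = TRUE)
  denom <- length(rw) * B * module$n_out
  act_denom <- T_ * B * module$n_hidden
  loss <- 0
  dZ <- matrix(0, module$n_out, module$n_hidden); dc <- numeric(module$n_out)
  dW <- matrix(0, module$n_hidden, module$n_hidden)
  dU <- matrix(0, module$n_hidden, module$n_in)
  db <- numeric(module$n_hidden)
  G <- matrix(0, B, module$n_hidden)
  dYs <- vector("list", T_)
  for (t in rw) {
    E <- fw$outputs[[t]] - targets
    loss <- loss + sum(E^2) / denom
    dYs[[t]] <- 2 * E / denom
  }
  for (t in T_:1) {
    if (!is.null(dYs[[t]])) {
      dZ <- dZ + t(dYs[[t]]) %*% fw$states[[t]]
      dc <- dc + colSums(dYs[[t]])
      G <- G + dYs[[t]] %*% module$Z
    }
    G <- G + (2 * l2_act / act_denom) * fw$states[[t]]
    dA <- alpha * G * nonlin_deriv(fw$tanhs[[t]], module)
    Xprev <- if (t > 1) fw$states[[t - 1]] else matrix(0, B, module$n_hidden)
    dW <- dW + t(dA) %*% Xprev
    dU <- dU + t(dA) %*% inputs[[t]]
    db <- db + colSums(dA)
    G <- (1 - alpha) * G + dA %*% module$W
  }
  dW <- dW + 2 * l2_w * module$W
  dU <- dU + 2 * l2_w * module$U
  dZ <- dZ + 2 * l2_out * module$Z
  grads <- list(W = dW, U = dU, Z = dZ, b = db, c = dc)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (gn > clip) grads <- lapply(grads, function(g) g * clip / gn)
  for (nm in names(grads)) {
    upd <- adam_step(module[[nm]], grads[[nm]], adam[[nm]], lr, step_t)
    module[[nm]] <- if (nm %in% c("b", "c")) as.numeric(upd$par) else upd$par
    adam[[nm]] <- upd$state
  }
  list(module = module, adam = adam, loss = loss)
}

mt_targets <- function(trials) {
  cbind(cos(deg2rad(trials$motion_deg)), sin(deg2rad(trials$motion_deg)),
        cos(deg2rad(trials$inc_center_deg)), sin(deg2rad(trials$inc_center_deg)),
        cos(deg2rad(trials$dec_center_deg)), sin(deg2rad(trials$dec_center_deg)))
}

#' Decode directions from (cos, sin) output channel pairs
#'
#' @param y Matrix of outputs.
#' @param cols Length-2 column index of the (cos, sin) pair.
#' @return Directions in degrees, `[0, 360)`.
#' @export
decode_direction <- function(y, cols = c(1, 2)) {
  rad2deg(atan2(y[, cols[2]], y[, cols[1]])) %% 360
}

#' Evaluate a trained MT-like module on held-out trials
#'
#' @param mt Trained MT-like `rnn_module`.
#' @param config The [rnn_config()] used for training.
#' @param n Number of held-out trials.
#' @param seed Seed for trial sampling and input noise.
#' @return List with `motion_mae_deg` (circular MAE of the decoded motion
#'   direction) and `center_accuracy` (fraction of trials whose decoded
#'   increased-center output is nearest the true center).
#' @export
evaluate_mt <- function(mt, config, n = 256, seed = 1) {
  with_seed(seed, {
    trials <- sample_trials(n, config$task)
    inputs <- make_inputs(trials, config)
    y <- readout_mean(rnn_forward(mt, inputs)$outputs,
                      readout_steps(config, "mt"))
    dec_m <- decode_direction(y, 1:2)
    dec_i <- decode_direction(y, 3:4)
    centers <- config$task$inc_centers
    near <- vapply(dec_i, function(d) {
      centers[which.min(circ_dist(d, centers))]
    }, numeric(1))
    list(motion_mae_deg = circ_mae(dec_m, trials$motion_deg),
         center_accuracy = mean(near == trials$inc_center_deg))
  })
}

#' Train the MT-like (sensory) module
#'
#' The module receives noisy motion and the two reward-center locations
#' and is trained by mean-squared error to reproduce all three as
#' noise-free (cos, sin) pairs on separate output channels at the end of
#' the trial — a separable output parameterization. Training is seeded and
#' bit-for-bit reproducible; failure to reach the validation gate is
#' flagged in `converged` with a warning, never silently accepted.
#'
#' @param config An [rnn_config()].
#' @param seed Integer seed controlling init, batches, and noise.
#' @return A trained `rnn_module` (with `training_log`, `converged`).
#' @export
train_mt_module <- function(config = rnn_config(), seed = 1) {
  with_seed(seed, {
    mod <- new_rnn_module(6, config$n_hidden, 6, config$leak, "mt_like",
                          config$nonlinearity)
    adam <- adam_new(list(W = dim(mod$W), U = dim(mod$U), Z = dim(mod$Z),
                          b = length(mod$b), c = length(mod$c)))
    log <- NULL
    best <- NULL; best_metric <- Inf
    step_t <- 0
    for (ep in seq_len(config$epochs)) {
      trials <- sample_trials(config$n_train, config$task)
      targets <- mt_targets(trials)
      idx <- sample.int(nrow(trials))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, nrow(trials), by = config$batch_size)) {
        sel <- idx[start:min(start + config$batch_size - 1, nrow(trials))]
        inputs <- make_inputs(trials[sel, , drop = FALSE], config)
        step_t <- step_t + 1
        st <- bptt_step(mod, inputs, targets[sel, , drop = FALSE],
                        readout_steps(config, "mt"), adam, config$lr, step_t,
                        l2_act = config$l2_act, l2_w = config$l2_w,
                        l2_out = config$l2_out)
        mod <- st$module; adam <- st$adam
        ep_loss <- ep_loss + st$loss; nb <- nb + 1
      }
      if (ep %% 5 == 0 || ep == config$epochs) {
        ev <- evaluate_mt(mod, config, config$val_n, seed = derive_seed(seed, 999))
        log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                     val = ev$motion_mae_deg))
        if (ev$motion_mae_deg < best_metric) {
          best_metric <- ev$motion_mae_deg; best <- mod
        }
        if (best_metric <= 0.9 * config$mt_mae_gate) break
      }
    }
    mod <- best
    mod$training_log <- log
    mod$converged <- best_metric <= config$mt_mae_gate
    if (!mod$converged) {
      warning("MT-like module did not reach the validation gate (MAE ",
              round(best_metric, 1), " deg > ", config$mt_mae_gate, " deg)")
    }
    mod
  })
}

dlpfc_inputs_from_mt <- function(mt, trials, config, noise = TRUE,
                                 perturb_mt = NULL) {
  inputs <- make_inputs(trials, config, noise = noise)
  fw <- rnn_forward(mt, inputs, perturb = perturb_mt)
  centers <- inputs[[1]][, 3:6, drop = FALSE]
  lapply(fw$outputs, function(y) cbind(y[, 1:2, drop = FALSE], centers))
}

dlpfc_targets <- function(trials, config) {
  # vectorized over (trial, candidate): accuracy kernel times region scale
  pr <- config$task$profile
  cand <- config$candidate_dirs
  err <- outer(trials$motion_deg, cand, circ_dist)
  acc <- exp(pr$accuracy_kappa * (cos(deg2rad(err)) - 1))
  d_inc <- outer(trials$inc_center_deg, cand, circ_dist)
  d_dec <- outer(trials$dec_center_deg, cand, circ_dist)
  hw <- pr$region_halfwidth
  sc <- if (isTRUE(pr$smooth_edge)) {
    1 + (pr$scale_increase - 1) * stats::plogis((hw - d_inc) / pr$edge_softness) +
      (pr$scale_decrease - 1) * stats::plogis((hw - d_dec) / pr$edge_softness)
  } else {
    ifelse(d_inc <= hw, pr$scale_increase,
           ifelse(d_dec <= hw, pr$scale_decrease, 1))
  }
  acc * sc
}

#' Evaluate a trained dlPFC-like module on held-out trials
#'
#' @param model A two-stage model (list with `mt`, `dlpfc`, `config`).
#' @param n Held-out trials.
#' @param seed Seed.
#' @param coherence Optional fixed coherence for the held-out trials;
#'   `NULL` uses the task's training mix. Behavioral comparisons (e.g. the
#'   no-scaling control) are conventionally run at the standard experiment
#'   coherence 0.5 so that perceptual noise, not reward scaling, is held
#'   constant.
#' @return List with `median_r` (median per-trial Pearson correlation
#'   between predicted and true expected-reward vectors over candidates),
#'   `choice_mae_deg` (circular MAE of choices vs motion direction), and
#'   the held-out `choices` and `trials`.
#' @export
evaluate_dlpfc <- function(model, n = 256, seed = 2, coherence = NULL) {
  config <- model$config
  with_seed(seed, {
    tk <- config$task
    if (!is.null(coherence)) tk$coherences <- coherence
    trials <- sample_trials(n, tk)
    din <- dlpfc_inputs_from_mt(model$mt, trials, config)
    pred <- readout_mean(rnn_forward(model$dlpfc, din)$outputs,
                         readout_steps(config, "dlpfc"))
    tgt <- dlpfc_targets(trials, config)
    rs <- vapply(seq_len(n), function(i) {
      suppressWarnings(stats::cor(pred[i, ], tgt[i, ]))
    }, numeric(1))
    choices <- model_choice(pred, config$candidate_dirs)
    list(median_r = stats::median(rs, na.rm = TRUE),
         choice_mae_deg = circ_mae(choices, trials$motion_deg),
         choices = choices, trials = trials)
  })
}

#' Train the dlPFC-like (decision) module on top of a frozen MT module
#'
#' The sensory module is frozen; its motion output channels (run in the
#' loop, with input noise) and the reward-center channels are the inputs.
#' The decision module is trained by mean-squared error to output the
#' expected reward of every candidate choice direction. Any attempt to
#' update a frozen module's weights is an error, and MT weights are
#' bit-identical before and after.
#'
#' @param mt A trained, frozen MT-like module (use [freeze_module()]).
#' @param config An [rnn_config()].
#' @param seed Integer seed.
#' @return A trained `rnn_module` with tag `"dlpfc_like"`.
#' @export
train_dlpfc_module <- function(mt, config = rnn_config(), seed = 1) {
  if (!isTRUE(mt$frozen)) {
    stop("the MT-like module must be frozen before wiring the decision stage")
  }
  K <- config$n_candidates
  with_seed(derive_seed(seed, 2), {
    mod <- new_rnn_module(6, config$n_hidden, K, config$leak, "dlpfc_like",
                          config$nonlinearity)
    adam <- adam_new(list(W = dim(mod$W), U = dim(mod$U), Z = dim(mod$Z),
                          b = length(mod$b), c = length(mod$c)))
    log <- NULL; best <- NULL; best_metric <- Inf; step_t <- 0
    for (ep in seq_len(config$epochs)) {
      trials <- sample_trials(config$n_train, config$task)
      targets <- dlpfc_targets(trials, config)
      idx <- sample.int(nrow(trials))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, nrow(trials), by = config$batch_size)) {
        sel <- idx[start:min(start + config$batch_size - 1, nrow(trials))]
        din <- dlpfc_inputs_from_mt(mt, trials[sel, , drop = FALSE], config)
        step_t <- step_t + 1
        st <- bptt_step(mod, din, targets[sel, , drop = FALSE],
                        readout_steps(config, "dlpfc"), adam, config$lr,
                        step_t, l2_act = config$l2_act, l2_w = config$l2_w,
                        l2_out = config$l2_out)
        mod <- st$module; adam <- st$adam
        ep_loss <- ep_loss + st$loss; nb <- nb + 1
      }
      if (ep %% 5 == 0 || ep == config$epochs) {
        ev <- evaluate_dlpfc(list(mt = mt, dlpfc = mod, config = config),
                             config$val_n, seed = derive_seed(seed, 998))
        metric <- 1 - ev$median_r
        log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                     val = ev$median_r))
        if (metric < best_metric) { best_metric <- metric; best <- mod }
        if (best_metric <= 1 - (config$dlpfc_r_gate + 0.05)) break
      }
    }
    mod <- best
    mod$training_log <- log
    mod$converged <- best_metric <= 1 - config$dlpfc_r_gate
    if (!mod$converged) {
      warning("dlPFC-like module did not reach the validation gate ",
              "(median r = ", round(1 - best_metric, 3), ")")
    }
    mod
  })
}

#' Freeze a module against further training
#'
#' @param module An `rnn_module`.
#' @return The module with `frozen = TRUE`.
#' @export
freeze_module <- function(module) {
  stopifnot(inherits(module, "rnn_module"))
  module$frozen <- TRUE
  module
}

#' Train the full two-stage model
#'
#' Trains the MT-like module, freezes it, and trains the dlPFC-like module
#' on top of it.
#'
#' @param config An [rnn_config()].
#' @param seed Integer seed.
#' @return An object of class `popformat_model`: list with `mt`, `dlpfc`,
#'   `config`, `seed`.
#' @export
train_two_stage <- function(config = rnn_config(), seed = 1) {
  mt <- freeze_module(train_mt_module(config, seed))
  dlpfc <- train_dlpfc_module(mt, config, seed)
  structure(list(mt = mt, dlpfc = dlpfc, config = config, seed = seed),
            class = "popformat_model")
}

#' Model choice from a predicted-reward readout
#'
#' The choice is the candidate direction with the largest predicted
#' reward; ties are broken by the lowest candidate index.
#'
#' @param pred Numeric vector of K predicted rewards, or a trials x K
#'   matrix.
#' @param candidates K candidate directions, degrees.
#' @return Choice direction(s), degrees.
#' @export
model_choice <- function(pred, candidates) {
  pred <- rbind(pred)
  stopifnot(ncol(pred) == length(candidates), length(candidates) >= 1)
  if (!all(is.finite(pred))) stop("non-finite predicted rewards")
  drop(candidates[max.col(pred, ties.method = "first")])
}

#' Run trials through the full two-stage model
#'
#' @param model A `popformat_model`.
#' @param trials Trial data frame as from [sample_trials()].
#' @param seed Optional seed for the input noise (shared-noise pairing of
#'   perturbed and control runs is achieved by passing the same seed).
#' @param perturb Optional perturbation: list with `module` (`"mt_like"` or
#'   `"dlpfc_like"`), `unit`, `strength`, and optionally `epoch`
#'   (timestep range; defaults to the motion epoch).
#' @param keep_states If `TRUE`, returns trial-end hidden states of both
#'   modules.
#' @return List with `choices`, `pred` (trials x K predicted rewards), and
#'   optionally `mt_state`, `dlpfc_state`.
#' @export
run_trials <- function(model, trials, seed = NULL, perturb = NULL,
                       keep_states = FALSE) {
  config <- model$config
  if (!is.null(perturb)) {
    if (is.null(perturb$epoch)) {
      # module-appropriate defaults: the sensory module is perturbed while
      # it is transmitting evidence (the stimulus epoch); the decision
      # module while it is forming and maintaining the decision (late
      # stimulus through the delay), released before the readout window so
      # the recurrent dynamics settle before the choice is read out
      perturb$epoch <- if (perturb$module == "mt_like") {
        c(config$motion_onset, config$motion_offset)
      } else {
        c(config$motion_offset - 4, config$n_timesteps - config$readout_window)
      }
    }
    stopifnot(perturb$strength >= 0,
              perturb$module %in% c("mt_like", "dlpfc_like"),
              perturb$epoch[1] >= 1, perturb$epoch[2] <= config$n_timesteps)
  }
  with_seed(seed, {
    inputs <- make_inputs(trials, config)
    p_mt <- if (!is.null(perturb) && perturb$module == "mt_like") perturb else NULL
    p_dl <- if (!is.null(perturb) && perturb$module == "dlpfc_like") perturb else NULL
    fw_mt <- rnn_forward(model$mt, inputs, keep = keep_states,
                         perturb = p_mt)
    centers <- inputs[[1]][, 3:6, drop = FALSE]
    din <- lapply(fw_mt$outputs, function(y) {
      cbind(y[, 1:2, drop = FALSE], centers)
    })
    fw_dl <- rnn_forward(model$dlpfc, din, keep = FALSE, perturb = p_dl)
    pred <- readout_mean(fw_dl$outputs, readout_steps(config, "dlpfc"))
    out <- list(choices = model_choice(pred, config$candidate_dirs),
                pred = pred)
    if (keep_states) {
      # sensory states at the end of the stimulus epoch, decision states
      # at the end of the trial: each module's functional readout time
      out$mt_state <- fw_mt$states[[config$motion_offset]]
      out$dlpfc_state <- fw_dl$final_state
    }
    out
  })
}

#' Save / load a two-stage model as JSON
#'
#' Checkpoints store weights, configuration, seed, and training logs in a
#' plain-text JSON layout.
#'
#' @param model A `popformat_model`.
#' @param path File path (`.json`).
#' @return `load_model` returns the `popformat_model`.
#' @export
save_model <- function(model, path) {
  ser_mod <- function(m) {
    list(W = m$W, U = m$U, Z = m$Z, b = m$b, c = m$c, leak = m$leak,
         n_in = m$n_in, n_hidden = m$n_hidden, n_out = m$n_out,
         nonlinearity = m$nonlinearity, frozen = m$frozen, tag = m$tag,
         converged = m$converged, training_log = m$training_log)
  }
  cfg <- model$config
  cfg$task$profile <- unclass(cfg$task$profile)
  cfg$task <- unclass(cfg$task)
  obj <- list(mt = ser_mod(model$mt), dlpfc = ser_mod(model$dlpfc),
              config = unclass(cfg), seed = model$seed,
              calibration = model$calibration)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_mod <- function(m) {
    structure(
      list(W = as.matrix(m$W), U = as.matrix(m$U), Z = as.matrix(m$Z),
           b = as.numeric(m$b), c = as.numeric(m$c), leak = m$leak,
           n_in = m$n_in, n_hidden = m$n_hidden, n_out = m$n_out,
           nonlinearity = m$nonlinearity, frozen = m$frozen,
           training_log = m$training_log, converged = m$converged,
           tag = m$tag),
      class = "rnn_module"
    )
  }
  cfg <- obj$config
  cfg$task$profile <- structure(cfg$task$profile, class = "reward_profile")
  cfg$task <- structure(cfg$task, class = "task_config")
  cfg <- structure(cfg, class = "rnn_config")
  structure(list(mt = de_mod(obj$mt), dlpfc = de_mod(obj$dlpfc),
                 config = cfg, seed = obj$seed,
                 calibration = obj$calibration),
            class = "popformat_model")
}
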