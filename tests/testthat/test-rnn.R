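test_that("one dynamics step matches its closed form", {
  mod <- manual_module(U = matrix(0, 3, 2), Z = matrix(0, 1, 3), leak = 1)
  expect_equal(step_dynamics(c(0.3, -0.2, 5), c(1, 1), mod), c(0, 0, 0))
  mod0 <- mod; mod0$leak <- 1e-12
  x <- c(0.4, 0.1, -0.7)
  expect_equal(step_dynamics(x, c(0, 0), mod0), x, tolerance = 1e-10)
  expect_error(step_dynamics(c(1, 2), c(0, 0), mod), "dimensions")
})

test_that("dynamics agree with the linearized map near the origin", {
  set.seed(2)
  mod <- manual_module(U = matrix(rnorm(12), 4, 3),
                       Z = matrix(0, 1, 4), leak = 0.2)
  mod$W <- matrix(rnorm(16, sd = 0.3), 4)
  eps <- 1e-6
  x <- rnorm(4) * eps; u <- rnorm(3) * eps
  lin <- (1 - mod$leak) * x + mod$leak * drop(mod$W %*% x + mod$U %*% u)
  expect_lt(max(abs(step_dynamics(x, u, mod) - lin)), 1e-12 * max(abs(lin)))
})

test_that("model choice is the argmax with a deterministic tie-break", {
  cand <- seq(0, 330, 30)
  p <- rep(0, 12); p[8] <- 1
  expect_equal(model_choice(p, cand), cand[8])
  expect_equal(model_choice(rep(0.5, 12), cand), cand[1])
  expect_error(model_choice(c(1, NA, rep(0, 10)), cand), "non-finite")
  # with true expected rewards on a 36-candidate grid, the choice matches
  # the fine-grid reward argmax to within half the candidate spacing
  pr <- reward_profile()
  tr <- trial_condition(motion = 145, inc_center = 45, profile = pr)
  cand36 <- seq(0, 350, 10)
  ch <- model_choice(expected_reward(cand36, tr, pr), cand36)
  expect_lte(circ_dist(ch, reward_argmax(tr, pr)), 5)
})

test_that("training is deterministic given the seed", {
  cfg <- tiny_config(epochs = 6)
  m1 <- suppressWarnings(train_mt_module(cfg, seed = 5))
  m2 <- suppressWarnings(train_mt_module(cfg, seed = 5))
  expect_identical(m1$W, m2$W)
  expect_identical(m1$Z, m2$Z)
  m3 <- suppressWarnings(train_mt_module(cfg, seed = 6))
  expect_false(identical(m1$W, m3$W))
})

test_that("frozen modules reject weight updates and stay bit-identical", {
  model <- get_tiny_model()
  expect_true(model$mt$frozen)
  cfg <- model$config
  trials <- sample_trials(8, cfg$task, seed = 1)
  inputs <- with_seed(1, popformat:::make_inputs(trials, cfg))
  adam <- popformat:::adam_new(list(W = dim(model$mt$W), U = dim(model$mt$U),
                                    Z = dim(model$mt$Z),
                                    b = length(model$mt$b),
                                    c = length(model$mt$c)))
  expect_error(
    popformat:::bptt_step(model$mt, inputs, popformat:::mt_targets(trials),
                          popformat:::readout_steps(cfg, "mt"), adam,
                          1e-3, 1),
    "frozen"
  )
  # retraining the decision stage leaves the sensory weights untouched
  w_before <- model$mt$W
  dl2 <- suppressWarnings(train_dlpfc_module(model$mt, tiny_config(epochs = 4),
                                             seed = 9))
  expect_identical(model$mt$W, w_before)
  expect_error(train_dlpfc_module(get_tiny_model()$dlpfc,
                                  tiny_config(epochs = 2), seed = 1),
               "frozen")
})

test_that("trained tiny model produces finite choices on the candidate grid", {
  model <- get_tiny_model()
  trials <- sample_trials(16, model$config$task, seed = 2)
  rt <- run_trials(model, trials, seed = 3)
  expect_true(all(rt$choices %in% model$config$candidate_dirs))
  expect_equal(dim(rt$pred), c(16L, model$config$n_candidates))
})

test_that("model checkpoints survive a JSON round trip", {
  model <- get_tiny_model()
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  m2 <- load_model(path)
  expect_equal(m2$mt$W, model$mt$W, tolerance = 1e-12)
  expect_equal(m2$dlpfc$Z, model$dlpfc$Z, tolerance = 1e-12)
  trials <- sample_trials(6, model$config$task, seed = 4)
  expect_equal(run_trials(m2, trials, seed = 5)$choices,
               run_trials(model, trials, seed = 5)$choices)
})
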