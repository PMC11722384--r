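rvm <- function(n, mu_deg, kappa, seed) {
  # von Mises sampler via rejection (Best-Fisher), adequate for tests
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      th <- runif(2 * n, -pi, pi)
      keep <- runif(2 * n) < exp(kappa * (cos(th) - 1))
      out <- c(out, th[keep])
    }
    (out[seq_len(n)] * 180 / pi + mu_deg) %% 360
  })
}

test_that("regime classifier recognizes constructed samples", {
  motion <- 20; pref <- 120   # offset 100
  # 50/50 mixture of two tight modes at the anchors: winner take all
  wta <- c(rvm(150, motion, 40, 1), rvm(150, pref, 40, 2))
  rc <- classify_regime(wta, motion, pref)
  expect_equal(rc$regime, "winner_take_all")
  expect_lt(rc$midpoint_mass, 0.10)
  expect_true(all(circ_dist(sort(rc$mode_locations_deg),
                            sort(c(motion, pref))) < 15))
  # one mode at the midpoint: vector averaging
  va <- rvm(300, motion + 50, 30, 3)
  rc2 <- classify_regime(va, motion, pref)
  expect_equal(rc2$regime, "vector_averaging")
  # centered at the motion direction: no effect
  rc3 <- classify_regime(rvm(300, motion, 30, 4), motion, pref)
  expect_equal(rc3$regime, "no_effect")
  expect_error(classify_regime(rvm(50, 0, 10, 5), 0, 100), "at least 100")
})

test_that("classifier is robust to candidate-grid quantization", {
  motion <- 0; pref <- 100
  q <- function(x) round(x / 10) * 10
  rc <- classify_regime(q(rvm(300, 50, 25, 6)), motion, pref)
  expect_equal(rc$regime, "vector_averaging")
  rc2 <- classify_regime(q(c(rvm(150, motion, 40, 7), rvm(150, pref, 40, 8))),
                         motion, pref)
  expect_equal(rc2$regime, "winner_take_all")
})

test_that("delta choice maps are conservative and matched", {
  tb <- data.frame(motion_deg = 0, perturbed = rep(c(FALSE, TRUE), each = 50),
                   choice_deg = c(runif(50, 0, 360), rep(45, 50)))
  class(tb) <- c("choice_table", "data.frame")
  dm <- delta_choice_map(tb, bin_deg = 10)
  expect_equal(sum(dm$delta), 0, tolerance = 1e-12)
  expect_equal(max(dm$delta), dm$delta[dm$bin_center_deg == 45])
  # identical perturbed and control samples cancel exactly
  tb2 <- tb; tb2$choice_deg <- rep(tb$choice_deg[1:50], 2)
  class(tb2) <- class(tb)
  expect_true(all(delta_choice_map(tb2)$delta == 0))
  tb3 <- tb[tb$perturbed, ]
  class(tb3) <- class(tb)
  expect_error(delta_choice_map(tb3), "unmatched")
})

test_that("unit preferences are recovered for hand-built tuning", {
  model <- manual_model()
  info <- unit_info(model, "mt_like")
  expect_true(info$tuned[1])
  expect_lt(circ_dist(info$preference_deg[1], 0), 10)
  expect_lt(circ_dist(info$preference_deg[3], 90), 10)
  expect_lt(circ_dist(info$preference_deg[4], 180), 10)
  expect_false(info$tuned[2])   # no drive at all: untuned flag
  expect_error(perturbation_site(model, "mt_like", 2, info = info),
               "untuned")
})

test_that("zero-strength perturbation collapses exactly onto control", {
  model <- get_tiny_model()
  u <- tuned_units(model, "mt_like", 2, seed = 1)
  tr <- data.frame(motion_deg = (u$preference_deg[1] - 60) %% 360,
                   inc_center_deg = 45, dec_center_deg = 225,
                   coherence = 0.5)
  tb <- run_perturbation_experiment(
    model, list(module = "mt_like", unit = u$unit[1], strength = 0),
    tr, n_reps = 40, seed = 6)
  expect_identical(tb$choice_deg[tb$perturbed], tb$choice_deg[!tb$perturbed])
})

test_that("site preference aggregates similarly tuned members", {
  model <- get_tiny_model()
  info <- unit_info(model, "mt_like")
  u <- info$unit[info$tuned][1]
  s0 <- perturbation_site(model, "mt_like", u, site_width = 0, info = info)
  expect_equal(s0$units, u)
  expect_equal(s0$preference_deg, info$preference_deg[info$unit == u])
  s30 <- perturbation_site(model, "mt_like", u, site_width = 30, info = info)
  expect_true(all(s0$units %in% s30$units))
  expect_true(all(circ_dist(info$preference_deg[match(s30$units, info$unit)],
                            s0$preference_deg) <= 30))
})

test_that("reward interaction index vanishes for identical maps", {
  # pure arithmetic check on the effect-size definition
  tb <- data.frame(motion_deg = 0, perturbed = rep(c(FALSE, TRUE), each = 60),
                   choice_deg = c(rep(0, 60), rep(c(0, 90), 30)))
  class(tb) <- c("choice_table", "data.frame")
  dm <- delta_choice_map(tb)
  tv <- 0.5 * sum(abs(dm$delta))
  expect_equal(tv, 0.5)   # half the mass moved from 0 to 90
})

test_that("a null perturbation sweep reports no effect at every offset", {
  model <- get_tiny_model()
  units <- tuned_units(model, "mt_like", 2, seed = 3)
  sw <- offset_sweep(model, "mt_like", units, offsets = c(60, 120),
                     strength = 0, n_reps = 100, seed = 9)
  expect_true(all(sw$table$regime == "no_effect"))
  expect_true(is.na(sw$va_limit_deg))
})
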