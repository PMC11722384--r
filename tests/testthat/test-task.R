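test_that("expected reward follows the accuracy kernel and region scaling", {
  pr <- reward_profile(accuracy_kappa = 2)
  tr <- trial_condition(motion = 0, inc_center = 120, coherence = 1,
                        profile = pr)
  # zero error, neutral region
  expect_equal(expected_reward(0, tr, pr), 1)
  # antipodal error in the neutral region: kernel value exp(kappa*(-2))
  tr2 <- trial_condition(motion = 90, inc_center = 0, profile = pr)
  expect_equal(expected_reward(270, tr2, pr), exp(-4))
  # inside the increased region the kernel is scaled up
  expect_equal(expected_reward(120, tr, pr),
               2 * exp(2 * (cos(deg2rad(120)) - 1)))
  # vectorized and bounded
  g <- seq(0, 359)
  r <- expected_reward(g, tr, pr)
  expect_true(all(r >= 0 & r <= pr$scale_increase))
})

test_that("reward regions must not overlap", {
  expect_error(trial_condition(0, 45, 100), "overlap")
  expect_silent(trial_condition(0, 45, 225))
})

test_that("maximum-reward choice is displaced toward the increased region", {
  pr <- reward_profile()
  # motion 60 degrees from the increased center (outside the region):
  # the argmax sits strictly between motion and center, at the region edge
  tr <- trial_condition(motion = 105, inc_center = 45, profile = pr)
  am <- reward_argmax(tr, pr)
  expect_gt(circ_dist(am, tr$motion), 0)
  expect_lt(circ_dist(am, tr$inc_center), circ_dist(tr$motion, tr$inc_center))
  s <- circ_signed(tr$motion, am)
  expect_true(sign(s) == sign(circ_signed(tr$motion, tr$inc_center)))
  # unit scaling restores the motion direction exactly
  pr1 <- reward_profile(scale_increase = 1 + 1e-12,
                        scale_decrease = 1 - 1e-12)
  expect_equal(reward_argmax(tr, pr1), tr$motion)
})

test_that("expected reward is invariant under global rotation", {
  pr <- reward_profile()
  for (rot in c(13, 111, 287)) {
    tr <- trial_condition(20, 80, profile = pr)
    trr <- trial_condition(20 + rot, 80 + rot, (260 + rot) %% 360,
                           profile = pr)
    ch <- seq(0, 350, 25)
    expect_equal(expected_reward(ch + rot, trr, pr),
                 expected_reward(ch, tr, pr))
  }
})

test_that("trial sampling draws motion and condition independently", {
  cfg <- task_config(motion_dirs = seq(0, 350, 10), inc_centers = c(45, 225))
  tt <- sample_trials(10000, cfg, seed = 11)
  tab <- table(tt$motion_deg, tt$inc_center_deg)
  expect_equal(dim(tab), c(36L, 2L))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
  # determinism and degenerate sampling
  expect_identical(sample_trials(50, cfg, seed = 3),
                   sample_trials(50, cfg, seed = 3))
  one <- sample_trials(20, task_config(motion_dirs = 90, inc_centers = 45),
                       seed = 1)
  expect_true(all(one$motion_deg == 90 & one$inc_center_deg == 45))
})

test_that("trial tables survive a CSV round trip", {
  tt <- sample_trials(25, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_trials(tt, path)
  expect_equal(read_trials(path), tt)
})
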