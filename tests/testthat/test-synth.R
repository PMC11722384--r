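test_that("noise-free generation round-trips the formatting angle", {
  for (th in seq(0, 90, 15)) {
    g <- generate_session(session_spec(true_theta_deg = th,
                                       noise_model = "none"),
                          seed = 20 + th)
    expect_lt(abs(formatting_angle(g$session)$theta_deg - th), 1)
  }
})

test_that("generation is bit-for-bit reproducible from (spec, seed)", {
  sp <- session_spec()
  g1 <- generate_session(sp, seed = 77)
  g2 <- generate_session(sp, seed = 77)
  expect_identical(g1$session$counts, g2$session$counts)
  expect_identical(g1$truth$reward_axis, g2$truth$reward_axis)
  g3 <- generate_session(sp, seed = 78)
  expect_false(identical(g1$session$counts, g3$session$counts))
})

test_that("Poisson counts match the construction means", {
  sp <- session_spec(n_trials_per_cell = 200, directions = seq(0, 270, 90),
                     n_units = 12)
  g <- generate_session(sp, seed = 31)
  s <- g$session
  # reconstruct the generator's rate for every cell from the ground truth
  plane <- g$truth$motion_plane
  r <- g$truth$reward_axis
  cell_rate <- function(dir, cond) {
    th <- dir * pi / 180
    pmax(sp$baseline_rate +
           sp$motion_signal_scale * (cos(th) * plane[, 1] +
                                     sin(th) * plane[, 2]) +
           (if (cond == "1") 0.5 else -0.5) * sp$reward_signal_scale * r, 0)
  }
  z_ok <- 0; tot <- 0
  for (dir in sp$directions) for (cond in c("1", "2")) {
    sel <- s$directions == dir & s$conditions == cond
    lam <- cell_rate(dir, cond)
    z <- (colMeans(s$counts[sel, , drop = FALSE]) - lam) /
      sqrt(lam / sum(sel) + 1e-12)
    z_ok <- z_ok + sum(abs(z) < 1.96)
    tot <- tot + length(z)
  }
  expect_gt(z_ok / tot, 0.94)
})

test_that("cell means concentrate around the true rates", {
  sp <- session_spec(n_trials_per_cell = 200, directions = seq(0, 300, 60),
                     n_units = 10, baseline_rate = 20,
                     motion_signal_scale = 0, reward_signal_scale = 1e-6)
  g <- generate_session(sp, seed = 55)
  s <- g$session
  cell <- interaction(s$directions, s$conditions)
  devs <- unlist(lapply(levels(cell), function(lv) {
    abs(colMeans(s$counts[cell == lv, , drop = FALSE]) - 20)
  }))
  expect_gt(mean(devs < 1), 0.95)
})

test_that("paired area generation supports the paired comparison design", {
  pairs <- generate_area_pair(8, c(75, 85), c(35, 45),
                              spec = session_spec(n_units = 16,
                                                  n_trials_per_cell = 5,
                                                  directions = seq(0, 330, 30)),
                              seed = 4)
  expect_length(pairs, 8)
  est <- t(vapply(pairs, function(p) {
    c(formatting_angle(p$a$session)$theta_deg,
      formatting_angle(p$b$session)$theta_deg)
  }, numeric(2)))
  expect_true(all(est[, 1] > est[, 2]))
  # too few pairs are refused by the comparison
  two <- generate_area_pair(2, spec = session_spec(n_units = 8,
                                                   n_trials_per_cell = 2,
                                                   directions = seq(0, 270, 90)),
                            seed = 5)
  th <- vapply(two, function(p) p$truth_theta, numeric(2))
  expect_error(compare_areas(th[1, ], th[2, ]), "at least 6")
})

test_that("the null paired design is not rejected in excess", {
  ps <- vapply(1:12, function(i) {
    pairs <- generate_area_pair(8, c(55, 65), c(55, 65),
                                spec = session_spec(n_units = 16,
                                                    n_trials_per_cell = 5,
                                                    directions = seq(0, 330, 30)),
                                seed = 400 + i)
    est <- t(vapply(pairs, function(p) {
      c(formatting_angle(p$a$session)$theta_deg,
        formatting_angle(p$b$session)$theta_deg)
    }, numeric(2)))
    compare_areas(est[, 1], est[, 2])$p.value
  }, numeric(1))
  expect_gt(median(ps), 0.05)
})
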