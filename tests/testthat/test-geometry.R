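# session with means exactly on a ring in a known plane, plus a condition
# offset along a known axis at a chosen angle to the plane
exact_session <- function(theta, n_units = 20, seed = 1) {
  generate_session(session_spec(n_units = n_units, n_trials_per_cell = 1,
                                true_theta_deg = theta,
                                noise_model = "none"), seed = seed)
}

test_that("condition means are idempotent under trial replication", {
  g <- exact_session(45)
  s <- g$session
  m1 <- condition_means(s)
  s2 <- session_data(rbind(s$counts, s$counts),
                     c(s$directions, s$directions),
                     c(s$conditions, s$conditions))
  expect_equal(condition_means(s2), m1)
  # empty cell is reported with its location
  s3 <- s
  keep <- !(s$directions == 0 & s$conditions == "1")
  s3 <- session_data(s$counts[keep, ], s$directions[keep],
                     s$conditions[keep])
  expect_error(condition_means(s3), "direction 0")
})

test_that("motion axes recover an exactly embedded ring plane", {
  g <- exact_session(90, seed = 2)
  ax <- motion_axes(condition_means(g$session))
  true_plane <- g$truth$motion_plane
  # principal angles between estimated and true plane
  sv <- svd(crossprod(ax, true_plane))$d
  expect_lt(max(acos(pmin(sv, 1))) * 180 / pi, 0.1)
  # centering invariance: adding a constant vector leaves the plane
  # unchanged (the in-plane basis is arbitrary for an exact circle)
  m <- condition_means(g$session)
  ax2 <- motion_axes(m + 5)
  sv2 <- svd(crossprod(ax2, ax))$d
  expect_lt(max(acos(pmin(sv2, 1))) * 180 / pi, 1e-6)
})

test_that("motion axes and theta are equivariant under unit-space rotation", {
  g <- exact_session(37, seed = 3)
  m <- condition_means(g$session)
  th1 <- formatting_angle(m)$theta_deg
  q <- qr.Q(qr(matrix(with_seed(9, rnorm(400)), 20)))
  mr <- m
  for (i in seq_len(dim(m)[1])) mr[i, , ] <- m[i, , ] %*% q
  expect_equal(formatting_angle(mr)$theta_deg, th1, tolerance = 1e-6)
})

test_that("reward axis is the normalized condition-mean difference", {
  m <- array(1, c(4, 2, 6))
  m[, 1, 5] <- 3   # conditions differ only in unit 5
  ax <- reward_axis(m)
  expect_equal(ax, c(0, 0, 0, 0, 1, 0))
  expect_error(reward_axis(array(1, c(4, 2, 6))), "identical")
})

test_that("subspace angle matches explicit orthonormal constructions", {
  A <- diag(1, 5)[, 1:2]
  expect_equal(subspace_angle(A, c(0, 0, 1, 0, 0)), 90)
  expect_equal(subspace_angle(A, c(1, 0, 0, 0, 0)), 0)
  r45 <- c(cos(pi / 4), 0, sin(pi / 4), 0, 0)
  expect_equal(subspace_angle(A, r45), 45)
  expect_error(subspace_angle(A, c(2, 0, 0, 0, 0)), "unit norm")
})

test_that("axis-vs-axis variant stays in [0, 90]", {
  g <- exact_session(60, seed = 5)
  fa <- formatting_angle(g$session, method = "axis")
  expect_true(fa$theta_deg >= 0 && fa$theta_deg <= 90)
})

test_that("paired area comparison has exact small-sample behavior", {
  expect_error(compare_areas(1:5, 2:6), "at least 6")
  th <- c(80, 70, 75, 85, 78, 72, 81)
  expect_equal(compare_areas(th, th)$p.value, 1)
  # all-positive identical differences: exact p with mid-ranks = 2 / 2^15
  a <- seq(40, 82, 3); b <- a - 30
  expect_length(a, 15)
  expect_equal(compare_areas(a, b)$p.value, 2 / 2^15, tolerance = 1e-12)
  # agreement with wilcox.test when the exact no-ties path applies
  set.seed(42)
  x <- runif(12, 60, 90); y <- runif(12, 40, 80)
  expect_equal(compare_areas(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("decoding is calibrated at chance under label shuffling", {
  g <- generate_session(session_spec(n_trials_per_cell = 14,
                                     directions = seq(0, 315, 45),
                                     n_units = 16), seed = 8)
  s <- g$session
  shuf <- with_seed(13, session_data(s$counts, s$directions,
                                     sample(s$conditions)))
  dc <- decode_check(shuf)
  # binomial 99% band around chance for n trials
  n <- length(s$conditions)
  expect_lt(abs(dc$condition_accuracy - 0.5), 3 * sqrt(0.25 / n))
  # noise-free session decodes perfectly
  g0 <- exact_session(45, seed = 9)
  s0 <- g0$session
  s0 <- session_data(s0$counts[rep(seq_len(nrow(s0$counts)), 5), ],
                     rep(s0$directions, 5), rep(s0$conditions, 5))
  dc0 <- decode_check(s0)
  expect_equal(dc0$condition_accuracy, 1)
  expect_equal(dc0$direction_mae_deg, 0)
})

test_that("sessions survive the CSV pair round trip", {
  g <- generate_session(session_spec(n_units = 8, n_trials_per_cell = 2,
                                     directions = seq(0, 270, 90)),
                        seed = 10, area = "MT")
  stem <- tempfile()
  write_session_csv(g$session, stem)
  s2 <- read_session_csv(stem)
  expect_equal(unname(s2$counts), unname(g$session$counts))
  expect_equal(s2$directions, g$session$directions)
  expect_equal(s2$area, "MT")
})
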