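test_that("the origin is a fixed point of a zero-bias module at rest", {
  mod <- manual_module(U = matrix(0, 4, 2), Z = matrix(0, 1, 4))
  mod$W <- matrix(0.1, 4, 4)
  fps <- find_fixed_points(mod, input = c(0, 0),
                           init_states = rbind(rep(0.2, 4), rep(0, 4)))
  expect_equal(nrow(fps$points), 1)
  expect_lt(fps$speeds[1], 1e-8)
  expect_equal(unname(fps$points[1, ]), rep(0, 4), tolerance = 1e-6)
  expect_true(fps$stable[1])
})

test_that("a contracting linear module has the closed-form fixed point", {
  set.seed(7)
  H <- 6
  W <- matrix(rnorm(H^2, sd = 0.2), H)
  W <- W / max(Mod(eigen(W)$values)) * 0.7   # spectral radius 0.7
  mod <- manual_module(U = matrix(rnorm(H * 2), H, 2),
                       Z = matrix(0, 1, H), nonlinearity = "identity")
  mod$W <- W
  mod$b <- rnorm(H, sd = 0.1)
  u <- c(0.4, -0.3)
  xstar <- solve(diag(H) - W, drop(mod$U %*% u) + mod$b)
  fps <- find_fixed_points(mod, u, rbind(rnorm(H), rnorm(H), rep(0, H)))
  expect_equal(nrow(fps$points), 1)
  expect_lt(max(abs(fps$points[1, ] - xstar)), 1e-8)
  expect_true(fps$stable[1])
})

test_that("an expanding linear map is flagged unstable", {
  H <- 3
  mod <- manual_module(U = matrix(0, H, 1), Z = matrix(0, 1, H),
                       nonlinearity = "identity", leak = 1)
  mod$W <- diag(c(1.1, 0.5, 0.2))
  st <- assess_stability(mod, rep(0, H), 0)
  expect_false(st$stable)
  expect_equal(st$leading_modulus, 1.1, tolerance = 1e-10)
  expect_error(assess_stability(mod, c(1, 1, 1), 0), "not a fixed point")
})

test_that("deduplication is order-independent", {
  mod <- manual_module(U = matrix(0, 4, 2), Z = matrix(0, 1, 4))
  mod$W <- matrix(0.05, 4, 4)
  inits <- rbind(rep(0.5, 4), rep(-0.5, 4), rep(0.01, 4), rep(0, 4))
  f1 <- find_fixed_points(mod, c(0, 0), inits)
  f2 <- find_fixed_points(mod, c(0, 0), inits[4:1, ])
  expect_equal(nrow(f1$points), nrow(f2$points))
  expect_equal(sort(f1$points[, 1]), sort(f2$points[, 1]), tolerance = 1e-8)
})

test_that("projection preserves structure of exactly planar points", {
  set.seed(11)
  basis <- qr.Q(qr(matrix(rnorm(40 * 2), 40)))
  coords <- cbind(cos(seq(0, 2 * pi, length.out = 13)[-13]),
                  sin(seq(0, 2 * pi, length.out = 13)[-13]))
  pts <- coords %*% t(basis)
  pr <- project_points(pts, "principal_components", k = 2)
  expect_equal(as.matrix(dist(pr$coords)), as.matrix(dist(pts)),
               tolerance = 1e-10)
  expect_equal(pr$variance_captured, 1, tolerance = 1e-12)
})

test_that("a noisy high-dimensional ring is captured by two components", {
  set.seed(12)
  basis <- qr.Q(qr(matrix(rnorm(128 * 2), 128)))
  ang <- seq(0, 350, 10) * pi / 180
  pts <- cbind(cos(ang), sin(ang)) %*% t(basis) +
    matrix(rnorm(36 * 128, sd = 1e-3), 36)
  pr <- project_points(pts, "principal_components", k = 2)
  expect_gt(pr$variance_captured, 0.99)
  expect_true(ring_topology(pr$coords, seq(0, 350, 10)))
})

test_that("ring topology check rejects a scrambled loop", {
  ang <- seq(0, 350, 30) * pi / 180
  ring <- cbind(cos(ang), sin(ang))
  expect_true(ring_topology(ring, seq(0, 330, 30)))
  scrambled_labels <- c(seq(0, 330, 30)[c(1, 7, 3, 9, 5, 11, 2, 8, 4, 10,
                                          6, 12)])
  expect_false(ring_topology(ring, scrambled_labels))
})

test_that("tiny-model fixed points exist for task inputs and are stable", {
  model <- get_tiny_model()
  fps <- module_fixed_points(model, "mt_like",
                             directions = seq(0, 270, 90),
                             centers = c(45, 225), n_random = 1, seed = 2)
  expect_gte(nrow(fps), 6)
  expect_true(all(fps$speed < 1e-8))
  expect_true(all(fps$stable))
})
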