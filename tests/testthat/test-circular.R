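test_that("circ_dist takes the shorter arc and is symmetric", {
  expect_equal(circ_dist(10, 350), 20)
  expect_equal(circ_dist(0, 180), 180)
  expect_equal(circ_dist(45, 225), 180)
  expect_equal(circ_dist(123.4, 123.4), 0)
  a <- runif(50, -720, 720); b <- runif(50, -720, 720)
  expect_equal(circ_dist(a, b), circ_dist(b, a))
  expect_true(all(circ_dist(a, b) <= 180))
  expect_error(circ_dist(NA, 0), "finite")
})

test_that("circ_signed is the signed counterpart of circ_dist", {
  expect_equal(circ_signed(0, 20), 20)
  expect_equal(circ_signed(0, 340), -20)
  a <- runif(50, 0, 360); b <- runif(50, 0, 360)
  expect_equal(abs(circ_signed(a, b)), circ_dist(a, b))
  expect_equal((a + circ_signed(a, b)) %% 360, b %% 360)
})

test_that("circular mean handles weights and degenerate input", {
  expect_equal(circ_mean(c(350, 10)), 0)
  expect_equal(circ_mean(c(0, 90), w = c(1, 0)), 0)
  expect_true(is.na(circ_mean(c(0, 180))))
  expect_equal(circ_mae(c(10, 350), c(0, 0)), 10)
})

test_that("with_seed restores the caller's RNG state", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(with_seed(1, runif(5)))
  expect_identical(runif(1), x1)
  expect_identical(with_seed(7, rnorm(3)), with_seed(7, rnorm(3)))
})
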