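#' Direction-tuned population with uniform preferred directions
#'
#' Builds a population of identically tuned units whose preferred motion
#' directions tile the circle in equal steps. Tuning curves are von Mises:
#' `baseline + amplitude * exp(kappa * (cos(theta - pref) - 1))`.
#'
#' @param step_deg Spacing of preferred directions; must divide 360.
#' @param tuning_kappa von Mises concentration of the tuning curve.
#' @param baseline_rate Baseline response, spikes/trial.
#' @param amplitude Tuned response amplitude at the preferred direction,
#'   spikes/trial.
#' @return An object of class `tuning_population`.
#' @export
build_population <- function(step_deg = 10, tuning_kappa = 2,
                             baseline_rate = 2, amplitude = 8) {
  stopifnot(step_deg > 0, is.finite(step_deg),
            tuning_kappa > 0, baseline_rate >= 0, amplitude >= 0)
  if (360 %% step_deg != 0) {
    stop("step_deg must divide 360 (got ", step_deg, ")")
  }
  structure(
    list(preferred = seq(0, 360 - step_deg, by = step_deg),
         tuning_kappa = tuning_kappa,
         baseline_rate = baseline_rate,
         amplitude = amplitude),
    class = "tuning_population"
  )
}

#' Reward-gain model
#'
#' Describes how multiplicative gain depends on the angular distance between
#' a unit's preferred direction and the increased-reward center, plus
#' unit-to-unit heterogeneity. The mean profile interpolates from
#' `gain_aligned` at zero distance to `gain_opposed` at 180 degrees, either
#' linearly in distance (default) or as a cosine. `coordination = "random"`
#' draws independent Gaussian gain noise per unit and condition;
#' `"orthogonalized"` afterwards projects the between-condition gain
#' difference pattern out of the motion-response plane, which guarantees a
#' separable population geometry.
#'
#' @param gain_aligned Mean gain when preferred direction equals the reward
#'   center.
#' @param gain_opposed Mean gain at 180 degrees from the reward center.
#' @param heterogeneity_sd Marginal SD of per-unit gain noise.
#' @param coordination `"random"` or `"orthogonalized"`.
#' @param shape `"linear"` or `"cosine"` mean profile.
#' @param noise_harmonics Number of Fourier harmonics (in preferred
#'   direction) making up the coordinated gain noise; `0` requests
#'   independent per-unit noise instead.
#' @return An object of class `gain_model`.
#' @export
gain_model <- function(gain_aligned = 1.3, gain_opposed = 0.8,
                       heterogeneity_sd = 0.35,
                       coordination = c("random", "orthogonalized"),
                       shape = c("linear", "cosine"),
                       noise_harmonics = 3) {
  stopifnot(gain_aligned > 0, gain_opposed > 0, heterogeneity_sd >= 0,
            noise_harmonics >= 0)
  structure(
    list(gain_aligned = gain_aligned, gain_opposed = gain_opposed,
         heterogeneity_sd = heterogeneity_sd,
         coordination = match.arg(coordination),
         shape = match.arg(shape),
         noise_harmonics = noise_harmonics),
    class = "gain_model"
  )
}

gain_mean_profile <- function(delta, gm) {
  if (gm$shape == "linear") {
    gm$gain_aligned + (gm$gain_opposed - gm$gain_aligned) * delta / 180
  } else {
    mid <- (gm$gain_aligned + gm$gain_opposed) / 2
    half <- (gm$gain_aligned - gm$gain_opposed) / 2
    mid + half * cos(deg2rad(delta))
  }
}

gain_noise <- function(pref, gm) {
  if (gm$heterogeneity_sd == 0) return(numeric(length(pref)))
  if (gm$noise_harmonics == 0) {
    return(stats::rnorm(length(pref), sd = gm$heterogeneity_sd))
  }
  # coordinated noise: smooth random function of preferred direction built
  # from random Fourier coefficients, marginal SD = heterogeneity_sd
  h <- seq_len(gm$noise_harmonics)
  a <- stats::rnorm(length(h)); b <- stats::rnorm(length(h))
  z <- outer(deg2rad(pref), h)
  drop(cos(z) %*% a + sin(z) %*% b) * gm$heterogeneity_sd /
    sqrt(gm$noise_harmonics)
}

#' Draw per-unit gains for one reward condition
#'
#' `gain_i = mean_profile(circ_dist(pref_i, reward_center)) + noise_i`,
#' with gains clipped below at 0.05. The noise term is, by default, a
#' smooth (coordinated) random function of preferred direction: the same
#' single-unit statistics can then be realized with population-level
#' modulation patterns that land anywhere from inside to orthogonal to the
#' motion plane, which is what makes the population formatting a draw-level
#' rather than unit-level property. Set `noise_harmonics = 0` in the
#' [gain_model()] for independent per-unit noise.
#'
#' @param pop A [build_population()] object.
#' @param reward_center Increased-reward center, degrees.
#' @param gm A [gain_model()].
#' @param seed Optional seed for the gain noise.
#' @return Numeric vector of per-unit gains.
#' @export
draw_gains <- function(pop, reward_center, gm = gain_model(), seed = NULL) {
  stopifnot(inherits(pop, "tuning_population"), inherits(gm, "gain_model"))
  delta <- circ_dist(pop$preferred, reward_center)
  mu <- gain_mean_profile(delta, gm)
  with_seed(seed, pmax(mu + gain_noise(pop$preferred, gm), 0.05))
}

tuning_curve <- function(pop, directions) {
  # n_dir x n_unit matrix of exp(kappa*(cos(theta - pref) - 1))
  outer(directions, pop$preferred, function(th, pf) {
    exp(pop$tuning_kappa * (cos(deg2rad(th - pf)) - 1))
  })
}

#' Draw gains for a set of reward conditions
#'
#' Draws one gain vector per condition. Under
#' `coordination = "orthogonalized"` the between-condition gain difference
#' is projected out of the plane of the population's direction means before
#' being re-applied, producing a separable (near-90-degree) geometry by
#' construction.
#'
#' @param pop A [build_population()] object.
#' @param centers Increased-reward centers, one per condition, degrees.
#' @param gm A [gain_model()].
#' @param directions Direction grid used to define the motion plane for the
#'   orthogonalized mode.
#' @param seed Optional seed.
#' @return Units x conditions gain matrix.
#' @export
draw_condition_gains <- function(pop, centers = c(45, 225), gm = gain_model(),
                                 directions = seq(0, 350, 10), seed = NULL) {
  g <- with_seed(seed, {
    vapply(centers, function(cc) draw_gains(pop, cc, gm, seed = NULL),
           numeric(length(pop$preferred)))
  })
  if (gm$coordination == "orthogonalized" && length(centers) == 2) {
    gbar <- rowMeans(g)
    resp <- simulate_mean_responses(pop, cbind(gbar, gbar), directions)
    ax <- motion_axes(resp)
    d <- g[, 1] - g[, 2]
    d_perp <- d - ax %*% (t(ax) %*% d)
    g <- cbind(gbar + d_perp / 2, gbar - d_perp / 2)
    g <- pmax(g, 0.05)
  }
  g
}

#' Mean population responses under gain modulation
#'
#' `response_i(theta, c) = baseline + gain_i(c) * amplitude *
#' exp(kappa * (cos(theta - pref_i) - 1))`: the multiplicative gain acts on
#' the tuned component only (set `scale_full = TRUE` to scale the baseline
#' as well).
#'
#' @param pop A [build_population()] object.
#' @param gains Units x conditions gain matrix (or a vector for one
#'   condition).
#' @param directions Motion directions, degrees.
#' @param scale_full If `TRUE`, gain scales baseline + tuned response.
#' @return Array `[n_directions, n_conditions, n_units]` of mean responses,
#'   with direction and condition dimnames.
#' @export
simulate_mean_responses <- function(pop, gains, directions = seq(0, 350, 10),
                                    scale_full = FALSE) {
  stopifnot(inherits(pop, "tuning_population"))
  gains <- as.matrix(gains)
  stopifnot(nrow(gains) == length(pop$preferred))
  tc <- tuning_curve(pop, directions)  # dir x unit
  n_dir <- length(directions)
  n_cond <- ncol(gains)
  n_unit <- length(pop$preferred)
  out <- array(NA_real_, dim = c(n_dir, n_cond, n_unit),
               dimnames = list(direction = directions,
                               condition = seq_len(n_cond), unit = NULL))
  for (k in seq_len(n_cond)) {
    tuned <- sweep(tc, 2, gains[, k] * pop$amplitude, "*")
    out[, k, ] <- if (scale_full) {
      sweep(tuned, 2, gains[, k] * pop$baseline_rate, "+")
    } else {
      tuned + pop$baseline_rate
    }
  }
  out
}

#' Formatting-angle sweep over heterogeneity draws
#'
#' Repeatedly draws reward gains for two antipodal reward conditions,
#' computes mean responses, and measures the formatting angle theta between
#' the reward axis and the motion plane with the geometry estimator. Across
#' draws the same single-unit tuning can yield anywhere from joint (small
#' theta) to separable (large theta) population geometry; the spread is the
#' point of the simulation.
#'
#' @param n_draws Number of independent heterogeneity draws.
#' @param pop A [build_population()] object.
#' @param centers Two increased-reward centers, degrees.
#' @param gm A [gain_model()].
#' @param directions Direction grid.
#' @param seed Optional master seed.
#' @return Data frame with columns `draw` and `theta_deg`.
#' @export
tuning_theta_sweep <- function(n_draws = 50, pop = build_population(),
                               centers = c(45, 225), gm = gain_model(),
                               directions = seq(0, 350, 10), seed = NULL) {
  theta <- vapply(seq_len(n_draws), function(i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    g <- draw_condition_gains(pop, centers, gm, directions, seed = s)
    means <- simulate_mean_responses(pop, g, directions)
    formatting_angle(means)$theta_deg
  }, numeric(1))
  data.frame(draw = seq_len(n_draws), theta_deg = theta)
}
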