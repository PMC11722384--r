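#' Specification of a synthetic recording session
#'
#' Describes a synthetic trials-by-units session whose population geometry
#' is injected by construction: direction means lie on a ring of radius
#' `motion_signal_scale` inside a random 2-D plane of unit space, and the
#' two reward conditions are offset by `reward_signal_scale` along a unit
#' vector making exactly `true_theta_deg` with that plane. Because the
#' geometry is built in mean space, the formatting angle has an exact
#' oracle.
#'
#' The default preset emulates a few dozen simultaneously recorded units
#' with modest trial counts and Poisson count noise: decoding both
#' variables is comfortably above chance while single-session angle
#' estimation stays visibly noisy.
#'
#' @param n_units Number of units (>= 4).
#' @param n_trials_per_cell Trials per (direction, condition) cell.
#' @param directions Direction grid, degrees.
#' @param n_conditions Number of reward conditions (2).
#' @param true_theta_deg Ground-truth formatting angle in `[0, 90]`.
#' @param motion_signal_scale Ring radius, spikes/trial.
#' @param reward_signal_scale Between-condition offset, spikes/trial.
#' @param baseline_rate Baseline rate, spikes/trial.
#' @param noise_model `"poisson"`, `"gaussian"`, or `"none"`.
#' @param gaussian_sd SD for the Gaussian noise model.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_units = 36, n_trials_per_cell = 20,
                         directions = seq(0, 350, by = 10),
                         n_conditions = 2, true_theta_deg = 45,
                         motion_signal_scale = 12, reward_signal_scale = 10,
                         baseline_rate = 10,
                         noise_model = c("poisson", "gaussian", "none"),
                         gaussian_sd = 3) {
  stopifnot(n_units >= 4, n_trials_per_cell >= 1,
            length(directions) >= 4, n_conditions == 2,
            true_theta_deg >= 0, true_theta_deg <= 90,
            motion_signal_scale >= 0, reward_signal_scale > 0,
            baseline_rate >= 0)
  structure(
    list(n_units = n_units, n_trials_per_cell = n_trials_per_cell,
         directions = directions %% 360, n_conditions = n_conditions,
         true_theta_deg = true_theta_deg,
         motion_signal_scale = motion_signal_scale,
         reward_signal_scale = reward_signal_scale,
         baseline_rate = baseline_rate,
         noise_model = match.arg(noise_model),
         gaussian_sd = gaussian_sd),
    class = "session_spec"
  )
}

#' Generate a synthetic session with known formatting angle
#'
#' Draws a random orthonormal triple (two vectors spanning the motion
#' plane, one orthogonal), places the reward axis at exactly the requested
#' angle to the plane, builds the mean-rate matrix, and samples trial
#' counts from the requested noise model. Rates are floored at zero before
#' Poisson sampling (rare at the default signal-to-baseline ratio; the
#' clipped fraction is reported).
#'
#' @param spec A [session_spec()].
#' @param seed Optional integer seed (bit-for-bit reproducible).
#' @param area Area tag passed to the session.
#' @return List with `session` (a [session_data()]), and `truth` (list with
#'   `motion_plane` units x 2, `reward_axis`, `theta_deg`, `clipped_frac`).
#' @export
generate_session <- function(spec = session_spec(), seed = NULL, area = "") {
  stopifnot(inherits(spec, "session_spec"))
  if (spec$n_units < 4) stop("theta is not identifiable with < 4 units")
  with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(spec$n_units * 3), ncol = 3)))
    e1 <- q[, 1]; e2 <- q[, 2]; e3 <- q[, 3]
    phi <- stats::runif(1, 0, 360)           # in-plane bearing of the tilt
    u_in <- cos(deg2rad(phi)) * e1 + sin(deg2rad(phi)) * e2
    r <- cos(deg2rad(spec$true_theta_deg)) * u_in +
      sin(deg2rad(spec$true_theta_deg)) * e3
    dirs <- spec$directions
    n_cell <- spec$n_trials_per_cell
    cond_offsets <- c(`1` = +0.5, `2` = -0.5) * spec$reward_signal_scale
    grid <- expand.grid(direction = dirs, condition = names(cond_offsets),
                        stringsAsFactors = FALSE)
    lam <- t(vapply(seq_len(nrow(grid)), function(k) {
      th <- deg2rad(grid$direction[k])
      spec$baseline_rate +
        spec$motion_signal_scale * (cos(th) * e1 + sin(th) * e2) +
        cond_offsets[[grid$condition[k]]] * r
    }, numeric(spec$n_units)))
    clipped <- mean(lam < 0)
    lam <- pmax(lam, 0)
    idx <- rep(seq_len(nrow(grid)), each = n_cell)
    mu <- lam[idx, , drop = FALSE]
    counts <- switch(spec$noise_model,
      poisson = matrix(stats::rpois(length(mu), mu), nrow = nrow(mu)),
      gaussian = mu + matrix(stats::rnorm(length(mu), sd = spec$gaussian_sd),
                             nrow = nrow(mu)),
      none = mu
    )
    list(
      session = session_data(counts, grid$direction[idx],
                             grid$condition[idx], area = area),
      truth = list(motion_plane = cbind(e1, e2), reward_axis = r,
                   theta_deg = spec$true_theta_deg, clipped_frac = clipped)
    )
  })
}

#' Generate paired sessions from two areas
#'
#' For each of `n_sessions` simulated recording days, draws a ground-truth
#' angle for area A and one for area B from uniform ranges and generates
#' both sessions (independent unit spaces, shared session structure). This
#' emulates a paired design in which two areas are recorded simultaneously.
#'
#' @param n_sessions Number of paired sessions (>= 2).
#' @param theta_range_a,theta_range_b Length-2 uniform ranges (degrees) for
#'   the two areas' ground-truth angles.
#' @param spec Shared [session_spec()] (its `true_theta_deg` is overridden
#'   per session and area).
#' @param seed Optional master seed.
#' @return List of per-session lists with elements `a`, `b` (each as
#'   returned by [generate_session()]) and `truth_theta` (named pair).
#' @export
generate_area_pair <- function(n_sessions = 15,
                               theta_range_a = c(75, 85),
                               theta_range_b = c(35, 45),
                               spec = session_spec(), seed = NULL) {
  stopifnot(n_sessions >= 2)
  with_seed(seed, {
    lapply(seq_len(n_sessions), function(i) {
      th_a <- stats::runif(1, theta_range_a[1], theta_range_a[2])
      th_b <- stats::runif(1, theta_range_b[1], theta_range_b[2])
      sp_a <- spec; sp_a$true_theta_deg <- th_a
      sp_b <- spec; sp_b$true_theta_deg <- th_b
      list(a = generate_session(sp_a, seed = NULL, area = "A"),
           b = generate_session(sp_b, seed = NULL, area = "B"),
           truth_theta = c(a = th_a, b = th_b))
    })
  })
}
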