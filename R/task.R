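#' Reward profile for the continuous estimation task
#'
#' The task rewards a choice direction according to the accuracy of the
#' direction estimate, multiplied by a scaling factor determined by where the
#' choice falls on the target ring. Accuracy is scored by a von-Mises-shaped
#' kernel `exp(kappa * (cos(delta) - 1))` of the angular error `delta`, which
#' is 1 at zero error and falls off smoothly and circularly. Choices inside
#' the increased-reward region are scaled up, choices inside the
#' decreased-reward region are scaled down, all other choices are unscaled.
#'
#' The default kernel concentration `accuracy_kappa = 4` (accuracy reward
#' falls to half at roughly 30 degrees of error, as befits a precision
#' task) keeps the reward landscape peaked: far from the scaled regions,
#' accuracy dominates and the maximum-reward choice is the motion
#' direction, while for moderate motion-to-center offsets (up to about 80
#' degrees with the default 2x scaling) the maximum-reward choice is
#' pulled off the motion direction toward the increased-reward region.
#'
#' @param accuracy_kappa Concentration (unitless, > 0) of the accuracy
#'   kernel.
#' @param scale_increase Multiplicative reward factor inside the
#'   increased-reward region (> 1).
#' @param scale_decrease Multiplicative factor inside the decreased-reward
#'   region (in (0, 1)).
#' @param region_halfwidth Angular half-width of each colored region,
#'   degrees, in (0, 90).
#' @param smooth_edge If `TRUE`, region edges are softened by a logistic
#'   ramp instead of a hard step.
#' @param edge_softness Logistic scale (degrees) of the soft edge.
#' @return An object of class `reward_profile`.
#' @export
reward_profile <- function(accuracy_kappa = 4,
                           scale_increase = 2,
                           scale_decrease = 0.5,
                           region_halfwidth = 45,
                           smooth_edge = FALSE,
                           edge_softness = 5) {
  stopifnot(
    is.finite(accuracy_kappa), accuracy_kappa > 0,
    is.finite(scale_increase), scale_increase > 1,
    is.finite(scale_decrease), scale_decrease > 0, scale_decrease < 1,
    is.finite(region_halfwidth), region_halfwidth > 0, region_halfwidth < 90
  )
  structure(
    list(
      accuracy_kappa = accuracy_kappa,
      scale_increase = scale_increase,
      scale_decrease = scale_decrease,
      region_halfwidth = region_halfwidth,
      smooth_edge = smooth_edge,
      edge_softness = edge_softness
    ),
    class = "reward_profile"
  )
}

#' Single trial of the estimation task
#'
#' A trial is defined by the motion direction of the stimulus, the reward
#' condition (locations of the increased- and decreased-reward region
#' centers on the target ring), and the motion coherence. The two colored
#' regions must not overlap given the profile's region half-width; by
#' default the decreased center is antipodal to the increased center.
#'
#' @param motion Motion direction, degrees.
#' @param inc_center Center of the increased-reward region, degrees.
#' @param dec_center Center of the decreased-reward region, degrees;
#'   defaults to antipodal to `inc_center`.
#' @param coherence Motion coherence in (0, 1].
#' @param profile A [reward_profile()] used to validate region overlap.
#' @return An object of class `trial_condition`.
#' @export
trial_condition <- function(motion, inc_center,
                            dec_center = (inc_center + 180) %% 360,
                            coherence = 1,
                            profile = reward_profile()) {
  stopifnot(
    is.finite(motion), is.finite(inc_center), is.finite(dec_center),
    is.finite(coherence), coherence > 0, coherence <= 1
  )
  motion <- motion %% 360
  inc_center <- inc_center %% 360
  dec_center <- dec_center %% 360
  if (circ_dist(inc_center, dec_center) <= 2 * profile$region_halfwidth) {
    stop("increased and decreased reward regions overlap (centers ",
         inc_center, " and ", dec_center, " deg, half-width ",
         profile$region_halfwidth, " deg)")
  }
  structure(
    list(motion = motion, inc_center = inc_center,
         dec_center = dec_center, coherence = coherence),
    class = "trial_condition"
  )
}

reward_scale_at <- function(choice, trial, profile) {
  d_inc <- circ_dist(choice, trial$inc_center)
  d_dec <- circ_dist(choice, trial$dec_center)
  hw <- profile$region_halfwidth
  if (isTRUE(profile$smooth_edge)) {
    s <- profile$edge_softness
    1 +
      (profile$scale_increase - 1) * stats::plogis((hw - d_inc) / s) +
      (profile$scale_decrease - 1) * stats::plogis((hw - d_dec) / s)
  } else {
    ifelse(d_inc <= hw, profile$scale_increase,
           ifelse(d_dec <= hw, profile$scale_decrease, 1))
  }
}

#' Expected reward of a choice
#'
#' Evaluates `accuracy_kernel(circ_dist(choice, motion)) * scale(choice)`
#' where the accuracy kernel is `exp(kappa * (cos(delta) - 1))` and the
#' scale factor depends on which (if any) colored region the choice falls
#' in. Vectorized over `choice`.
#'
#' @param choice Choice direction(s), degrees.
#' @param trial A [trial_condition()].
#' @param profile A [reward_profile()].
#' @return Expected reward, non-negative, at most `scale_increase`.
#' @export
expected_reward <- function(choice, trial, profile = reward_profile()) {
  stopifnot(inherits(trial, "trial_condition"),
            inherits(profile, "reward_profile"),
            all(is.finite(choice)))
  err <- circ_dist(choice, trial$motion)
  acc <- exp(profile$accuracy_kappa * (cos(deg2rad(err)) - 1))
  acc * reward_scale_at(choice %% 360, trial, profile)
}

#' Maximum-reward choice on a fine grid
#'
#' Exhaustive search for the choice direction maximizing expected reward.
#' Ties are broken by the lowest grid index.
#'
#' @param trial A [trial_condition()].
#' @param profile A [reward_profile()].
#' @param step Grid step in degrees (default 1).
#' @return The grid direction (degrees) with the largest expected reward.
#' @export
reward_argmax <- function(trial, profile = reward_profile(), step = 1) {
  grid <- seq(0, 360 - step, by = step)
  r <- expected_reward(grid, trial, profile)
  grid[which.max(r)]
}

#' Task configuration
#'
#' Sampling scheme for trials: allowed motion directions, allowed
#' increased-reward center positions (the decreased center is placed at a
#' fixed angular offset, antipodal by default), and coherence levels. Motion
#' direction and reward condition are drawn independently on every trial.
#'
#' @param motion_dirs Allowed motion directions, degrees.
#' @param inc_centers Allowed increased-reward centers, degrees.
#' @param coherences Allowed coherence levels in (0, 1].
#' @param dec_offset Offset (degrees) from increased to decreased center.
#' @param profile A [reward_profile()].
#' @return An object of class `task_config`.
#' @export
task_config <- function(motion_dirs = seq(0, 350, by = 10),
                        inc_centers = c(45, 225),
                        coherences = 1,
                        dec_offset = 180,
                        profile = reward_profile()) {
  stopifnot(length(motion_dirs) >= 1, length(inc_centers) >= 1,
            length(coherences) >= 1, all(coherences > 0), all(coherences <= 1))
  structure(
    list(motion_dirs = motion_dirs %% 360, inc_centers = inc_centers %% 360,
         coherences = coherences, dec_offset = dec_offset, profile = profile),
    class = "task_config"
  )
}

#' Sample task trials
#'
#' Motion direction, reward condition, and coherence are drawn independently
#' and uniformly from their allowed sets, mirroring random interleaving of
#' conditions across trials.
#'
#' @param n Number of trials.
#' @param config A [task_config()].
#' @param seed Optional integer seed; when given, sampling is reproducible
#'   and the caller's RNG state is untouched.
#' @return A data frame with columns `trial_id`, `motion_deg`,
#'   `inc_center_deg`, `dec_center_deg`, `coherence`.
#' @export
sample_trials <- function(n, config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"), n >= 1)
  with_seed(seed, {
    motion <- config$motion_dirs[sample.int(length(config$motion_dirs), n,
                                            replace = TRUE)]
    inc <- config$inc_centers[sample.int(length(config$inc_centers), n,
                                         replace = TRUE)]
    coh <- config$coherences[sample.int(length(config$coherences), n,
                                        replace = TRUE)]
    dec <- (inc + config$dec_offset) %% 360
    # validate non-overlap once (same half-width for all trials)
    trial_condition(motion[1], inc[1], dec[1], coh[1], config$profile)
    data.frame(trial_id = seq_len(n), motion_deg = motion,
               inc_center_deg = inc, dec_center_deg = dec, coherence = coh)
  })
}

#' Write or read a trial table
#'
#' Trial tables are stored as plain CSV with the columns produced by
#' [sample_trials()].
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials` returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path)
}
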