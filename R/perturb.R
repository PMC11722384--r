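#' Preferred direction of a model unit
#'
#' Runs noise-free trials over the direction grid (both reward conditions,
#' full coherence), takes the unit's trial-end activity, and estimates the
#' preference as the circular mean of the direction grid weighted by
#' above-minimum activity, seeded at the grid argmax. Units whose activity
#' range is below a floor are flagged untuned and excluded from
#' perturbation experiments.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param unit_index Unit index within the module.
#' @param activity_floor Minimum activity range (fraction of the largest
#'   unit range in the module) below which a unit is untuned.
#' @return List with `preference_deg` (or `NA`), `tuned` (logical), and
#'   `range` (activity range).
#' @export
unit_preference <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                            unit_index, activity_floor = 0.1) {
  module_tag <- match.arg(module_tag)
  info <- unit_info(model, module_tag, activity_floor)
  row <- info[info$unit == unit_index, ]
  list(preference_deg = row$preference_deg, tuned = row$tuned,
       range = row$range)
}

# Trial-end activity of every unit in one module on the noise-free
# direction grid, averaged over the two reward conditions.
unit_activity_by_direction <- function(model, module_tag) {
  config <- model$config
  dirs <- config$task$motion_dirs
  centers <- config$task$inc_centers
  grid <- expand.grid(motion_deg = dirs, inc_center_deg = centers)
  grid$dec_center_deg <- (grid$inc_center_deg + config$task$dec_offset) %% 360
  grid$coherence <- 1
  rt <- run_trials(model, grid, keep_states = TRUE)
  st <- if (module_tag == "mt_like") rt$mt_state else rt$dlpfc_state
  out <- rowsum(st, group = grid$motion_deg) / length(centers)
  rownames(out) <- sort(unique(grid$motion_deg))
  out
}

#' Tuning summary of every unit in a module
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param activity_floor Untuned threshold, as in [unit_preference()].
#' @return Data frame with one row per unit: `unit`, `preference_deg`,
#'   `tuned`, `range`.
#' @export
unit_info <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                      activity_floor = 0.1) {
  module_tag <- match.arg(module_tag)
  act <- unit_activity_by_direction(model, module_tag)
  dirs <- as.numeric(rownames(act))
  rngs <- apply(act, 2, function(z) diff(range(z)))
  out <- lapply(seq_len(ncol(act)), function(i) {
    a <- act[, i]
    if (rngs[i] < activity_floor * max(rngs)) {
      return(data.frame(unit = i, preference_deg = NA_real_, tuned = FALSE,
                        range = rngs[i]))
    }
    w <- a - min(a)
    peak <- dirs[which.max(a)]
    rel <- circ_signed(peak, dirs)
    data.frame(unit = i,
               preference_deg = (peak + sum(w * rel) / sum(w)) %% 360,
               tuned = TRUE, range = rngs[i])
  })
  do.call(rbind, out)
}

#' Tuned units of a module
#'
#' Picks among the better-driven tuned units (activity range in the upper
#' half of the module), emulating the experimental practice of stimulating
#' responsive, clearly tuned sites. Units can be restricted by the
#' alignment of their preference with the task's two trained reward
#' conditions: `"aligned"` units sit inside the scaled region of one
#' center (and are increased-aligned in one condition, decreased-aligned
#' in the other); `"neutral"` units sit outside both regions.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param n Number of units wanted.
#' @param alignment `"any"`, `"neutral"`, or `"aligned"`.
#' @param seed Seed for the random choice among eligible units.
#' @return Data frame with `unit`, `preference_deg`.
#' @export
tuned_units <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                        n = 5, alignment = c("any", "neutral", "aligned"),
                        seed = 1) {
  module_tag <- match.arg(module_tag)
  alignment <- match.arg(alignment)
  config <- model$config
  info <- unit_info(model, module_tag)
  ok <- info[info$tuned, ]
  if (nrow(ok) == 0) stop("no tuned units in the ", module_tag, " module")
  if (alignment != "any") {
    cls <- vapply(ok$preference_deg, preference_alignment, character(1),
                  centers = config$task$inc_centers,
                  halfwidth = config$task$profile$region_halfwidth)
    ok <- ok[cls == alignment, ]
    if (nrow(ok) == 0) stop("no ", alignment, "-preference tuned units")
  }
  strong <- ok[ok$range >= stats::median(ok$range), ]
  if (nrow(strong) < n) strong <- ok
  pick <- with_seed(seed, strong[sample.int(nrow(strong),
                                            min(n, nrow(strong))), ])
  data.frame(unit = pick$unit, preference_deg = pick$preference_deg)
}

#' Perturbation site around a seed unit
#'
#' A site is the seed unit plus all tuned units whose preference lies
#' within `site_width` degrees of the seed's preference — the model analog
#' of the cluster of similarly tuned neurons activated by one stimulating
#' electrode. `site_width = 0` restricts the site to the seed unit.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param unit Seed unit index.
#' @param site_width Half-width (degrees) of the preference window.
#' @param info Optional precomputed [unit_info()] table.
#' @return List with `units` (member indices) and `preference_deg` (of the
#'   seed unit).
#' @export
perturbation_site <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                              unit, site_width = 30, info = NULL) {
  module_tag <- match.arg(module_tag)
  if (is.null(info)) info <- unit_info(model, module_tag)
  pref <- info$preference_deg[info$unit == unit]
  if (!isTRUE(info$tuned[info$unit == unit])) {
    stop("seed unit ", unit, " is untuned")
  }
  tu <- info[info$tuned, ]
  sel <- circ_dist(tu$preference_deg, pref) <= site_width
  members <- tu$unit[sel]
  # site preference: activity-range-weighted circular mean of the members,
  # the analog of multiunit tuning measured on a stimulating electrode
  rel <- circ_signed(pref, tu$preference_deg[sel])
  w <- tu$range[sel]
  site_pref <- (pref + sum(w * rel) / sum(w)) %% 360
  list(units = sort(unique(c(unit, members))), preference_deg = site_pref,
       seed_preference_deg = pref)
}

# Alignment class of a preference relative to the task's two reward
# conditions: "aligned" if it falls inside the scaled region of one of the
# two trained center locations (it is then increased-aligned in one
# condition and decreased-aligned in the other), "neutral" if it is at
# least `margin` degrees outside both regions.
preference_alignment <- function(preference, centers = c(45, 225),
                                 halfwidth = 45, margin = 5) {
  d <- circ_dist(preference, centers)
  if (any(d <= halfwidth - margin)) "aligned"
  else if (all(d > halfwidth + margin)) "neutral"
  else "boundary"
}

# Trials for a unit with preference p and signed offset delta: the motion
# direction is p - delta and the reward condition is one of the task's two
# trained conditions. Both conditions are returned (interleaved), matching
# the random interleaving of reward conditions across trials.
neutral_trial <- function(preference, offset, coherence = 0.5,
                          centers = c(45, 225), dec_offset = 180) {
  data.frame(motion_deg = (preference - offset) %% 360,
             inc_center_deg = centers,
             dec_center_deg = (centers + dec_offset) %% 360,
             coherence = coherence)
}

#' Run a single-unit perturbation experiment
#'
#' For each row of the trial grid, runs `n_reps` perturbed and `n_reps`
#' control repetitions with shared input-noise seeds (pairing is exact:
#' zero strength reproduces control choices trial by trial). The
#' perturbation is an additive constant drive to the unit's pre-activation
#' during the motion epoch — the model analog of microstimulation.
#'
#' @param model A `popformat_model`.
#' @param spec List with `module` (`"mt_like"`/`"dlpfc_like"`), `unit`,
#'   `strength`, optional `epoch`.
#' @param trials Trial grid data frame (one row per condition).
#' @param n_reps Repetitions per condition and arm.
#' @param seed Master seed for the shared input noise.
#' @return A `choice_table` data frame: trial fields, `rep`, `perturbed`,
#'   `choice_deg`.
#' @export
run_perturbation_experiment <- function(model, spec, trials, n_reps = 200,
                                        seed = 1) {
  stopifnot(spec$strength >= 0)
  big <- trials[rep(seq_len(nrow(trials)), each = n_reps), , drop = FALSE]
  big$rep <- rep(seq_len(n_reps), times = nrow(trials))
  noise_seed <- derive_seed(seed, 11)
  ctrl <- run_trials(model, big, seed = noise_seed)
  pert <- run_trials(model, big, seed = noise_seed,
                     perturb = list(module = spec$module, unit = spec$unit,
                                    strength = spec$strength,
                                    epoch = spec$epoch))
  out <- rbind(
    cbind(big, perturbed = FALSE, choice_deg = ctrl$choices),
    cbind(big, perturbed = TRUE, choice_deg = pert$choices)
  )
  rownames(out) <- NULL
  class(out) <- c("choice_table", "data.frame")
  out
}

#' Perturbation-minus-control choice map
#'
#' Bins choices and subtracts the proportion of control choices from the
#' proportion of perturbation choices per bin, optionally within groups.
#' Differences sum to zero within every group.
#'
#' @param table A `choice_table` from [run_perturbation_experiment()].
#' @param bin_deg Bin width, degrees (must divide 360).
#' @param group Optional name of a grouping column in `table`.
#' @return Data frame with `group` (if any), `bin_center_deg`, `delta`.
#' @export
delta_choice_map <- function(table, bin_deg = 10, group = NULL) {
  stopifnot(360 %% bin_deg == 0)
  breaks <- seq(0, 360, by = bin_deg)
  centers <- breaks[-1] - bin_deg / 2
  one <- function(tb) {
    if (!any(tb$perturbed) || all(tb$perturbed)) {
      stop("unmatched cells: need both perturbed and control choices")
    }
    p <- table(cut((tb$choice_deg[tb$perturbed]) %% 360, breaks,
                   include.lowest = TRUE))
    q <- table(cut((tb$choice_deg[!tb$perturbed]) %% 360, breaks,
                   include.lowest = TRUE))
    data.frame(bin_center_deg = centers,
               delta = as.numeric(p / sum(p)) - as.numeric(q / sum(q)))
  }
  if (is.null(group)) return(one(table))
  parts <- split(table, table[[group]])
  out <- do.call(rbind, lapply(names(parts), function(g) {
    cbind(group = g, one(parts[[g]]))
  }))
  rownames(out) <- NULL
  out
}

# ---- von Mises mixture machinery ------------------------------------------

vm_loglik <- function(x_rad, mu, kappa) {
  sum(kappa * cos(x_rad - mu) - log_bessel_i0(kappa) - log(2 * pi))
}

fit_vm1 <- function(x_rad) {
  mu <- atan2(mean(sin(x_rad)), mean(cos(x_rad)))
  R <- sqrt(mean(sin(x_rad))^2 + mean(cos(x_rad))^2)
  kappa <- min(a1inv(R), 500)
  list(mu = mu, kappa = kappa, loglik = vm_loglik(x_rad, mu, kappa),
       n_par = 2)
}

fit_vm2_em <- function(x_rad, init_mu, max_iter = 200, tol = 1e-7) {
  w <- 0.5
  mu <- init_mu
  kap <- c(4, 4)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    l1 <- log(w) + kap[1] * cos(x_rad - mu[1]) - log_bessel_i0(kap[1])
    l2 <- log(1 - w) + kap[2] * cos(x_rad - mu[2]) - log_bessel_i0(kap[2])
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    g1 <- exp(l1 - den)
    ll <- sum(den) - length(x_rad) * log(2 * pi)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    w <- mean(g1)
    w <- min(max(w, 1e-3), 1 - 1e-3)
    for (k in 1:2) {
      gk <- if (k == 1) g1 else 1 - g1
      s <- sum(gk * sin(x_rad)); c_ <- sum(gk * cos(x_rad))
      mu[k] <- atan2(s, c_)
      R <- sqrt(s^2 + c_^2) / sum(gk)
      kap[k] <- min(a1inv(R), 500)
    }
  }
  list(w = w, mu = mu, kappa = kap, loglik = ll, n_par = 5)
}

fit_vm2 <- function(x_rad, anchors_rad) {
  inits <- list(
    anchors_rad,
    stats::quantile(x_rad, c(0.25, 0.75), names = FALSE, type = 1),
    anchors_rad + c(0.3, -0.3)
  )
  fits <- lapply(inits, function(i0) {
    tryCatch(fit_vm2_em(x_rad, i0), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(NULL)
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

#' Classify a perturbation choice distribution
#'
#' Fits 1- and 2-component von Mises mixtures by maximum likelihood and
#' selects between them by BIC (a difference of at least `ic_margin` is
#' required to declare two modes). `winner_take_all` requires two selected
#' modes falling within `mode_tol` of the motion direction and the unit
#' preference respectively and a midpoint mass below `midpoint_mass_max`;
#' `vector_averaging` requires a single mode strictly between motion and
#' preference (exclusive `guard`-degree bands at both ends); a single mode
#' at the motion direction is `no_effect`; anything else is `other`.
#'
#' @param choices Choice directions, degrees (>= 100 values).
#' @param motion_deg Motion direction, degrees.
#' @param preference_deg Perturbed unit's preference, degrees.
#' @param guard Exclusive band (degrees) around motion and preference for
#'   the vector-averaging call.
#' @param mode_tol Mode-location tolerance (degrees) for winner-take-all.
#' @param midpoint_window Half-width (degrees) of the midpoint-mass window.
#' @param midpoint_mass_max Maximum midpoint mass for winner-take-all.
#' @param ic_margin Required BIC difference to declare two modes.
#' @param dequantize_deg Choices produced by an argmax over discrete
#'   candidates are quantized to the candidate spacing; before fitting,
#'   uniform jitter of this half-width (degrees) is added (with a fixed
#'   internal seed, so the call is deterministic) so that the mixture fits
#'   are not driven by the quantization. Two fitted modes closer than
#'   twice the mode tolerance are treated as one.
#' @return An object of class `regime_call`: list with `regime`,
#'   `mode_locations_deg`, `midpoint_mass`, `evidence` (BIC difference,
#'   positive favors two modes), and `weights`.
#' @export
classify_regime <- function(choices, motion_deg, preference_deg,
                            guard = 10, mode_tol = 25,
                            midpoint_window = 30, midpoint_mass_max = 0.10,
                            ic_margin = 10, dequantize_deg = 5) {
  if (length(choices) < 100) stop("need at least 100 choices")
  n <- length(choices)
  jit <- with_seed(20221, stats::runif(n, -dequantize_deg, dequantize_deg))
  x <- deg2rad((choices + jit) %% 360)
  d <- circ_signed(motion_deg, preference_deg)
  midpoint <- (motion_deg + d / 2) %% 360
  midpoint_mass <- mean(circ_dist(choices, midpoint) <= midpoint_window)
  f1 <- fit_vm1(x)
  f2 <- fit_vm2(x, deg2rad(c(motion_deg, preference_deg)))
  bic1 <- -2 * f1$loglik + f1$n_par * log(n)
  bic2 <- if (is.null(f2)) Inf else -2 * f2$loglik + f2$n_par * log(n)
  evidence <- bic1 - bic2
  two_modes <- is.finite(evidence) && evidence > ic_margin
  if (two_modes && circ_dist(rad2deg(f2$mu[1]), rad2deg(f2$mu[2])) <
        2 * mode_tol) {
    two_modes <- FALSE  # quantization or shoulder structure, not bimodality
  }
  call_out <- function(regime, modes, weights = NA_real_) {
    structure(list(regime = regime, mode_locations_deg = modes %% 360,
                   midpoint_mass = midpoint_mass, evidence = evidence,
                   weights = weights),
              class = "regime_call")
  }
  if (two_modes) {
    modes <- rad2deg(f2$mu) %% 360
    w <- c(f2$w, 1 - f2$w)
    dm <- circ_dist(modes, motion_deg)
    dp <- circ_dist(modes, preference_deg)
    # assign each mode to its nearest anchor; require distinct anchors
    at_motion <- which.min(dm)
    at_pref <- which.min(dp)
    ok <- at_motion != at_pref &&
      dm[at_motion] <= mode_tol && dp[at_pref] <= mode_tol &&
      midpoint_mass < midpoint_mass_max
    if (ok) return(call_out("winner_take_all", modes, w))
    return(call_out("other", modes, w))
  }
  mode1 <- rad2deg(f1$mu) %% 360
  if (circ_dist(mode1, motion_deg) <= guard) {
    return(call_out("no_effect", mode1))
  }
  s <- circ_signed(motion_deg, mode1)
  between <- sign(s) == sign(d) && abs(s) > guard && abs(s) < abs(d) - guard
  if (between) return(call_out("vector_averaging", mode1))
  call_out("other", mode1)
}

#' Calibrate the perturbation strength of a module
#'
#' Bisection on the additive drive so that the median (over units)
#' circular-mean choice shift toward the preference, at a 60-degree
#' motion-to-preference offset under neutral reward alignment, is close to
#' a target (20 degrees by default) — a fixed, module-specific operating
#' point for all perturbation experiments.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param units Data frame from [tuned_units()]; default picks 5.
#' @param target_shift_deg Target mean shift, degrees.
#' @param n_reps Repetitions per arm and unit.
#' @param coherence Trial coherence.
#' @param max_strength Upper bisection bound.
#' @param iters Bisection iterations.
#' @param site_width Site half-width, degrees (see [perturbation_site()]).
#' @param seed Seed.
#' @return The calibrated strength (unitless additive drive).
#' @export
calibrate_perturbation <- function(model,
                                   module_tag = c("mt_like", "dlpfc_like"),
                                   units = NULL, target_shift_deg = 20,
                                   n_reps = 100, coherence = 0.5,
                                   max_strength = 8, iters = 7,
                                   site_width = 30, seed = 1) {
  module_tag <- match.arg(module_tag)
  if (is.null(units)) units <- tuned_units(model, module_tag, 5, seed = seed)
  info <- unit_info(model, module_tag)
  sites <- lapply(units$unit, function(u) {
    perturbation_site(model, module_tag, u, site_width, info)
  })
  shift_at <- function(strength) {
    sh <- vapply(seq_len(nrow(units)), function(i) {
      tr <- neutral_trial(sites[[i]]$preference_deg, 60, coherence,
                          centers = model$config$task$inc_centers)
      tb <- run_perturbation_experiment(
        model, list(module = module_tag, unit = sites[[i]]$units,
                    strength = strength), tr,
        ceiling(n_reps / nrow(tr)), seed = derive_seed(seed, i))
      mp <- circ_mean(tb$choice_deg[tb$perturbed])
      mc <- circ_mean(tb$choice_deg[!tb$perturbed])
      towards <- sign(circ_signed(tr$motion_deg[1], sites[[i]]$preference_deg))
      towards * circ_signed(mc, mp)
    }, numeric(1))
    stats::median(sh)
  }
  # the dose-response need not be monotone (attractor capture saturates
  # or reverses), so scan a geometric strength grid and refine around the
  # strength whose shift is closest to the target
  grid <- max_strength / 2^((iters - 1):0)
  shifts <- vapply(grid, shift_at, numeric(1))
  k <- which.min(abs(shifts - target_shift_deg))
  lo <- if (k > 1) grid[k - 1] else grid[k] / 2
  hi <- if (k < length(grid)) grid[k + 1] else grid[k]
  cand <- c(grid[k], lo + (hi - lo) * c(0.25, 0.5, 0.75))
  cshifts <- c(shifts[k], vapply(cand[-1], shift_at, numeric(1)))
  cand[which.min(abs(cshifts - target_shift_deg))]
}

#' Offset sweep: extent of the vector-averaging regime
#'
#' For each absolute motion-to-preference offset, runs a perturbation
#' experiment for every unit under neutral reward alignment, classifies
#' each unit's perturbation-trial choice distribution, and takes the
#' majority regime across units. Returns the largest offset whose majority
#' call is vector averaging.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param units Data frame from [tuned_units()].
#' @param offsets Offsets to test, degrees.
#' @param strength Perturbation strength (from
#'   [calibrate_perturbation()]).
#' @param n_reps Perturbation trials per unit and offset.
#' @param coherence Trial coherence.
#' @param site_width Site half-width, degrees.
#' @param seed Seed.
#' @return List with `va_limit_deg` (largest majority-vector-averaging
#'   offset, `NA` if none) and `table` (offset x unit regime calls).
#' @export
offset_sweep <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                         units, offsets = seq(10, 180, by = 10),
                         strength, n_reps = 200, coherence = 0.5,
                         site_width = 30, seed = 1) {
  module_tag <- match.arg(module_tag)
  stopifnot(nrow(units) >= 1)
  info <- unit_info(model, module_tag)
  sites <- lapply(units$unit, function(u) {
    perturbation_site(model, module_tag, u, site_width, info)
  })
  rows <- list()
  for (off in offsets) {
    for (i in seq_len(nrow(units))) {
      tr <- neutral_trial(sites[[i]]$preference_deg, off, coherence,
                          centers = model$config$task$inc_centers)
      tb <- run_perturbation_experiment(
        model, list(module = module_tag, unit = sites[[i]]$units,
                    strength = strength), tr, n_reps,
        seed = derive_seed(seed, off * 100 + i))
      # one homogeneous classification per interleaved reward condition,
      # each against its own control distribution
      for (cc in unique(tb$inc_center_deg)) {
        sub <- tb[tb$inc_center_deg == cc, ]
        anchor <- circ_mean(sub$choice_deg[!sub$perturbed])
        rc <- classify_regime(sub$choice_deg[sub$perturbed], anchor,
                              sites[[i]]$preference_deg)
        rows[[length(rows) + 1]] <- data.frame(
          offset_deg = off, unit = units$unit[i], inc_center_deg = cc,
          regime = rc$regime, midpoint_mass = rc$midpoint_mass)
      }
    }
  }
  tab <- do.call(rbind, rows)
  maj <- vapply(offsets, function(off) {
    r <- tab$regime[tab$offset_deg == off]
    names(which.max(table(r)))
  }, character(1))
  va <- offsets[maj == "vector_averaging"]
  list(va_limit_deg = if (length(va)) max(va) else NA_real_,
       table = tab, majority = data.frame(offset_deg = offsets, regime = maj))
}

# Trial with the preference aligned to the increased or the decreased
# reward center, at a fixed motion offset from the preference. The reward
# condition is one of the task's two trained conditions: for a unit whose
# preference sits inside the region of center c*, the condition with the
# increased center at c* is the increased-aligned class and the antipodal
# condition is the decreased-aligned class.
aligned_trial <- function(preference, align = c("increased", "decreased"),
                          offset = 100, coherence = 0.5,
                          centers = c(45, 225), dec_offset = 180) {
  align <- match.arg(align)
  cstar <- centers[which.min(circ_dist(preference, centers))]
  inc <- if (align == "increased") cstar else (cstar + dec_offset) %% 360
  data.frame(motion_deg = (preference - offset) %% 360,
             inc_center_deg = inc %% 360,
             dec_center_deg = (inc + dec_offset) %% 360,
             coherence = coherence)
}

#' Reward-condition interaction of the perturbation effect
#'
#' Effect size per alignment class is the total variation distance of the
#' perturbation-minus-control choice map from zero; the index is
#' effect(preference aligned with increased center) minus
#' effect(aligned with decreased center). Modules with joint
#' reward-and-motion formatting show a positive index; separable modules
#' show little dependence.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param units Data frame from [tuned_units()].
#' @param strength Perturbation strength.
#' @param offset Motion-to-preference offset, degrees.
#' @param n_reps Repetitions per arm and unit.
#' @param coherence Trial coherence.
#' @param site_width Site half-width, degrees.
#' @param seed Seed.
#' @return List with `index`, `effect_increased`, `effect_decreased`.
#' @export
reward_interaction_index <- function(model,
                                     module_tag = c("mt_like", "dlpfc_like"),
                                     units, strength, offset = 100,
                                     n_reps = 200, coherence = 0.5,
                                     site_width = 30, seed = 1) {
  module_tag <- match.arg(module_tag)
  info <- unit_info(model, module_tag)
  sites <- lapply(units$unit, function(u) {
    perturbation_site(model, module_tag, u, site_width, info)
  })
  effect <- function(align) {
    tv <- vapply(seq_len(nrow(units)), function(i) {
      tr <- aligned_trial(sites[[i]]$preference_deg, align, offset, coherence,
                          centers = model$config$task$inc_centers)
      tb <- run_perturbation_experiment(
        model, list(module = module_tag, unit = sites[[i]]$units,
                    strength = strength), tr, n_reps,
        seed = derive_seed(seed, i + ifelse(align == "increased", 0, 500)))
      dm <- delta_choice_map(tb)
      0.5 * sum(abs(dm$delta))
    }, numeric(1))
    mean(tv)
  }
  ei <- effect("increased"); ed <- effect("decreased")
  list(index = ei - ed, effect_increased = ei, effect_decreased = ed)
}

#' Perturbation effect as a function of motion coherence
#'
#' Lowering coherence weakens the sensory evidence relative to the
#' perturbation. The per-coherence effect size is the circular-mean choice
#' shift toward the preference for the sensory module and the
#' preference-mode mass (fraction of perturbation choices within the mode
#' tolerance of the preference) for the decision module.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param units Data frame from [tuned_units()].
#' @param strength Perturbation strength.
#' @param coherences At least 3 coherence levels.
#' @param offset Motion-to-preference offset, degrees.
#' @param n_reps Repetitions per arm and unit.
#' @param site_width Site half-width, degrees.
#' @param seed Seed.
#' @return Data frame with `coherence`, `shift_deg`, `pref_mass`.
#' @export
coherence_sweep <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                            units, strength,
                            coherences = c(0.2, 0.5, 1), offset = 100,
                            n_reps = 200, site_width = 30, seed = 1) {
  module_tag <- match.arg(module_tag)
  stopifnot(length(coherences) >= 3)
  info <- unit_info(model, module_tag)
  sites <- lapply(units$unit, function(u) {
    perturbation_site(model, module_tag, u, site_width, info)
  })
  out <- lapply(coherences, function(coh) {
    res <- vapply(seq_len(nrow(units)), function(i) {
      tr <- neutral_trial(sites[[i]]$preference_deg, offset, coh,
                          centers = model$config$task$inc_centers)
      tb <- run_perturbation_experiment(
        model, list(module = module_tag, unit = sites[[i]]$units,
                    strength = strength), tr,
        ceiling(n_reps / nrow(tr)), seed = derive_seed(seed, round(coh * 1000) + i))
      pc <- tb$choice_deg[tb$perturbed]
      cc <- tb$choice_deg[!tb$perturbed]
      towards <- sign(circ_signed(tr$motion_deg[1], sites[[i]]$preference_deg))
      c(shift = towards * circ_signed(circ_mean(cc), circ_mean(pc)),
        mass = mean(circ_dist(pc, sites[[i]]$preference_deg) <= 25))
    }, numeric(2))
    data.frame(coherence = coh, shift_deg = mean(res["shift", ]),
               pref_mass = mean(res["mass", ]))
  })
  do.call(rbind, out)
}

#' Regime dissociation experiment at a fixed offset
#'
#' Runs the headline perturbation comparison: for each module, perturbs
#' `n_units` aligned-preference sites at a fixed motion-to-preference
#' offset in the increased-aligned reward condition (the condition in
#' which the perturbed site's preference carries the increased reward),
#' classifies each site's perturbation-trial choice distribution relative
#' to the mean control choice and the site preference, and reports the
#' per-module majority call.
#'
#' @param model A `popformat_model`.
#' @param n_units Sites per module.
#' @param offset Motion-to-preference offset, degrees.
#' @param strengths Optional named list (`mt_like`, `dlpfc_like`) of
#'   perturbation strengths; calibrated on neutral sites when missing.
#' @param n_reps Repetitions per arm and site.
#' @param coherence Trial coherence.
#' @param seed Seed.
#' @return List per module with `majority`, `calls` (data frame of per-site
#'   regimes and midpoint masses), and `strength`.
#' @export
regime_dissociation <- function(model, n_units = 5, offset = 100,
                                strengths = NULL, n_reps = 200,
                                coherence = 0.5, seed = 1) {
  out <- list()
  for (mtag in c("mt_like", "dlpfc_like")) {
    units <- tuned_units(model, mtag, n_units, "aligned",
                         seed = derive_seed(seed, 21))
    strength <- strengths[[mtag]]
    if (is.null(strength)) {
      ncal <- tuned_units(model, mtag, n_units, "neutral",
                          seed = derive_seed(seed, 22))
      strength <- calibrate_perturbation(model, mtag, ncal,
                                         coherence = coherence,
                                         seed = derive_seed(seed, 23))
    }
    info <- unit_info(model, mtag)
    calls <- lapply(seq_len(nrow(units)), function(i) {
      site <- perturbation_site(model, mtag, units$unit[i], info = info)
      tr <- aligned_trial(site$preference_deg, "increased", offset,
                          coherence, centers = model$config$task$inc_centers)
      tb <- run_perturbation_experiment(
        model, list(module = mtag, unit = site$units, strength = strength),
        tr, n_reps, seed = derive_seed(seed, 30 + i))
      rc <- classify_regime(tb$choice_deg[tb$perturbed],
                            circ_mean(tb$choice_deg[!tb$perturbed]),
                            site$preference_deg)
      data.frame(unit = units$unit[i], regime = rc$regime,
                 midpoint_mass = rc$midpoint_mass)
    })
    calls <- do.call(rbind, calls)
    out[[mtag]] <- list(
      majority = names(which.max(table(calls$regime))),
      calls = calls, strength = strength)
  }
  out
}
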