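# 31-bit polynomial rolling hash over the serialized object; enough to
# fingerprint a configuration in output manifests
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Global run configuration
#'
#' One object holding the per-stage configurations and the global seed.
#' Every stochastic stage consumes a named sub-seed derived from the
#' global seed, and every output directory carries a manifest with the
#' configuration hash and the sub-seeds used.
#'
#' @param seed Global integer seed.
#' @param tuning_draws Heterogeneity draws for the tuning simulation.
#' @param n_sessions Paired sessions for the synthetic-recordings stage.
#' @param rnn An [rnn_config()].
#' @param session A [session_spec()].
#' @param gain A [gain_model()].
#' @param n_units Perturbed units per module.
#' @param n_reps Perturbation repetitions per condition and arm.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, tuning_draws = 50, n_sessions = 15,
                       rnn = rnn_config(), session = session_spec(),
                       gain = gain_model(), n_units = 5, n_reps = 200) {
  structure(
    list(seed = as.integer(seed), tuning_draws = tuning_draws,
         n_sessions = n_sessions, rnn = rnn, session = session,
         gain = gain, n_units = n_units, n_reps = n_reps),
    class = "run_config"
  )
}

write_manifest <- function(out_dir, tag, config, seeds, extra = NULL) {
  manifest <- c(list(
    figure_tag = tag,
    config_hash = config_hash(config),
    global_seed = config$seed,
    sub_seeds = as.list(seeds),
    package_version = as.character(utils::packageVersion("popformat")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Reproduce the data behind one figure-style analysis
#'
#' Each tag runs one stage of the pipeline end to end and writes plain
#' CSV/JSON data tables plus a manifest (configuration hash and every
#' sub-seed used) to `out_dir`:
#' \describe{
#'   \item{`fig1_sim`}{gain-modulated tuning simulation: per-draw
#'     formatting angles and one example mean-response table.}
#'   \item{`fig2_synthetic`}{synthetic paired sessions: per-session
#'     estimated angle pairs and the paired signed-rank comparison.}
#'   \item{`fig3_behavior`}{trained model choices on held-out trials and
#'     the reward-bias summary.}
#'   \item{`fig3_fixed_points`}{fixed points of both modules with
#'     2-D/3-D projections.}
#'   \item{`fig4_perturbation`}{perturbation experiments at a 100-degree
#'     offset: choice tables, perturbation-minus-control maps, regime
#'     calls, and reward-interaction indices.}
#' }
#'
#' @param figure_tag One of the tags above.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param model Optional pre-trained `popformat_model` (otherwise trained
#'   on demand for the tags that need one).
#' @return Invisibly, the output directory.
#' @export
reproduce <- function(figure_tag = c("fig1_sim", "fig2_synthetic",
                                     "fig3_behavior", "fig3_fixed_points",
                                     "fig4_perturbation"),
                      config = run_config(), out_dir = figure_tag,
                      model = NULL) {
  figure_tag <- match.arg(figure_tag)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  need_model <- figure_tag %in% c("fig3_behavior", "fig3_fixed_points",
                                  "fig4_perturbation")
  if (need_model && is.null(model)) {
    seeds$train <- derive_seed(config$seed, 1)
    model <- train_two_stage(config$rnn, seed = seeds$train)
    save_model(model, file.path(out_dir, "model.json"))
  }
  switch(figure_tag,
    fig1_sim = {
      seeds$tuning <- derive_seed(config$seed, 2)
      sw <- tuning_theta_sweep(config$tuning_draws, gm = config$gain,
                               seed = seeds$tuning)
      utils::write.csv(sw, file.path(out_dir, "theta_by_draw.csv"),
                       row.names = FALSE)
      pop <- build_population()
      g <- draw_condition_gains(pop, gm = config$gain,
                                seed = derive_seed(seeds$tuning, 1))
      means <- simulate_mean_responses(pop, g)
      flat <- expand.grid(direction = as.numeric(dimnames(means)[[1]]),
                          condition = seq_len(dim(means)[2]))
      flat <- cbind(flat, matrix(aperm(means, c(1, 2, 3)),
                                 nrow = nrow(flat),
                                 dimnames = list(NULL,
                                   paste0("unit", seq_len(dim(means)[3])))))
      utils::write.csv(flat, file.path(out_dir, "example_mean_responses.csv"),
                       row.names = FALSE)
    },
    fig2_synthetic = {
      seeds$synth <- derive_seed(config$seed, 3)
      pairs <- generate_area_pair(config$n_sessions, spec = config$session,
                                  seed = seeds$synth)
      est <- t(vapply(pairs, function(p) {
        c(theta_a = formatting_angle(p$a$session)$theta_deg,
          theta_b = formatting_angle(p$b$session)$theta_deg,
          truth_a = unname(p$truth_theta["a"]),
          truth_b = unname(p$truth_theta["b"]))
      }, numeric(4)))
      df <- data.frame(session = seq_len(nrow(est)), est)
      utils::write.csv(df, file.path(out_dir, "theta_pairs.csv"),
                       row.names = FALSE)
      cmp <- compare_areas(df$theta_a, df$theta_b)
      jsonlite::write_json(
        list(p_value = cmp$p.value, statistic = cmp$statistic,
             mean_theta_a = cmp$mean_pair[1], mean_theta_b = cmp$mean_pair[2],
             n = cmp$n),
        file.path(out_dir, "area_comparison.json"),
        auto_unbox = TRUE, digits = NA)
    },
    fig3_behavior = {
      seeds$eval <- derive_seed(config$seed, 4)
      ev <- evaluate_dlpfc(model, n = 512, seed = seeds$eval,
                           coherence = 0.5)
      tb <- cbind(ev$trials, choice_deg = ev$choices)
      utils::write.csv(tb, file.path(out_dir, "choices.csv"),
                       row.names = FALSE)
      off <- circ_signed(tb$inc_center_deg, tb$motion_deg)
      serr <- circ_signed(tb$motion_deg, tb$choice_deg)
      sel <- abs(off) > 0 & abs(off) < 150
      jsonlite::write_json(
        list(median_profile_r = ev$median_r,
             choice_mae_deg = ev$choice_mae_deg,
             mean_bias_toward_increased_deg =
               mean(-sign(off[sel]) * serr[sel])),
        file.path(out_dir, "behavior_summary.json"),
        auto_unbox = TRUE, digits = NA)
    },
    fig3_fixed_points = {
      seeds$fp <- derive_seed(config$seed, 5)
      for (mtag in c("mt_like", "dlpfc_like")) {
        fps <- module_fixed_points(model, mtag, seed = seeds$fp)
        pts <- do.call(rbind, fps$point)
        pr <- project_points(pts, "motion_variance", k = 3,
                             directions = fps$motion_deg,
                             conditions = fps$inc_center_deg)
        utils::write.csv(
          data.frame(motion_deg = fps$motion_deg,
                     inc_center_deg = fps$inc_center_deg,
                     speed = fps$speed, stable = fps$stable,
                     dim1 = pr$coords[, 1], dim2 = pr$coords[, 2],
                     dim3 = pr$coords[, 3]),
          file.path(out_dir, paste0("fixed_points_", mtag, ".csv")),
          row.names = FALSE)
      }
    },
    fig4_perturbation = {
      seeds$perturb <- derive_seed(config$seed, 6)
      out <- list()
      for (mtag in c("mt_like", "dlpfc_like")) {
        units <- tuned_units(model, mtag, config$n_units, "aligned",
                             seed = seeds$perturb)
        strength <- calibrate_perturbation(model, mtag, units,
                                           seed = seeds$perturb)
        info <- unit_info(model, mtag)
        calls <- list()
        maps <- list()
        for (i in seq_len(nrow(units))) {
          site <- perturbation_site(model, mtag, units$unit[i], info = info)
          for (al in c("increased", "decreased")) {
            tr <- aligned_trial(site$preference_deg, al, 100, 0.5,
                                centers = model$config$task$inc_centers)
            tb <- run_perturbation_experiment(
              model, list(module = mtag, unit = site$units,
                          strength = strength), tr, config$n_reps,
              seed = derive_seed(seeds$perturb, i))
            rc <- classify_regime(tb$choice_deg[tb$perturbed],
                                  circ_mean(tb$choice_deg[!tb$perturbed]),
                                  site$preference_deg)
            dm <- delta_choice_map(tb)
            dm$unit <- units$unit[i]; dm$alignment <- al
            maps[[length(maps) + 1]] <- dm
            calls[[length(calls) + 1]] <- list(
              unit = units$unit[i], alignment = al, regime = rc$regime,
              midpoint_mass = rc$midpoint_mass,
              mode_locations_deg = rc$mode_locations_deg)
          }
        }
        ri <- reward_interaction_index(model, mtag, units, strength,
                                       seed = seeds$perturb)
        utils::write.csv(do.call(rbind, maps),
                         file.path(out_dir, paste0("delta_maps_", mtag,
                                                   ".csv")),
                         row.names = FALSE)
        out[[mtag]] <- list(strength = strength, regimes = calls,
                            reward_interaction = ri)
      }
      jsonlite::write_json(out, file.path(out_dir, "perturbation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  )
  write_manifest(out_dir, figure_tag, config, seeds)
  invisible(out_dir)
}

#' Read a run configuration from a YAML file
#'
#' The YAML file may contain top-level `seed`, `tuning_draws`,
#' `n_sessions`, `n_units`, `n_reps`, and nested `rnn`, `session`, `gain`
#' blocks whose fields override the corresponding constructor defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, block) {
    if (is.null(block)) return(fn())
    do.call(fn, block)
  }
  run_config(
    seed = if (is.null(y$seed)) 1 else y$seed,
    tuning_draws = if (is.null(y$tuning_draws)) 50 else y$tuning_draws,
    n_sessions = if (is.null(y$n_sessions)) 15 else y$n_sessions,
    rnn = build(rnn_config, y$rnn),
    session = build(session_spec, y$session),
    gain = build(gain_model, y$gain),
    n_units = if (is.null(y$n_units)) 5 else y$n_units,
    n_reps = if (is.null(y$n_reps)) 200 else y$n_reps
  )
}
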