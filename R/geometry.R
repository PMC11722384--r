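#' Recording-session container
#'
#' Trials-by-units activity (spike counts or model-unit activations) with a
#' motion-direction label and a reward-condition label per trial.
#'
#' @param counts Numeric trials x units matrix.
#' @param directions Direction label (degrees) per trial, assumed on the
#'   stimulus grid.
#' @param conditions Reward-condition label per trial (factor-like).
#' @param area Free-text area tag (e.g. `"MT"`, `"dlPFC"`).
#' @return An object of class `session_data`.
#' @export
session_data <- function(counts, directions, conditions, area = "") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(directions),
            nrow(counts) == length(conditions))
  if (ncol(counts) < 3) stop("session needs at least 3 units")
  directions <- directions %% 360
  if (length(unique(directions)) < 4) {
    stop("session needs at least 4 distinct directions")
  }
  if (length(unique(conditions)) < 2) {
    stop("session needs at least 2 reward conditions")
  }
  structure(
    list(counts = counts, directions = directions,
         conditions = as.character(conditions), area = area),
    class = "session_data"
  )
}

#' Mean response per direction bin and reward condition
#'
#' Trial-averaged responses on the grid of observed direction labels and
#' conditions. Every (direction, condition) cell must contain at least one
#' trial.
#'
#' @param session A [session_data()] object.
#' @return Array `[n_directions, n_conditions, n_units]` with direction and
#'   condition dimnames.
#' @export
condition_means <- function(session) {
  stopifnot(inherits(session, "session_data"))
  dirs <- sort(unique(session$directions))
  conds <- sort(unique(session$conditions))
  n_unit <- ncol(session$counts)
  out <- array(NA_real_, dim = c(length(dirs), length(conds), n_unit),
               dimnames = list(direction = dirs, condition = conds,
                               unit = NULL))
  for (i in seq_along(dirs)) {
    for (j in seq_along(conds)) {
      sel <- session$directions == dirs[i] & session$conditions == conds[j]
      if (!any(sel)) {
        stop("empty cell: direction ", dirs[i], ", condition ", conds[j])
      }
      out[i, j, ] <- colMeans(session$counts[sel, , drop = FALSE])
    }
  }
  out
}

fix_sign <- function(v, tol = 1e-10) {
  i <- which(abs(v) > tol)[1]
  if (!is.na(i) && v[i] < 0) -v else v
}

#' Motion-variance plane
#'
#' The two orthonormal directions of unit space that account for the most
#' variance across motion-direction means (averaged over reward
#' conditions). Deterministic up to sign; signs are fixed by making the
#' first non-zero coordinate of each axis positive.
#'
#' @param means Direction x condition x unit mean array from
#'   [condition_means()] (or any array with those dimensions).
#' @return Units x 2 matrix with orthonormal columns.
#' @export
motion_axes <- function(means) {
  stopifnot(length(dim(means)) == 3)
  if (dim(means)[1] < 3) stop("need at least 3 direction bins")
  m <- apply(means, c(1, 3), mean)           # dir x unit, averaged over cond
  mc <- sweep(m, 2, colMeans(m))             # center across directions
  sv <- svd(mc)
  if (sv$d[2] <= max(dim(mc)) * sv$d[1] * 1e-10) {
    stop("direction means have rank < 2; cannot define a motion plane")
  }
  ax <- sv$v[, 1:2, drop = FALSE]
  apply(ax, 2, fix_sign)
}

#' Reward axis
#'
#' With two reward conditions (the default design), the normalized
#' difference of the two condition means, each averaged across directions.
#' With more conditions, the top principal axis of the condition means.
#'
#' @param means Direction x condition x unit mean array.
#' @return Unit-norm vector in unit space.
#' @export
reward_axis <- function(means) {
  stopifnot(length(dim(means)) == 3)
  cm <- apply(means, c(2, 3), mean)           # cond x unit
  if (nrow(cm) == 2) {
    d <- cm[1, ] - cm[2, ]
  } else {
    cmc <- sweep(cm, 2, colMeans(cm))
    d <- svd(cmc)$v[, 1]
  }
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12 * max(1, max(abs(cm)))) {
    stop("reward conditions have identical means; no reward axis")
  }
  fix_sign(d / nrm)
}

#' Angle between the reward axis and the motion plane
#'
#' `theta = acos(||projection of the reward axis onto the motion plane||)`,
#' in degrees. 90 degrees means the reward axis is orthogonal to the motion
#' plane (fully separable formatting); 0 degrees means it lies inside the
#' plane (fully joint formatting).
#'
#' @param axes Units x 2 orthonormal motion-plane basis.
#' @param r Unit-norm reward axis.
#' @return Angle in `[0, 90]` degrees.
#' @export
subspace_angle <- function(axes, r) {
  stopifnot(is.matrix(axes), ncol(axes) == 2, length(r) == nrow(axes))
  gram <- crossprod(axes)
  if (max(abs(gram - diag(2))) > 1e-6) stop("motion axes are not orthonormal")
  if (abs(sum(r^2) - 1) > 1e-6) stop("reward axis is not unit norm")
  p <- sqrt(sum((crossprod(axes, r))^2))
  rad2deg(acos(min(1, max(0, p))))
}

#' Formatting angle of a population
#'
#' End-to-end estimator: condition means, motion plane, reward axis, and
#' the angle between them. `method = "plane"` (default) measures the angle
#' between the reward axis and the top-2 motion plane; `method = "axis"`
#' measures the angle between the single top motion axis and the reward
#' axis.
#'
#' @param x A [session_data()] object or a direction x condition x unit
#'   mean array.
#' @param method `"plane"` or `"axis"`.
#' @return List with `theta_deg`, `motion_axes`, `reward_axis`, and
#'   `variance_captured` (fraction of direction-mean variance in the motion
#'   plane).
#' @export
formatting_angle <- function(x, method = c("plane", "axis")) {
  method <- match.arg(method)
  means <- if (inherits(x, "session_data")) condition_means(x) else x
  ax <- motion_axes(means)
  r <- reward_axis(means)
  m <- apply(means, c(1, 3), mean)
  mc <- sweep(m, 2, colMeans(m))
  d2 <- svd(mc)$d^2
  varcap <- sum(d2[1:2]) / sum(d2)
  theta <- if (method == "plane") {
    subspace_angle(ax, r)
  } else {
    rad2deg(acos(min(1, abs(sum(ax[, 1] * r)))))
  }
  list(theta_deg = theta, motion_axes = ax, reward_axis = r,
       variance_captured = varcap, method = method)
}

# Exact two-sided signed-rank p-value with mid-ranks for ties, by dynamic
# programming over the distribution of the positive-rank sum under random
# sign flips. Mid-ranks are doubled so the DP runs on integers. Zeros must
# already be dropped.
signed_rank_exact_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled mid-ranks
  v <- sum(r2[d > 0])
  total <- sum(r2)
  # dist[k + 1] = number of sign assignments with doubled-rank sum k
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  p_lo <- sum(dist[seq_len(v + 1)])
  p_hi <- sum(dist[seq(v + 1, total + 1)])
  min(1, 2 * min(p_lo, p_hi))
}

#' Paired comparison of formatting angles across areas
#'
#' Two-sided paired Wilcoxon signed-rank test on per-session formatting
#' angles from two simultaneously recorded areas. For n <= 25 the exact
#' sign-flip distribution of the rank sum is used (mid-ranks for tied
#' magnitudes, zero differences dropped); above that, the usual normal
#' approximation with continuity correction via [stats::wilcox.test()].
#'
#' @param theta_a,theta_b Paired per-session angles, degrees.
#' @return List with `p.value`, `statistic` (positive-rank sum), per-session
#'   `differences`, `mean_pair` (the across-session mean of each area), and
#'   `n`.
#' @export
compare_areas <- function(theta_a, theta_b) {
  stopifnot(length(theta_a) == length(theta_b))
  n <- length(theta_a)
  if (n < 6) stop("need at least 6 paired sessions (got ", n, ")")
  d <- theta_a - theta_b
  if (all(d == 0)) {
    return(list(p.value = 1, statistic = NA_real_, differences = d,
                mean_pair = c(mean(theta_a), mean(theta_b)), n = n))
  }
  dnz <- d[d != 0]
  v <- sum(rank(abs(dnz))[dnz > 0])
  p <- if (n <= 25) {
    signed_rank_exact_p(dnz)
  } else {
    suppressWarnings(
      stats::wilcox.test(theta_a, theta_b, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value
    )
  }
  list(p.value = p, statistic = v, differences = d,
       mean_pair = c(mean(theta_a), mean(theta_b)), n = n)
}

#' Cross-validated decoding sanity check
#'
#' 5-fold cross-validated nearest-class-centroid decoding of the reward
#' condition (accuracy) and the motion direction (circular mean absolute
#' error), with chance levels reported alongside.
#'
#' @param session A [session_data()] object.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return List with `condition_accuracy`, `condition_chance`,
#'   `direction_mae_deg`, `direction_mae_chance_deg`.
#' @export
decode_check <- function(session, folds = 5, seed = 1) {
  stopifnot(inherits(session, "session_data"))
  dirs <- sort(unique(session$directions))
  conds <- sort(unique(session$conditions))
  cell <- interaction(session$directions, session$conditions, drop = TRUE)
  if (min(table(cell)) < folds) {
    stop("need at least ", folds, " trials per (direction, condition) cell")
  }
  fold_id <- with_seed(seed, {
    out <- integer(length(cell))
    for (lv in levels(cell)) {
      idx <- which(cell == lv)
      out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    out
  })
  pred_dir <- numeric(length(cell))
  pred_cond <- character(length(cell))
  key <- expand.grid(direction = dirs, condition = conds,
                     stringsAsFactors = FALSE)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    cent <- t(vapply(seq_len(nrow(key)), function(k) {
      sel <- !test & session$directions == key$direction[k] &
        session$conditions == key$condition[k]
      colMeans(session$counts[sel, , drop = FALSE])
    }, numeric(ncol(session$counts))))
    x <- session$counts[test, , drop = FALSE]
    d2 <- outer(rowSums(x^2), rowSums(cent^2), "+") - 2 * x %*% t(cent)
    nearest <- max.col(-d2, ties.method = "first")
    pred_dir[test] <- key$direction[nearest]
    pred_cond[test] <- key$condition[nearest]
  }
  list(
    condition_accuracy = mean(pred_cond == session$conditions),
    condition_chance = 1 / length(conds),
    direction_mae_deg = circ_mae(pred_dir, session$directions),
    direction_mae_chance_deg = 90
  )
}

#' Write / read a session as a CSV pair
#'
#' Counts go in `<stem>_counts.csv` (trials x units) and labels in
#' `<stem>_labels.csv` (`direction_deg`, `condition`, `area`).
#'
#' @param session A [session_data()] object.
#' @param stem Path stem (no extension).
#' @return `read_session_csv` returns the [session_data()] object.
#' @export
write_session_csv <- function(session, stem) {
  utils::write.csv(as.data.frame(session$counts),
                   paste0(stem, "_counts.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(direction_deg = session$directions,
               condition = session$conditions, area = session$area),
    paste0(stem, "_labels.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(stem) {
  counts <- as.matrix(utils::read.csv(paste0(stem, "_counts.csv")))
  lab <- utils::read.csv(paste0(stem, "_labels.csv"))
  session_data(counts, lab$direction_deg, lab$condition,
               area = as.character(lab$area[1]))
}
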