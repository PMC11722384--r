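fp_preact <- function(module, x, u) {
  drop(module$W %*% x) + drop(module$U %*% u) + as.numeric(module$b)
}

fp_map <- function(module, x, u) {
  (1 - module$leak) * x +
    module$leak * drop(apply_nonlin(rbind(fp_preact(module, x, u)), module))
}

fp_jacobian <- function(module, x, u) {
  a <- fp_preact(module, x, u)
  d <- switch(module$nonlinearity,
              identity = rep(1, length(a)),
              relu = as.numeric(a > 0),
              1 - tanh(a)^2)
  (1 - module$leak) * diag(module$n_hidden) +
    module$leak * (d * module$W)
}

fp_speed <- function(module, x, u) {
  sqrt(sum((fp_map(module, x, u) - x)^2))
}

# iterate the map, then polish with damped Newton on F(x) - x = 0
fp_converge <- function(module, x, u, tol, max_iter) {
  for (i in seq_len(max_iter)) {
    xn <- fp_map(module, x, u)
    done <- sqrt(sum((xn - x)^2)) < tol
    x <- xn
    if (done) break
  }
  for (i in seq_len(50)) {
    r <- fp_map(module, x, u) - x
    if (sqrt(sum(r^2)) < tol * 1e-2) break
    J <- fp_jacobian(module, x, u) - diag(module$n_hidden)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    # damped: accept the largest step that reduces the residual
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (fp_speed(module, xn, u) < sqrt(sum(r^2)) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- x + lam * step
  }
  x
}

#' Find fixed points of a recurrent module under constant input
#'
#' Iterates the dynamics from each initial state until the state change
#' falls below `tol` (then polishes with damped Newton), deduplicates the
#' survivors by single-linkage clustering at a Euclidean radius (which is
#' order-independent), and assesses the stability of each survivor. Points
#' that fail to reach `tol` are dropped with a diagnostic attribute rather
#' than silently reported.
#'
#' @param module An `rnn_module`.
#' @param input Constant input vector (length `n_in`).
#' @param init_states Matrix of initial states (rows) or a single vector.
#' @param tol Convergence tolerance on the one-step speed `||F(x) - x||`.
#' @param max_iter Maximum map iterations per initial state.
#' @param dedup_radius Merge radius; default `1e-3` times the RMS scale of
#'   the converged states.
#' @param labels Optional data frame of per-initial-state labels (e.g.
#'   direction and condition); carried through to the output assignment.
#' @return An object of class `fixed_point_set`: list with `points`
#'   (k x n_hidden), `speeds`, `stable`, `leading_modulus`, `n_merged`
#'   (inits per point), and `assignment` (per-init point index, with
#'   labels if given; non-converged inits get `NA`).
#' @export
find_fixed_points <- function(module, input, init_states, tol = 1e-8,
                              max_iter = 5000, dedup_radius = NULL,
                              labels = NULL) {
  stopifnot(inherits(module, "rnn_module"))
  init_states <- rbind(init_states)
  n <- nrow(init_states)
  pts <- t(vapply(seq_len(n), function(i) {
    fp_converge(module, init_states[i, ], input, tol, max_iter)
  }, numeric(module$n_hidden)))
  speeds <- vapply(seq_len(n), function(i) fp_speed(module, pts[i, ], input),
                   numeric(1))
  ok <- speeds < tol
  assignment <- rep(NA_integer_, n)
  assign_df <- function(a) {
    df <- data.frame(point = a)
    if (!is.null(labels)) df <- cbind(labels, df)
    df
  }
  if (!any(ok)) {
    out <- structure(
      list(points = pts[0, , drop = FALSE], speeds = numeric(0),
           stable = logical(0), leading_modulus = numeric(0),
           n_merged = integer(0),
           assignment = assign_df(assignment)),
      class = "fixed_point_set"
    )
    attr(out, "diagnostic") <- paste0("no initial state converged below tol=",
                                      tol, "; min speed ", min(speeds))
    return(out)
  }
  good <- pts[ok, , drop = FALSE]
  if (is.null(dedup_radius)) {
    dedup_radius <- max(1e-3 * sqrt(mean(good^2)), 100 * tol)
  }
  cl <- if (nrow(good) == 1) 1L else {
    stats::cutree(stats::hclust(stats::dist(good), method = "single"),
                  h = dedup_radius)
  }
  k <- max(cl)
  reps <- t(vapply(seq_len(k), function(j) {
    colMeans(good[cl == j, , drop = FALSE])
  }, numeric(module$n_hidden)))
  rep_speeds <- vapply(seq_len(k), function(j) {
    fp_speed(module, reps[j, ], input)
  }, numeric(1))
  # a merged mean can sit off the attractor on a slow manifold; fall back
  # to the fastest-converged member if so
  for (j in seq_len(k)) {
    if (rep_speeds[j] >= tol) {
      members <- which(cl == j)
      best <- members[which.min(speeds[ok][members])]
      reps[j, ] <- good[best, ]
      rep_speeds[j] <- speeds[ok][best]
    }
  }
  stab <- lapply(seq_len(k), function(j) {
    assess_stability(module, reps[j, ], input, check_converged = FALSE)
  })
  assignment[ok] <- cl
  structure(
    list(points = reps, speeds = rep_speeds,
         stable = vapply(stab, `[[`, logical(1), "stable"),
         leading_modulus = vapply(stab, `[[`, numeric(1), "leading_modulus"),
         n_merged = as.integer(table(cl)),
         assignment = assign_df(assignment)),
    class = "fixed_point_set"
  )
}

#' Stability of a fixed point
#'
#' Computes the Jacobian of the discrete-time map at the point; the point
#' is stable iff all eigenvalue moduli are below `1 + eps_num`.
#'
#' @param module An `rnn_module`.
#' @param point State vector (a fixed point at tolerance `tol`).
#' @param input Constant input vector.
#' @param tol Tolerance at which `point` must be a fixed point.
#' @param eps_num Numerical slack on the unit circle.
#' @param check_converged If `TRUE` (default), error when `point` is not a
#'   fixed point at `tol`.
#' @return List with `stable` (logical) and `leading_modulus`.
#' @export
assess_stability <- function(module, point, input, tol = 1e-6,
                             eps_num = 1e-6, check_converged = TRUE) {
  if (check_converged && fp_speed(module, point, input) > tol) {
    stop("point is not a fixed point at tolerance ", tol)
  }
  ev <- eigen(fp_jacobian(module, point, input), only.values = TRUE)$values
  lm <- max(Mod(ev))
  list(stable = lm < 1 + eps_num, leading_modulus = lm)
}

#' Constant inputs for fixed-point analysis
#'
#' Builds the noise-free stimulus-epoch input vector of one (direction,
#' reward condition) pair for the sensory module, or the corresponding
#' decision-module input (the sensory module's fixed-point motion outputs
#' plus the reward-center channels).
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param motion Motion direction, degrees.
#' @param inc_center Increased-reward center, degrees.
#' @param coherence Coherence of the constant motion input.
#' @return Input vector of length 6.
#' @export
fixed_point_input <- function(model, module_tag = c("mt_like", "dlpfc_like"),
                              motion, inc_center, coherence = 1) {
  module_tag <- match.arg(module_tag)
  config <- model$config
  dec <- (inc_center + config$task$dec_offset) %% 360
  u_mt <- c(coherence * cos(deg2rad(motion)), coherence * sin(deg2rad(motion)),
            cos(deg2rad(inc_center)), sin(deg2rad(inc_center)),
            cos(deg2rad(dec)), sin(deg2rad(dec)))
  if (module_tag == "mt_like") return(u_mt)
  x0 <- numeric(model$mt$n_hidden)
  xf <- fp_converge(model$mt, x0, u_mt, 1e-10, 2000)
  y <- drop(model$mt$Z %*% xf + model$mt$c)
  c(y[1:2], u_mt[3:6])
}

#' Fixed points of a trained module across task conditions
#'
#' For every (direction, condition) pair, iterates the module from the
#' end-of-stimulus state of a noise-free trial (plus random restarts)
#' under the pair's constant input and collects the resulting fixed
#' points with labels.
#'
#' @param model A `popformat_model`.
#' @param module_tag `"mt_like"` or `"dlpfc_like"`.
#' @param directions Motion directions, degrees.
#' @param centers Increased-center positions, degrees.
#' @param n_random Random restarts per pair.
#' @param tol,max_iter Passed to [find_fixed_points()].
#' @param seed Seed for the restarts.
#' @return A data frame with one row per (direction, condition) pair:
#'   labels, fixed-point coordinates (as a matrix column `point`),
#'   `speed`, `stable`, `leading_modulus`, `n_points` found for the pair.
#' @export
module_fixed_points <- function(model,
                                module_tag = c("mt_like", "dlpfc_like"),
                                directions = seq(0, 315, by = 45),
                                centers = c(45, 225), n_random = 3,
                                tol = 1e-8, max_iter = 5000, seed = 1) {
  module_tag <- match.arg(module_tag)
  config <- model$config
  module <- if (module_tag == "mt_like") model$mt else model$dlpfc
  grid <- expand.grid(motion_deg = directions, inc_center_deg = centers)
  grid$dec_center_deg <- (grid$inc_center_deg + config$task$dec_offset) %% 360
  grid$coherence <- 1
  rt <- run_trials(model, grid, keep_states = TRUE)
  states <- if (module_tag == "mt_like") rt$mt_state else rt$dlpfc_state
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    u <- fixed_point_input(model, module_tag, grid$motion_deg[i],
                           grid$inc_center_deg[i])
    inits <- rbind(states[i, ],
                   with_seed(derive_seed(seed, i), {
                     matrix(stats::rnorm(n_random * module$n_hidden,
                                         sd = stats::sd(states)),
                            n_random)
                   }))
    fps <- find_fixed_points(module, u, inits, tol = tol,
                             max_iter = max_iter)
    if (nrow(fps$points) == 0) {
      return(NULL)
    }
    # the point reached from the trial-end state is the labelled one
    j <- fps$assignment$point[1]
    if (is.na(j)) j <- which.min(fps$speeds)
    data.frame(motion_deg = grid$motion_deg[i],
               inc_center_deg = grid$inc_center_deg[i],
               speed = fps$speeds[j], stable = fps$stable[j],
               leading_modulus = fps$leading_modulus[j],
               n_points = nrow(fps$points),
               point = I(list(fps$points[j, ])))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  class(out) <- c("module_fixed_points", "data.frame")
  out
}

#' Low-dimensional projection of states or fixed points
#'
#' Projects points onto orthonormal axes chosen either as the
#' motion-variance plane (top principal axes of direction means, requires
#' direction and condition labels) or as ordinary principal components.
#'
#' @param points Matrix of points (rows) in unit space.
#' @param axes_from `"motion_variance"` or `"principal_components"`.
#' @param k Number of axes (2 or 3).
#' @param directions,conditions Labels per point (required for
#'   `"motion_variance"`).
#' @return List with `coords` (points x k), `axes` (units x k,
#'   orthonormal), and `variance_captured`.
#' @export
project_points <- function(points,
                           axes_from = c("motion_variance",
                                         "principal_components"),
                           k = 2, directions = NULL, conditions = NULL) {
  axes_from <- match.arg(axes_from)
  points <- as.matrix(points)
  if (nrow(points) < k + 1) stop("need at least k + 1 points")
  ctr <- colMeans(points)
  pc <- sweep(points, 2, ctr)
  if (axes_from == "principal_components") {
    sv <- svd(pc)
    if (sv$d[k] <= max(dim(pc)) * sv$d[1] * 1e-12) {
      stop("degenerate covariance: rank < ", k)
    }
    axes <- sv$v[, seq_len(k), drop = FALSE]
    varcap <- sum(sv$d[seq_len(k)]^2) / sum(sv$d^2)
  } else {
    if (is.null(directions) || is.null(conditions)) {
      stop("motion_variance axes need direction and condition labels")
    }
    dirs <- sort(unique(directions))
    conds <- sort(unique(conditions))
    means <- array(NA_real_, c(length(dirs), length(conds), ncol(points)))
    for (i in seq_along(dirs)) for (j in seq_along(conds)) {
      sel <- directions == dirs[i] & conditions == conds[j]
      if (!any(sel)) stop("missing (direction, condition) cell")
      means[i, j, ] <- colMeans(points[sel, , drop = FALSE])
    }
    ax2 <- motion_axes(means)
    axes <- if (k == 2) ax2 else {
      # third axis: reward axis orthogonalized against the motion plane
      r <- reward_axis(means)
      r3 <- r - ax2 %*% crossprod(ax2, r)
      if (sqrt(sum(r3^2)) < 1e-10) stop("reward axis lies in the motion plane")
      cbind(ax2, r3 / sqrt(sum(r3^2)))
    }
    sv <- svd(pc)
    varcap <- sum((pc %*% axes)^2) / sum(sv$d^2)
  }
  axes <- apply(axes, 2, fix_sign)
  list(coords = pc %*% axes, axes = axes, variance_captured = varcap)
}

#' Ring-topology check for direction-labelled points
#'
#' Tests whether points ordered by motion direction form a closed
#' non-self-intersecting loop in the sense that each point's nearest
#' neighbor is one of its two direction-adjacent points.
#'
#' @param points Matrix of points (rows), one per direction.
#' @param directions Direction label (degrees) per point.
#' @return `TRUE` if the ring topology holds.
#' @export
ring_topology <- function(points, directions) {
  o <- order(directions)
  pts <- as.matrix(points)[o, , drop = FALSE]
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points")
  d2 <- as.matrix(stats::dist(pts))
  diag(d2) <- Inf
  all(vapply(seq_len(n), function(i) {
    nb <- which.min(d2[i, ])
    nb %in% c(i %% n + 1, (i - 2) %% n + 1)
  }, logical(1)))
}
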