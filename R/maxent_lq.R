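#' Linear + quadratic feature matrix for an environmental stack
#'
#' Builds the feature set of the minimal maximum-entropy model: each
#' environmental variable and its square (product, threshold and hinge
#' feature classes are deliberately absent), min-max scaled to `[0, 1]`
#' over the background cells. The same scaling is applied everywhere, so
#' presence features can fall slightly outside `[0, 1]` if they exceed the
#' background range. Variables constant on the background carry no
#' information and are dropped with a warning.
#'
#' @param env An `env_stack` (named list of `raster_layer`s on one grid).
#' @param background_cells Integer cell ids defining the scaling
#'   population.
#' @param variables Optional character vector restricting which layers are
#'   used (default all).
#' @return List of class `feature_matrix`: `values` (matrix, one row per
#'   grid cell, `NA` on invalid cells), `names`, `scaling` (per-feature
#'   min/max), `dropped`.
#' @export
build_features <- function(env, background_cells, variables = names(env)) {
  stopifnot(length(variables) >= 1)
  g <- env[[1]]$grid
  raw <- vapply(variables, function(nm) env[[nm]]$values,
                numeric(n_cells(g)))
  feats <- cbind(raw, raw^2)
  colnames(feats) <- c(variables, paste0(variables, "_sq"))
  lo <- apply(feats[background_cells, , drop = FALSE], 2L, min)
  hi <- apply(feats[background_cells, , drop = FALSE], 2L, max)
  const <- hi - lo <= 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(feats)[const], collapse = ", "))
  }
  keep <- which(!const)
  scaled <- sweep(feats[, keep, drop = FALSE], 2L, lo[keep], "-")
  scaled <- sweep(scaled, 2L, (hi - lo)[keep], "/")
  structure(list(values = scaled, names = colnames(feats)[keep],
                 scaling = data.frame(feature = colnames(feats)[keep],
                                      min = lo[keep], max = hi[keep]),
                 dropped = colnames(feats)[const], grid = g),
            class = "feature_matrix")
}

#' Sample background cells from a bias file
#'
#' The bias file is a binary layer marking every cell holding at least one
#' collection of any species in the target group; sampling the background
#' from it makes the background reflect survey effort (target-group
#' background). Cells are drawn uniformly without replacement; if fewer
#' than `n_bg` positive cells exist, all are used.
#'
#' @param bias Binary `raster_layer` (1 = surveyed).
#' @param n_bg Background size (default 10000).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Sorted integer vector of background cell ids.
#' @export
sample_background <- function(bias, n_bg = 10000, seed = 1) {
  pos <- which(!is.na(bias$values) & bias$values == 1)
  if (length(pos) == 0) stop("bias file has no positive cells")
  if (length(pos) <= n_bg) return(pos)
  set.seed(seed)
  sort(sample(pos, n_bg, replace = FALSE))
}

#' Build a bias file from occurrence records
#'
#' @param records Occurrence data.frame (any species) with valid
#'   coordinates.
#' @param grid A `grid_spec`.
#' @return Binary `raster_layer`, 1 where at least one record falls.
#' @export
bias_file <- function(records, grid) {
  cell <- point_to_cell(records$lon, records$lat, grid)
  v <- numeric(n_cells(grid))
  v[unique(cell[!is.na(cell)])] <- 1
  raster_layer(grid, v)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

maxent_objective <- function(lambda, f_pres_mean, F_bg, beta) {
  eta <- drop(F_bg %*% lambda)
  logZ <- log_sum_exp(eta)
  sum(lambda * f_pres_mean) - logZ - sum(beta * abs(lambda))
}

#' Fit the minimal maximum-entropy (Gibbs) model
#'
#' Maximises the L1-penalised log-likelihood of a Gibbs distribution over
#' the background cells,
#' `(1/m) sum_presences lambda.f(x) - log Z(lambda) - sum_j beta_j |lambda_j|`,
#' with `Z = sum_{x in B} exp(lambda.f(x))` and per-feature penalty
#' `beta_j = reg_multiplier * s_j / sqrt(m)` (`s_j` = feature standard
#' deviation over the presence cells, floored at 1e-4). The optimiser is
#' proximal gradient ascent with backtracking line search, so the
#' penalised objective is non-decreasing across iterations; the fit is
#' deterministic given presences, background and config. In the
#' unregularised limit the solution satisfies the constraint
#' `E_q[f_j] =` presence mean of `f_j`; with all features dropped or
#' infinite regularisation it reduces to the uniform distribution on the
#' background (maximum entropy).
#'
#' @param presence_cells Integer cell ids of presences (at least 5
#'   required). Deduplication to cells is the cleaning pipeline's job and
#'   is not repeated here, so passing duplicated cells weights their
#'   features accordingly.
#' @param background_cells Integer cell ids of the background sample.
#' @param features A `feature_matrix`.
#' @param reg_multiplier Regularisation multiplier c (default 1.0).
#' @param tol Convergence tolerance on the objective change
#'   (default 1e-7).
#' @param max_iter Iteration cap (default 500); non-convergence returns
#'   the best iterate with a warning.
#' @return List of class `maxent_model`: `lambda`, `beta`, `logZ`,
#'   `entropy` (H of the background distribution), `m`,
#'   `presence_cells`, `background_cells`, `feature_names`, `objective`
#'   (trace), `converged`.
#' @export
fit_maxent <- function(presence_cells, background_cells, features,
                       reg_multiplier = 1.0, tol = 1e-7, max_iter = 500) {
  m <- length(presence_cells)
  if (m < 5) stop("fewer than 5 presence cells")
  F_pres <- features$values[presence_cells, , drop = FALSE]
  F_bg <- features$values[background_cells, , drop = FALSE]
  if (anyNA(F_pres) || anyNA(F_bg))
    stop("presence or background cells fall on invalid feature cells")
  f_pres_mean <- colMeans(F_pres)
  s <- pmax(apply(F_pres, 2L, stats::sd), 1e-4)
  beta <- reg_multiplier * s / sqrt(m)
  p <- ncol(F_bg)
  # monotone accelerated proximal gradient (FISTA with a monotonicity
  # safeguard): the extrapolated point speeds convergence, but the
  # iterate is only accepted if it improves the penalised objective, so
  # the recorded trace is non-decreasing by construction
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  smooth_at <- function(lam) sum(lam * f_pres_mean) -
    log_sum_exp(drop(F_bg %*% lam))
  lambda <- numeric(p)
  y <- lambda
  tk <- 1
  obj <- maxent_objective(lambda, f_pres_mean, F_bg, beta)
  trace <- obj
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta_y <- drop(F_bg %*% y)
    logZ_y <- log_sum_exp(eta_y)
    q_y <- exp(eta_y - logZ_y)
    grad <- f_pres_mean - drop(crossprod(F_bg, q_y))
    smooth_y <- sum(y * f_pres_mean) - logZ_y
    repeat {
      z <- soft(y + step * grad, step * beta)
      delta <- z - y
      if (smooth_at(z) >= smooth_y + sum(grad * delta) -
          sum(delta^2) / (2 * step) - 1e-12 || step < 1e-12) break
      step <- step / 2
    }
    obj_z <- maxent_objective(z, f_pres_mean, F_bg, beta)
    if (obj_z < obj) {
      # extrapolation overshot: keep the iterate, restart momentum
      y <- lambda
      tk <- 1
      trace <- c(trace, obj)
      next
    }
    lambda_prev <- lambda
    lambda <- z
    tk_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- lambda + (tk / tk_next) * (z - lambda) +
      ((tk - 1) / tk_next) * (lambda - lambda_prev)
    tk <- tk_next
    trace <- c(trace, obj_z)
    if (obj_z - obj < tol) {
      obj <- obj_z
      converged <- TRUE
      break
    }
    obj <- obj_z
    step <- min(step * 2, 1e6)
  }
  if (!converged)
    warning("maxent fit did not converge in ", max_iter,
            " iterations; returning best iterate")
  eta <- drop(F_bg %*% lambda)
  logZ <- log_sum_exp(eta)
  q <- exp(eta - logZ)
  H <- -sum(q * log(pmax(q, 1e-300)))
  structure(list(lambda = stats::setNames(lambda, features$names),
                 beta = beta, logZ = logZ, entropy = H, m = m,
                 presence_cells = presence_cells,
                 background_cells = background_cells,
                 feature_names = features$names,
                 reg_multiplier = reg_multiplier,
                 objective = trace, converged = converged),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> m = %d presences, |B| = %d, ",
                     "H = %.3f, %sconverged in %d iterations\n"),
              x$m, length(x$background_cells), x$entropy,
              if (x$converged) "" else "NOT ", length(x$objective) - 1))
  invisible(x)
}

#' Logistic suitability map of a fitted model
#'
#' Evaluates the raw Gibbs density `q(x) = exp(lambda.f(x)) / Z` at every
#' valid cell and applies the logistic transform
#' `l(x) = e^H q(x) / (1 + e^H q(x))` (prevalence 0.5), a strictly
#' monotone transform of `q`, so cell rankings are preserved. A cell with
#' `q(x) = e^(-H)` (a "typical" cell) maps to 0.5.
#'
#' @param model A `maxent_model`.
#' @param features The `feature_matrix` used for fitting.
#' @return A `raster_layer` of suitabilities in `(0, 1)`.
#' @export
logistic_map <- function(model, features) {
  g <- features$grid
  vals <- rep(NA_real_, n_cells(g))
  ok <- !is.na(features$values[, 1])
  eta <- drop(features$values[ok, , drop = FALSE] %*% model$lambda)
  vals[ok] <- stats::plogis(model$entropy + eta - model$logZ)
  raster_layer(g, vals, ok)
}

#' Rank-based training AUC
#'
#' Probability that a randomly chosen presence cell outranks a randomly
#' chosen background cell in suitability, with ties counted one half
#' (midranks) — the two-sample rank statistic. Invariant under strictly
#' monotone transforms of the suitability, so raw and logistic outputs
#' give identical AUCs.
#'
#' @param pres Suitability values at presence cells.
#' @param bg Suitability values at background cells.
#' @return AUC in `[0, 1]`.
#' @export
training_auc <- function(pres, bg) {
  stopifnot(length(pres) > 0, length(bg) > 0)
  r <- rank(c(pres, bg))
  m <- length(pres)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(bg))
}

#' Ten-percent training-presence threshold
#'
#' The largest suitability value `t` such that at least 90% of training
#' presences score `>= t`; binarising at `l >= t` therefore drops (at
#' most) the lowest 10% of training presences.
#'
#' @param pres Suitability values at training presence cells (>= 1).
#' @return Threshold value.
#' @export
threshold_10pct <- function(pres) {
  n <- length(pres)
  stopifnot(n >= 1)
  v <- sort(pres)
  v[n - ceiling(0.9 * n) + 1]
}
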