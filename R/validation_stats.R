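#' Bias-corrected null-model significance test
#'
#' Tests whether a fitted presence-only model discriminates better than
#' chance given the survey effort. 99 null models are fitted to `n` cells
#' drawn without replacement from the surveyed (bias-positive) cells,
#' where `n` is the number of geographically unique presences, using the
#' identical background and configuration; the observed training AUC is
#' ranked among the 100 AUCs (ascending, ties assigned the lowest
#' position, which is conservative) and the model is significant iff its
#' rank is 95 or above — an upper one-sided test at the 5% level.
#' Sampling nulls from the bias cells rather than the whole grid makes
#' the test robust to survey-effort artefacts; set `from_bias = FALSE`
#' for whole-grid nulls.
#'
#' @param presence_cells Unique presence cell ids of the observed model.
#' @param features A `feature_matrix`.
#' @param background_cells Background cell ids (shared by observed and
#'   null fits).
#' @param bias Binary bias `raster_layer`.
#' @param seed Integer seed for the null draws.
#' @param n_null Number of null models (default 99).
#' @param reg_multiplier,tol,max_iter Passed to [fit_maxent()].
#' @param from_bias Draw null presences from bias-positive cells
#'   (default) or from all cells with valid features.
#' @param observed_model Optional pre-fitted `maxent_model` to avoid
#'   refitting.
#' @return List of class `null_model_result`: `observed_auc`,
#'   `null_aucs`, `rank`, `significant`, `n`.
#' @export
null_model_test <- function(presence_cells, features, background_cells,
                            bias, seed = 1, n_null = 99,
                            reg_multiplier = 1.0, tol = 1e-7,
                            max_iter = 500, from_bias = TRUE,
                            observed_model = NULL) {
  presence_cells <- sort(unique(presence_cells))
  n <- length(presence_cells)
  valid <- which(!is.na(features$values[, 1]))
  pool <- if (from_bias)
    intersect(which(!is.na(bias$values) & bias$values == 1), valid)
  else valid
  if (n > length(pool))
    stop("more unique presences than available null cells")
  model_auc <- function(cells, model = NULL) {
    if (is.null(model))
      model <- fit_maxent(cells, background_cells, features,
                          reg_multiplier, tol, max_iter)
    eta_p <- drop(features$values[model$presence_cells, , drop = FALSE] %*%
                    model$lambda)
    eta_b <- drop(features$values[background_cells, , drop = FALSE] %*%
                    model$lambda)
    training_auc(eta_p, eta_b)
  }
  observed_auc <- model_auc(presence_cells, observed_model)
  set.seed(seed)
  draws <- lapply(seq_len(n_null), function(r)
    sample(pool, n, replace = FALSE))
  null_aucs <- vapply(draws, function(cells)
    suppressWarnings(model_auc(cells)), numeric(1))
  rank <- 1L + sum(null_aucs < observed_auc)
  cutoff <- ceiling(0.95 * (n_null + 1L))  # rank 95 of 100 at the default
  structure(list(observed_auc = observed_auc, null_aucs = null_aucs,
                 rank = rank, significant = rank >= cutoff,
                 n = n),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("<null_model_result> AUC %.3f, rank %d/%d, %ssignificant\n",
              x$observed_auc, x$rank, length(x$null_aucs) + 1L,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Binomial GLM of collection probability vs interpolated abundance
#'
#' Logit regression of the indicator "cell holds at least one cleaned
#' collection" on the interpolated relative abundance, over all valid
#' forested study cells. A significant positive slope means the chance of
#' being collected rises with local abundance — the premise under which
#' collections can be treated as a draw from the species' abundance
#' distribution.
#'
#' @param collection_cells Cell ids with at least one cleaned collection.
#' @param surface An `abundance_surface`.
#' @param study_cells Cell ids over which the model is fitted (valid
#'   forested cells).
#' @return List: `slope`, `p`, `significant_positive`, `flag`
#'   (`"ok"`, `"degenerate_predictor"` or `"separation"`), `n`.
#' @export
glm_collection_vs_abundance <- function(collection_cells, surface,
                                        study_cells) {
  y <- as.integer(study_cells %in% collection_cells)
  x <- surface$ra$values[study_cells]
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one collected and one uncollected cell")
  if (stats::sd(x) == 0)
    return(list(slope = NA_real_, p = NA_real_,
                significant_positive = FALSE,
                flag = "degenerate_predictor", n = length(y)))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]
  p <- co["x", "Pr(>|z|)"]
  list(slope = slope, p = p,
       significant_positive = isTRUE(slope > 0 && p < 0.05),
       flag = if (sep) "separation" else "ok", n = length(y))
}

#' Spearman correlation between suitability and plot abundance
#'
#' Midrank-based Spearman rho between model suitability at plot
#' localities and the plots' observed relative abundance, with the
#' large-sample p-value. Every plot is one observation, even when several
#' plots share a grid cell.
#'
#' @param suit Suitability values at plot localities.
#' @param ra Plot relative abundances (same length, >= 3).
#' @return List: `rho`, `p`, `flag` (`"ok"` or `"degenerate"`), `n`.
#' @export
spearman_suit_vs_abundance <- function(suit, ra) {
  stopifnot(length(suit) == length(ra), length(suit) >= 3)
  if (stats::sd(suit) == 0 || stats::sd(ra) == 0)
    return(list(rho = NA_real_, p = NA_real_, flag = "degenerate",
                n = length(suit)))
  ct <- suppressWarnings(stats::cor.test(suit, ra, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, flag = "ok",
       n = length(suit))
}

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# iteratively reweighted least squares on the smoothed check loss
rq_irls <- function(x, y, tau, max_iter = 100, eps = 1e-8) {
  X <- cbind(1, x)
  ab <- stats::lm.fit(X, y)$coefficients
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% ab)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    ab_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(ab_new - ab)) < 1e-12) { ab <- ab_new; break }
    ab <- ab_new
  }
  unname(ab)
}

# exact vertex polish: the check loss is piecewise linear, so an optimum
# lies on a line through two sample points; search pairs among the
# lowest-|residual| points around the working solution
rq_vertex_polish <- function(x, y, tau, ab, n_cand = 40) {
  r <- y - ab[1] - ab[2] * x
  cand <- order(abs(r))[seq_len(min(n_cand, length(x)))]
  pr <- utils::combn(cand, 2)
  dx <- x[pr[1, ]] - x[pr[2, ]]
  ok <- abs(dx) > 1e-12
  if (!any(ok)) return(ab)
  b <- (y[pr[1, ok]] - y[pr[2, ok]]) / dx[ok]
  a <- y[pr[1, ok]] - b * x[pr[1, ok]]
  A <- c(ab[1], a); B <- c(ab[2], b)
  R <- matrix(y, nrow = length(A), ncol = length(y), byrow = TRUE) -
    A - outer(B, x)
  loss <- rowSums(R * (tau - (R < 0)))
  k <- which.min(loss)
  c(A[k], B[k])
}

rq_fit <- function(x, y, tau, polish = TRUE, n_cand = 40) {
  ab <- rq_irls(x, y, tau)
  if (polish) ab <- rq_vertex_polish(x, y, tau, ab, n_cand)
  ab
}

#' Linear 90th-percentile quantile regression
#'
#' Fits `(intercept, slope)` minimising the check (pinball) loss
#' `sum rho_tau(y - a - b x)` with `rho_tau(r) = r (tau - 1[r < 0])` and
#' `tau = 0.9`: the fitted line tracks the conditional 90th percentile of
#' `y` given `x`, i.e. whether high suitability bounds the top of the
#' local-abundance distribution. The optimiser is IRLS on the smoothed
#' loss followed by an exact polish over candidate lines through sample
#' point pairs (an optimum of the piecewise-linear loss lies on such a
#' line). The slope's confidence interval and p-value come from a
#' nonparametric pairs bootstrap (percentile interval; p = doubled
#' fraction of bootstrap slopes on the minority side of zero).
#'
#' @param x Suitability at plot localities (>= 10 values, non-degenerate).
#' @param y Plot relative abundances.
#' @param tau Quantile level (default 0.9).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `quantreg_fit`: `intercept`, `slope`, `loss`,
#'   `ci` (2.5/97.5 percentile), `p`, `tau`, `n`, `boot_slopes`.
#' @export
quantile_reg_90 <- function(x, y, tau = 0.9, n_boot = 200, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (stats::sd(x) == 0) stop("degenerate predictor: x is constant")
  ab <- rq_fit(x, y, tau)
  loss <- check_loss(y - ab[1] - ab[2] * x, tau)
  set.seed(seed)
  n <- length(x)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0) return(NA_real_)
    rq_fit(x[idx], y[idx], tau, n_cand = 20)[2]
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  structure(list(intercept = ab[1], slope = ab[2], loss = loss,
                 ci = ci, p = p, tau = tau, n = n, boot_slopes = boot),
            class = "quantreg_fit")
}

#' @export
print.quantreg_fit <- function(x, ...) {
  cat(sprintf("<quantreg_fit> tau = %.2f: slope %.4g [%.4g, %.4g], p = %.3g\n",
              x$tau, x$slope, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Environmental collinearity screen
#'
#' Pairwise Spearman correlations between environmental layers over valid
#' cells, with greedy elimination until all retained pairs satisfy
#' `|rho| < threshold`: at each step the variable with the most
#' over-threshold partners is dropped (ties broken by the larger mean
#' absolute correlation). The PCA loadings of all variables are reported
#' to support the (manual, out-of-scope) biological-relevance choice
#' among the retained set.
#'
#' @param env An `env_stack` (>= 2 layers).
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return List of class `collinearity_screen`: `rho` (matrix),
#'   `retained`, `dropped`, `loadings`, `threshold`.
#' @export
collinearity_screen <- function(env, threshold = 0.7) {
  stopifnot(length(env) >= 2)
  M <- vapply(env, function(l) l$values, numeric(n_cells(env[[1]]$grid)))
  M <- M[stats::complete.cases(M), , drop = FALSE]
  rho <- stats::cor(M, method = "spearman")
  retained <- colnames(rho)
  dropped <- character()
  repeat {
    A <- abs(rho[retained, retained, drop = FALSE])
    diag(A) <- 0
    counts <- rowSums(A > threshold)
    if (max(counts) == 0) break
    worst <- names(counts)[counts == max(counts)]
    if (length(worst) > 1) {
      mean_abs <- rowMeans(A[worst, , drop = FALSE])
      worst <- worst[which.max(mean_abs)]
    }
    dropped <- c(dropped, worst[1])
    retained <- setdiff(retained, worst[1])
  }
  loadings <- stats::prcomp(M, scale. = TRUE)$rotation
  structure(list(rho = rho, retained = retained, dropped = dropped,
                 loadings = loadings, threshold = threshold),
            class = "collinearity_screen")
}
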