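#' Baseline configuration for static and dynamic inference
#'
#' @param cv_folds Cross-validation folds (default 5).
#' @param n_penalties Length of the automatic penalty grid (default 50).
#' @param penalty_grid Optional explicit descending penalty grid.
#' @param n_repetitions Repetitions for edge confidence (default 1; the
#'   repetitions differ only in the CV fold assignment).
#' @param derivative_scheme Finite-difference scheme for the dynamic
#'   baseline: `"central"` (default; forward/backward at stage edges, never
#'   across a boundary).
#' @param seed Integer seed.
#' @return Object of class `baseline_config`.
#' @export
baseline_config <- function(cv_folds = 5L, n_penalties = 50L,
                            penalty_grid = NULL, n_repetitions = 1L,
                            derivative_scheme = "central", seed = 1L) {
  stopifnot(cv_folds >= 2, n_repetitions >= 1,
            derivative_scheme == "central")
  structure(list(cv_folds = as.integer(cv_folds),
                 n_penalties = as.integer(n_penalties),
                 penalty_grid = penalty_grid,
                 n_repetitions = as.integer(n_repetitions),
                 derivative_scheme = derivative_scheme,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

# lasso with CV over plain sample rows (no grouping); returns coefficient
# vector over the columns of Z
lasso_cv_fit <- function(Z, y, cfg, seed, min_ratio = 1e-4) {
  if (stats::sd(y) == 0 || all(apply(Z, 2L, stats::sd) == 0)) {
    warning("degenerate regression (no variance); empty model")
    return(stats::setNames(rep(0, ncol(Z)), colnames(Z)))
  }
  penalties <- cfg$penalty_grid %||% {
    n <- length(y)
    lam_max <- max(abs(crossprod(Z, y)) / n)
    if (lam_max <= 0) lam_max <- 1e-3
    exp(seq(log(lam_max), log(lam_max * min_ratio),
            length.out = cfg$n_penalties))
  }
  folds <- min(cfg$cv_folds, nrow(Z))
  local_seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(Z)))
  one_col <- ncol(Z) == 1L
  Zf <- if (one_col) cbind(Z, `..pad` = 0) else Z
  cv <- glmnet::cv.glmnet(Zf, y, lambda = penalties, foldid = foldid,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-9, maxit = 1e6)
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda.min))[-1L]
  if (one_col) co <- co[1L]
  stats::setNames(co, colnames(Z))
}

#' Static (steady-state) network inference
#'
#' The comparator that ignores all dynamics: genes are assumed to be at
#' steady state within each stage, so the kinetic ODE reduces to
#' 0 = -deg_i x_i + sum_j beta_ij x_j. Dividing by the (positive)
#' degradation rate makes x_i the response of a sign-preserving linear model
#' x_i = sum_{j != i} c_ij x_j, fitted per stage across that stage's samples
#' by L1 regression with cross-validated sparsity.
#'
#' @param data A [staged_expression()].
#' @param cfg A [baseline_config()].
#' @return A [stage_networks()]; coefficients are the c_ij (proportional to
#'   beta_ij / deg_i), confidence is the edge occurrence frequency across
#'   `cfg$n_repetitions` refits.
#' @export
static_infer <- function(data, cfg = baseline_config()) {
  stopifnot(inherits(data, "staged_expression"))
  n_s <- vapply(data$matrices, ncol, 0L)
  if (any(n_s < 3L)) stop("static inference needs >= 3 samples per stage")
  p <- data$n_genes; S <- data$n_stages
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_repetitions)
  coef_sum <- lapply(seq_len(S), function(s) matrix(0, p, p))
  occ <- lapply(seq_len(S), function(s) matrix(0, p, p))
  for (r in seq_len(cfg$n_repetitions)) {
    fit_seeds <- derive_seeds(rep_seeds[r], p * S)
    for (s in seq_len(S)) {
      X <- t(data$matrices[[s]])  # samples x genes
      # canonical sample order so results don't depend on column order
      X <- X[order(rowSums(X)), , drop = FALSE]
      for (i in seq_len(p)) {
        co <- lasso_cv_fit(X[, -i, drop = FALSE], X[, i], cfg,
                           seed = fit_seeds[(s - 1L) * p + i])
        coef_sum[[s]][i, -i] <- coef_sum[[s]][i, -i] + co
        occ[[s]][i, -i] <- occ[[s]][i, -i] + (co != 0)
      }
    }
  }
  coefs <- lapply(coef_sum, `/`, cfg$n_repetitions)
  conf <- lapply(occ, `/`, cfg$n_repetitions)
  support <- lapply(conf, function(m) (m > 0.5) * 1)
  stage_networks(coefs, conf, support, data$gene_ids, data$stage_labels,
                 meta = list(method = "static", seed = cfg$seed))
}

# per-stage finite-difference derivatives; never differencing across a
# stage boundary; second-order one-sided formulas at the stage edges so the
# edge rows do not degrade the fit
stage_derivatives <- function(times, values) {
  n <- length(times)
  if (n < 3L) stop("dynamic inference needs >= 3 timepoints per stage")
  D <- matrix(0, nrow(values), n)
  for (k in 2:(n - 1L)) {
    D[, k] <- (values[, k + 1L] - values[, k - 1L]) /
      (times[k + 1L] - times[k - 1L])
  }
  D[, 1L] <- (-3 * values[, 1L] + 4 * values[, 2L] - values[, 3L]) /
    (2 * (times[2L] - times[1L]))
  D[, n] <- (3 * values[, n] - 4 * values[, n - 1L] + values[, n - 2L]) /
    (2 * (times[n] - times[n - 1L]))
  D
}

#' Dynamic (time-course) network inference
#'
#' The comparator with full temporal information: per stage, estimates each
#' gene's time derivative by finite differences along the stage's ordered
#' timepoints, then L1-regresses the derivative on the expression levels of
#' all genes (self term included; its coefficient estimates minus the
#' degradation rate) with cross-validated sparsity.
#'
#' @param tc A `time_course`.
#' @param cfg A [baseline_config()].
#' @return A [stage_networks()]; off-diagonal coefficients estimate the
#'   regulatory strengths beta_ij, the diagonal stores the (negated)
#'   degradation estimates.
#' @export
dynamic_infer <- function(tc, cfg = baseline_config()) {
  stopifnot(inherits(tc, "time_course"))
  p <- nrow(tc$values); S <- length(tc$stage_labels)
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_repetitions)
  coef_sum <- lapply(seq_len(S), function(s) matrix(0, p, p))
  diag_sum <- lapply(seq_len(S), function(s) numeric(p))
  occ <- lapply(seq_len(S), function(s) matrix(0, p, p))
  for (r in seq_len(cfg$n_repetitions)) {
    fit_seeds <- derive_seeds(rep_seeds[r], p * S)
    for (s in seq_len(S)) {
      cols <- which(tc$stage_of_timepoint == s)
      if (length(cols) < 3L)
        stop("stage ", tc$stage_labels[s], " has fewer than 3 timepoints")
      V <- tc$values[, cols, drop = FALSE]
      D <- stage_derivatives(tc$times[cols], V)
      X <- t(V)  # timepoints x genes
      for (i in seq_len(p)) {
        # noiseless derivatives want a nearly unpenalised fit: deep grid
        co <- lasso_cv_fit(X, D[i, ], cfg,
                           seed = fit_seeds[(s - 1L) * p + i],
                           min_ratio = 1e-7)
        coef_sum[[s]][i, -i] <- coef_sum[[s]][i, -i] + co[-i]
        diag_sum[[s]][i] <- diag_sum[[s]][i] + co[i]
        occ[[s]][i, -i] <- occ[[s]][i, -i] + (co[-i] != 0)
      }
    }
  }
  coefs <- lapply(seq_len(S), function(s) {
    m <- coef_sum[[s]] / cfg$n_repetitions
    diag(m) <- 0
    m
  })
  conf <- lapply(occ, `/`, cfg$n_repetitions)
  support <- lapply(conf, function(m) (m > 0.5) * 1)
  out <- stage_networks(coefs, conf, support, tc$gene_ids, tc$stage_labels,
                        meta = list(method = "dynamic", seed = cfg$seed))
  out$degradation_estimates <- lapply(seq_len(S), function(s)
    stats::setNames(diag_sum[[s]] / cfg$n_repetitions, tc$gene_ids))
  out
}
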