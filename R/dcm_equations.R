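#' Fraction-factor configuration
#'
#' The cascade equations are instantiated at several positions ("fraction
#' factors") along a stage: interpolating fractions in [0, 1] (0 = stage
#' start, 0.5 = middle, 1 = stage end) plus a head-end extrapolation at
#' -head_extrapolation and a tail-end extrapolation at
#' 1 + tail_extrapolation, which control the linearity of the model at the
#' far ends of a stage.
#'
#' @param interpolation_fractions Sorted reals in [0, 1] (default 0, 0.5, 1).
#' @param head_extrapolation Positive real Lambda_h (default 4).
#' @param tail_extrapolation Positive real Lambda_t (default 4).
#' @return Object of class `fraction_config`; `$settings` holds the full
#'   vector of fraction settings actually used.
#' @export
fraction_config <- function(interpolation_fractions = c(0, 0.5, 1),
                            head_extrapolation = 4,
                            tail_extrapolation = 4) {
  f <- sort(interpolation_fractions)
  stopifnot(length(f) >= 1L, all(f >= 0), all(f <= 1),
            head_extrapolation > 0, tail_extrapolation > 0)
  structure(list(interpolation_fractions = f,
                 head_extrapolation = head_extrapolation,
                 tail_extrapolation = tail_extrapolation,
                 settings = c(-head_extrapolation, f,
                              1 + tail_extrapolation)),
            class = "fraction_config")
}

#' DCM configuration
#'
#' @param rho Inter-stage influence coefficient, a constant in (-1, 1)
#'   multiplying the previous stage's value in the cascade equation
#'   (default 0.6). It is a monotone function of degradation rate and stage
#'   duration and is treated as a shared hyperparameter, not estimated.
#' @param n_bootstrap_groups Bootstrap groups per model fit (default 200).
#' @param group_size Samples drawn (without replacement) per gene per stage
#'   per group (default 16; must not exceed any stage's sample count).
#' @param cv_folds Cross-validation folds, stratified by bootstrap group
#'   (default 5).
#' @param n_penalties Length of the automatic log-spaced penalty grid
#'   (default 50).
#' @param penalty_grid Optional explicit descending penalty grid; overrides
#'   `n_penalties`.
#' @param n_repetitions Independent modelling repetitions used for edge
#'   confidence (default 100).
#' @param top_k_edges `"cv"` (default) binarises each repetition's network as
#'   the cross-validation-selected support; an integer keeps the k strongest
#'   edges per stage instead.
#' @param equation_set `"ladder"` (default) builds the cascade equations
#'   between successive quantile check-points of each bootstrap subsample
#'   (see [build_ladder_equations()]); `"fraction"` builds the same-fraction
#'   cross-stage equations (see [build_equations()]).
#' @param discretization For the `"fraction"` equation set: `"forward"`
#'   (default) takes cascade predictors from the earlier stage of each pair;
#'   `"trapezoid"` averages the two stages' quantiles.
#' @param standardize Standardise predictors inside the cross-validated
#'   lasso (coefficients are returned on the original scale). Default TRUE;
#'   regulatory strengths are comparable across genes while expression
#'   scales are not.
#' @param penalty_rule Penalty selection from the CV curve: `"min"`
#'   (default; the CV-minimising penalty, best edge ranking on the
#'   benchmark) or `"1se"` (the sparsest model within one standard error of
#'   the minimum; markedly sparser supports, near-empty under pure noise).
#' @param seed Integer seed for all randomness in the fit.
#' @return Object of class `dcm_config`.
#' @export
dcm_config <- function(rho = 0.6, n_bootstrap_groups = 200L, group_size = 16L,
                       cv_folds = 5L, n_penalties = 50L, penalty_grid = NULL,
                       n_repetitions = 100L, top_k_edges = "cv",
                       equation_set = c("ladder", "fraction"),
                       discretization = c("forward", "trapezoid"),
                       standardize = TRUE, penalty_rule = c("min", "1se"),
                       seed = 1L) {
  stopifnot(rho > -1, rho < 1, n_bootstrap_groups >= 1, group_size >= 2,
            cv_folds >= 2, n_repetitions >= 1)
  if (!identical(top_k_edges, "cv"))
    stopifnot(is.numeric(top_k_edges), top_k_edges >= 1)
  structure(list(rho = rho,
                 n_bootstrap_groups = as.integer(n_bootstrap_groups),
                 group_size = as.integer(group_size),
                 cv_folds = as.integer(cv_folds),
                 n_penalties = as.integer(n_penalties),
                 penalty_grid = penalty_grid,
                 n_repetitions = as.integer(n_repetitions),
                 top_k_edges = top_k_edges,
                 equation_set = match.arg(equation_set),
                 discretization = match.arg(discretization),
                 standardize = isTRUE(standardize),
                 penalty_rule = match.arg(penalty_rule),
                 seed = as.integer(seed)),
            class = "dcm_config")
}

#' Direction-aware empirical stage quantile with linear extension
#'
#' Estimates a gene's expression at the lambda-fraction position of a stage
#' from that stage's unordered samples. Under the steady-rate assumption the
#' samples are draws from a linear trend, so the value at fraction f is the
#' empirical quantile at f if the gene ascends through the stage, and at
#' 1 - f if it descends. Quantiles use plotting positions (k-1)/(n-1) with
#' linear interpolation between order statistics. Fractions outside [0, 1]
#' (extrapolations) extend the chord through the direction-adjusted 0- and
#' 1-quantiles: value(f) = Q(0) + f * (Q(1) - Q(0)).
#'
#' @param samples Numeric vector with at least 2 values.
#' @param fraction Numeric vector of fraction settings (may lie outside
#'   [0, 1]).
#' @param direction `"ascending"` or `"descending"`.
#' @return Numeric vector of estimated expression values, one per fraction.
#' @export
stage_quantile <- function(samples, fraction, direction = "ascending") {
  n <- length(samples)
  if (n < 2L) stop("stage_quantile needs at least 2 samples")
  stopifnot(direction %in% c("ascending", "descending"))
  sx <- sort(samples)
  q_adj <- function(f) {
    # direction-adjusted quantile for f in [0, 1]
    pf <- if (direction == "ascending") f else 1 - f
    h <- (n - 1) * pf + 1
    fl <- floor(h)
    sx[fl] + (h - fl) * (sx[pmin(fl + 1, n)] - sx[fl])
  }
  out <- numeric(length(fraction))
  inside <- fraction >= 0 & fraction <= 1
  if (any(inside)) out[inside] <- q_adj(fraction[inside])
  if (any(!inside)) {
    q0 <- q_adj(0); q1 <- q_adj(1)
    out[!inside] <- q0 + fraction[!inside] * (q1 - q0)
  }
  out
}

#' Build the cascaded model equations from staged samples
#'
#' For every bootstrap group, every fraction setting and every pair of
#' consecutive stages, emits one linear model equation per gene linking the
#' gene's expression at the same fraction of the two stages:
#' y = q_i^{s+1}(f) - rho * q_i^{s}(f) with predictors z_j = q_j^{s}(f)
#' (j != i), where q is the direction-aware stage quantile computed on that
#' group's subsample. The equation family is attributed to the earlier
#' stage; the final stage additionally owns a backward family
#' (y = q_i^{S}(f) - rho * q_i^{S-1}(f), predictors from stage S), so every
#' stage has its own equations.
#'
#' @param data A [staged_expression()].
#' @param trends A `trend_assignment` for the same data.
#' @param fc A [fraction_config()].
#' @param cfg A [dcm_config()].
#' @param seed Integer seed for the bootstrap subsampling (defaults to
#'   `cfg$seed`).
#' @return Object of class `dcm_equations` holding, per (gene, stage) family,
#'   the response vector, predictor matrix, and bootstrap group ids.
#' @export
build_equations <- function(data, trends, fc = fraction_config(),
                            cfg = dcm_config(), seed = cfg$seed) {
  stopifnot(inherits(data, "staged_expression"),
            inherits(trends, "trend_assignment"),
            inherits(fc, "fraction_config"), inherits(cfg, "dcm_config"))
  S <- data$n_stages
  if (S < 2L) stop("DCM requires >= 2 stages")
  p <- data$n_genes
  if (!identical(dim(trends$direction), c(p, S)) &&
      !all(dim(trends$direction) == c(p, S)))
    stop("trend assignment does not match the data's genes/stages")
  n_s <- vapply(data$matrices, ncol, 0L)
  if (any(cfg$group_size > n_s))
    stop("group_size exceeds the sample count of stage ",
         data$stage_labels[which(cfg$group_size > n_s)[1L]])
  fracs <- fc$settings
  nf <- length(fracs)
  G <- cfg$n_bootstrap_groups
  local_seed(seed)
  # Q[gene, fraction, stage, group]: subsampled direction-aware quantiles
  Q <- array(NA_real_, c(p, nf, S, G))
  for (g in seq_len(G)) {
    for (s in seq_len(S)) {
      m <- data$matrices[[s]]
      for (i in seq_len(p)) {
        sub <- sample.int(n_s[s], cfg$group_size)
        Q[i, , s, g] <- stage_quantile(m[i, sub], fracs,
                                       trends$direction[i, s])
      }
    }
  }
  rho <- cfg$rho
  families <- vector("list", p * S)
  dim(families) <- c(p, S)
  for (s in seq_len(S)) {
    # forward family for stages 1..S-1; backward family for the last stage
    s_resp <- if (s < S) c(s, s + 1L) else c(s - 1L, s)
    s_pred <- s
    for (i in seq_len(p)) {
      y <- as.vector(Q[i, , s_resp[2L], ] - rho * Q[i, , s_resp[1L], ])
      zs <- Q[, , s_pred, , drop = FALSE]
      if (cfg$discretization == "trapezoid" && s < S)
        zs <- (zs + Q[, , s + 1L, , drop = FALSE]) / 2
      Z <- t(matrix(zs[-i, , 1L, ], nrow = p - 1L))
      colnames(Z) <- data$gene_ids[-i]
      families[[i, s]] <- list(
        y = y, Z = Z,
        group = rep(seq_len(G), each = nf),
        fraction = rep(fracs, times = G))
    }
  }
  structure(list(families = families, gene_ids = data$gene_ids,
                 stage_labels = data$stage_labels, n_groups = G,
                 fraction_settings = fracs, rho = rho),
            class = "dcm_equations")
}

#' Build the cascaded ladder equations from staged samples
#'
#' The package's default equation system. Within each bootstrap group the
#' direction-adjusted sorted subsample of a stage is its empirical quantile
#' ladder: value q(l_k) at fraction check-point l_k = (k-1)/(m-1) for a
#' subsample of size m (exactly [stage_quantile()] evaluated on a dense
#' fraction grid). The intra-stage steady-rate assumption is imposed between
#' successive check-points through the cascade relation
#' y = q_i^s(l_{k+1}) - rho^{1/(m-1)} * q_i^s(l_k),
#' with predictors z_j = q_j^s(l_k) (j != i): the inter-stage influence
#' coefficient rho compounds across a stage's m-1 steps to the full
#' stage-to-stage influence that links consecutive stages under the
#' continuity assumption. Each stage owns its own equation family.
#'
#' @inheritParams build_equations
#' @return A `dcm_equations` object (`fraction` metadata holds the ladder
#'   check-point of each row).
#' @export
build_ladder_equations <- function(data, trends, fc = fraction_config(),
                                   cfg = dcm_config(), seed = cfg$seed) {
  stopifnot(inherits(data, "staged_expression"),
            inherits(trends, "trend_assignment"), inherits(cfg, "dcm_config"))
  S <- data$n_stages
  if (S < 2L) stop("DCM requires >= 2 stages")
  p <- data$n_genes
  n_s <- vapply(data$matrices, ncol, 0L)
  m <- cfg$group_size
  if (any(m > n_s))
    stop("group_size exceeds the sample count of stage ",
         data$stage_labels[which(m > n_s)[1L]])
  G <- cfg$n_bootstrap_groups
  rho_step <- sign(cfg$rho) * abs(cfg$rho)^(1 / (m - 1))
  local_seed(seed)
  # L[gene, check-point, stage, group]: sorted direction-adjusted subsample
  L <- array(NA_real_, c(p, m, S, G))
  for (g in seq_len(G)) {
    for (s in seq_len(S)) {
      mat <- data$matrices[[s]]
      desc <- trends$direction[, s] == "descending"
      for (i in seq_len(p)) {
        v <- sort.int(mat[i, sample.int(n_s[s], m)])
        L[i, , s, g] <- if (desc[i]) rev(v) else v
      }
    }
  }
  lam <- (seq_len(m) - 1) / (m - 1)
  families <- vector("list", p * S)
  dim(families) <- c(p, S)
  for (s in seq_len(S)) {
    for (i in seq_len(p)) {
      y <- as.vector(L[i, -1L, s, ] - rho_step * L[i, -m, s, ])
      Z <- t(matrix(L[-i, -m, s, ], nrow = p - 1L))
      colnames(Z) <- data$gene_ids[-i]
      families[[i, s]] <- list(
        y = y, Z = Z,
        group = rep(seq_len(G), each = m - 1L),
        fraction = rep(lam[-m], times = G))
    }
  }
  structure(list(families = families, gene_ids = data$gene_ids,
                 stage_labels = data$stage_labels, n_groups = G,
                 fraction_settings = lam, rho = cfg$rho),
            class = "dcm_equations")
}

#' @export
print.dcm_equations <- function(x, ...) {
  cat("dcm_equations:", length(x$gene_ids), "genes x",
      length(x$stage_labels), "stage families;",
      n_equations(x, 1L, 1L), "equations per family\n")
  invisible(x)
}

#' Count model equations
#'
#' Number of equation rows in one (gene, stage) family — bootstrap groups
#' times fraction settings — or, with `gene`/`stage` omitted, the count for
#' all genes of one stage family or the grand total.
#'
#' @param eqs A `dcm_equations` object.
#' @param gene,stage Optional indices restricting the count.
#' @return Integer row count.
#' @export
n_equations <- function(eqs, gene = NULL, stage = NULL) {
  genes <- gene %||% seq_along(eqs$gene_ids)
  stages <- stage %||% seq_along(eqs$stage_labels)
  sum(vapply(stages, function(s) {
    sum(vapply(genes, function(i) length(eqs$families[[i, s]]$y), 0L))
  }, 0L))
}
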