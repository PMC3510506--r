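# L1 fitting layer. The objective for one (gene, stage) equation family is
#   min_b  sum_rows (y - Z b)^2 / (2 n)  +  penalty * sum_j |b_j|
# with no intercept and no predictor standardisation (the cascade equations
# are homogeneous: all quantities live on the expression scale).

default_penalty_grid <- function(Z, y, n_penalties) {
  n <- length(y)
  lam_max <- max(abs(crossprod(Z, y)) / n)
  if (lam_max <= 0) lam_max <- 1e-3
  exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_penalties))
}

#' L1-penalised coefficient path for one equation family
#'
#' Fits the lasso over a descending penalty grid for the model equations of
#' one (gene, stage) family; objective RSS/(2n) + penalty * L1, intercept-free
#' and unstandardised.
#'
#' @param eqs A `dcm_equations` object (or any list with `y`, `Z` when
#'   `gene`/`stage` are omitted).
#' @param gene,stage Family indices.
#' @param penalties Descending positive penalty grid; `NULL` (default) builds
#'   a 50-point log-spaced grid from the data.
#' @return List with `penalties` and `coefficients` (predictors x penalties
#'   matrix).
#' @export
fit_sparse_path <- function(eqs, gene, stage, penalties = NULL) {
  fam <- eqs$families[[gene, stage]]
  y <- fam$y; Z <- fam$Z
  if (length(y) < 2L) stop("need at least 2 equations to fit a family")
  if (all(Z == 0)) {
    warning("degenerate design (all-zero predictors); returning zero path")
    if (is.null(penalties)) penalties <- default_penalty_grid(Z, y, 50L)
    beta <- matrix(0, ncol(Z), length(penalties),
                   dimnames = list(colnames(Z), NULL))
    return(list(penalties = penalties, coefficients = beta))
  }
  if (is.null(penalties)) penalties <- default_penalty_grid(Z, y, 50L)
  one_col <- ncol(Z) == 1L  # glmnet needs >= 2 columns; pad with a dead one
  Zf <- if (one_col) cbind(Z, `..pad` = 0) else Z
  fit <- glmnet::glmnet(Zf, y, family = "gaussian", alpha = 1,
                        lambda = penalties, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-9)
  beta <- as.matrix(fit$beta)
  if (one_col) beta <- beta[1L, , drop = FALSE]
  # glmnet may truncate the path; pad missing penalties with the last column
  if (ncol(beta) < length(penalties)) {
    pad <- matrix(beta[, ncol(beta)], nrow(beta),
                  length(penalties) - ncol(beta))
    beta <- cbind(beta, pad)
  }
  dimnames(beta) <- list(colnames(Z), NULL)
  list(penalties = penalties, coefficients = beta)
}

#' Cross-validated sparsity selection for one equation family
#'
#' K-fold cross-validation over the family's equation rows, with folds
#' stratified by bootstrap group so the near-duplicate rows of one group
#' never straddle a fold boundary. Picks the penalty minimising mean
#' held-out squared error and refits on all rows at that penalty.
#'
#' @param eqs A `dcm_equations`.
#' @param gene,stage Family indices.
#' @param cfg A [dcm_config()] (supplies folds and penalty grid length).
#' @param seed Seed for the group-to-fold assignment.
#' @param standardize Standardise predictors inside the solver (defaults to
#'   the config's choice); coefficients are returned on the original scale.
#' @return List with `penalty`, `coefficients` (named vector over predictor
#'   genes), `cv_error` (mean held-out MSE per penalty) and `penalties`.
#' @export
select_sparsity_cv <- function(eqs, gene, stage, cfg = dcm_config(),
                               seed = cfg$seed, standardize = cfg$standardize) {
  fam <- eqs$families[[gene, stage]]
  y <- fam$y; Z <- fam$Z; grp <- fam$group
  n_grp <- length(unique(grp))
  folds <- cfg$cv_folds
  if (n_grp < folds) {
    warning("fewer bootstrap groups than folds; reducing folds to ", n_grp)
    folds <- n_grp
  }
  if (all(Z == 0)) {
    warning("degenerate design (all-zero predictors); empty model")
    co <- stats::setNames(rep(0, ncol(Z)), colnames(Z))
    return(list(penalty = Inf, coefficients = co,
                cv_error = NA_real_, penalties = NA_real_))
  }
  # an explicit grid overrides the solver's own standardisation-aware grid
  penalties <- cfg$penalty_grid
  local_seed(seed)
  grp_fold <- sample(rep_len(seq_len(folds), n_grp))
  foldid <- grp_fold[match(grp, sort(unique(grp)))]
  one_col <- ncol(Z) == 1L
  Zf <- if (one_col) cbind(Z, `..pad` = 0) else Z
  cv_args <- list(x = Zf, y = y, foldid = foldid,
                  standardize = standardize, intercept = FALSE,
                  thresh = 1e-9, maxit = 1e6)
  if (is.null(penalties)) cv_args$nlambda <- cfg$n_penalties else
    cv_args$lambda <- penalties
  cv <- do.call(glmnet::cv.glmnet, cv_args)
  best <- if (identical(cfg$penalty_rule %||% "min", "1se")) cv$lambda.1se else
    cv$lambda.min
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = best, exact = FALSE))[-1L]
  if (one_col) co <- co[1L]
  names(co) <- colnames(Z)
  list(penalty = best, coefficients = co,
       cv_error = stats::setNames(cv$cvm, NULL), penalties = cv$lambda)
}

#' Inferred per-stage networks
#'
#' Container for inference output: per-stage coefficient matrices (mean over
#' repetitions; entry [i, j] is the inferred influence of regulator j on
#' target i), per-stage binary support of the final repetition-aggregated
#' model, and per-stage edge-confidence matrices (occurrence frequency of an
#' edge across repetitions, in [0, 1]).
#'
#' @param coefficients,confidence,support Lists of P x P matrices (one per
#'   stage), zero diagonal.
#' @param gene_ids Gene identifiers.
#' @param stage_labels Stage labels.
#' @param meta List of provenance fields (method, seed, config).
#' @return Object of class `stage_networks`.
#' @export
stage_networks <- function(coefficients, confidence, support, gene_ids,
                           stage_labels, meta = list()) {
  nm <- list(gene_ids, gene_ids)
  lab <- function(lst) lapply(lst, function(m) { dimnames(m) <- nm; m })
  structure(list(coefficients = lab(coefficients),
                 confidence = lab(confidence), support = lab(support),
                 gene_ids = gene_ids, stage_labels = stage_labels,
                 meta = meta),
            class = "stage_networks")
}

#' @export
print.stage_networks <- function(x, ...) {
  cat("stage_networks (", x$meta$method %||% "?", "): ",
      length(x$gene_ids), " genes, ", length(x$stage_labels), " stages; ",
      "edges per stage: ",
      paste(vapply(x$support, function(m) sum(m != 0), 0L), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# one complete modelling pass: equations -> CV lasso per family
dcm_single_fit <- function(data, trends, fc, cfg, seed) {
  seeds <- derive_seeds(seed, 2L)
  builder <- if (cfg$equation_set == "ladder") build_ladder_equations else
    build_equations
  eqs <- builder(data, trends, fc, cfg, seed = seeds[1L])
  p <- data$n_genes; S <- data$n_stages
  cv_seeds <- derive_seeds(seeds[2L], p * S)
  coefs <- lapply(seq_len(S), function(s) matrix(0, p, p))
  for (s in seq_len(S)) {
    for (i in seq_len(p)) {
      sel <- select_sparsity_cv(eqs, i, s, cfg,
                                seed = cv_seeds[(s - 1L) * p + i])
      coefs[[s]][i, -i] <- sel$coefficients
    }
  }
  coefs
}

binarize_stage <- function(coef_mat, top_k) {
  if (identical(top_k, "cv")) return((coef_mat != 0) * 1)
  ab <- abs(coef_mat); diag(ab) <- -Inf
  k <- min(top_k, sum(is.finite(ab) & ab > -Inf))
  ord <- order(ab, decreasing = TRUE)
  keep <- ord[seq_len(k)]
  out <- matrix(0, nrow(coef_mat), ncol(coef_mat))
  out[keep] <- 1
  diag(out) <- 0
  out
}

#' Reconstruct stage-specific networks with the dynamic cascaded method
#'
#' Runs the full DCM: gene-evolving trend analysis (unless supplied),
#' bootstrap construction of the cascade model equations at the configured
#' fraction settings, L1-penalised fitting with cross-validated sparsity per
#' gene and stage, and aggregation of `cfg$n_repetitions` independent
#' repetitions into edge confidences (an edge's occurrence frequency across
#' repetitions) and mean coefficients.
#'
#' @param data A [staged_expression()].
#' @param trends Optional `trend_assignment`; estimated from `data` when
#'   `NULL`.
#' @param fc A [fraction_config()].
#' @param cfg A [dcm_config()].
#' @param store_repetitions Keep each repetition's binary networks in the
#'   result (`$repetitions`), for auditing confidence counts.
#' @return A [stage_networks()] object.
#' @export
dcm_infer <- function(data, trends = NULL, fc = fraction_config(),
                      cfg = dcm_config(), store_repetitions = FALSE) {
  stopifnot(inherits(data, "staged_expression"))
  if (data$n_stages < 2L) stop("DCM requires >= 2 stages")
  if (is.null(trends)) trends <- estimate_trends(data)
  p <- data$n_genes; S <- data$n_stages
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_repetitions)
  coef_sum <- lapply(seq_len(S), function(s) matrix(0, p, p))
  occ <- lapply(seq_len(S), function(s) matrix(0, p, p))
  reps <- if (store_repetitions) vector("list", cfg$n_repetitions)
  for (r in seq_len(cfg$n_repetitions)) {
    coefs <- dcm_single_fit(data, trends, fc, cfg, rep_seeds[r])
    bins <- lapply(coefs, binarize_stage, top_k = cfg$top_k_edges)
    for (s in seq_len(S)) {
      coef_sum[[s]] <- coef_sum[[s]] + coefs[[s]]
      occ[[s]] <- occ[[s]] + bins[[s]]
    }
    if (store_repetitions) reps[[r]] <- bins
  }
  coefs <- lapply(coef_sum, `/`, cfg$n_repetitions)
  conf <- lapply(occ, `/`, cfg$n_repetitions)
  support <- lapply(conf, function(m) (m > 0.5) * 1)
  out <- stage_networks(coefs, conf, support, data$gene_ids,
                        data$stage_labels,
                        meta = list(method = "dcm", seed = cfg$seed,
                                    rho = cfg$rho,
                                    n_repetitions = cfg$n_repetitions))
  if (store_repetitions) out$repetitions <- reps
  out
}

#' Threshold inferred networks into per-stage edge lists
#'
#' @param nets A [stage_networks()].
#' @param mode `"confidence"` keeps edges with confidence >= `value`;
#'   `"top_k"` keeps the `value` highest-confidence edges per stage (ties
#'   broken by |coefficient|, then lexicographic regulator/target pair).
#' @param value Threshold (confidence level, or k).
#' @return Named list (per stage) of data frames with columns regulator,
#'   target, coefficient, confidence.
#' @export
threshold_network <- function(nets, mode = c("confidence", "top_k"), value) {
  mode <- match.arg(mode)
  p <- length(nets$gene_ids)
  out <- lapply(seq_along(nets$stage_labels), function(s) {
    conf <- nets$confidence[[s]]
    co <- nets$coefficients[[s]]
    idx <- which(row(conf) != col(conf), arr.ind = TRUE)
    df <- data.frame(regulator = nets$gene_ids[idx[, 2L]],
                     target = nets$gene_ids[idx[, 1L]],
                     coefficient = co[idx], confidence = conf[idx],
                     stringsAsFactors = FALSE)
    if (mode == "confidence") {
      df <- df[df$confidence >= value, , drop = FALSE]
    } else {
      k <- value
      if (k > nrow(df)) {
        warning("top_k exceeds the number of possible edges; keeping all")
        k <- nrow(df)
      }
      ord <- order(-df$confidence, -abs(df$coefficient),
                   df$regulator, df$target)
      df <- df[ord[seq_len(k)], , drop = FALSE]
    }
    rownames(df) <- NULL
    df
  })
  names(out) <- nets$stage_labels
  out
}
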