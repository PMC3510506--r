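#' ROC curve and AUC by rank statistics
#'
#' AUC via the Mann-Whitney statistic with midrank handling of tied scores;
#' ROC points are computed at every distinct score threshold.
#'
#' @param scores Numeric vector of edge scores (higher = more confident).
#' @param labels Logical (or 0/1) vector; TRUE marks a true edge.
#' @return List with `auc`, `n_pos`, `n_neg`, and a `roc` data frame with
#'   columns threshold, fpr, tpr.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: need at least one true and one false instance")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  list(auc = auc, n_pos = n_pos, n_neg = n_neg, roc = roc)
}

#' Significance of an AUC against a random guess
#'
#' Z = (AUC - 0.5) / SE with the Hanley-McNeil standard error evaluated
#' under the null AUC of 0.5, and a two-sided normal p-value.
#'
#' @param auc Observed AUC.
#' @param n_pos,n_neg Numbers of true and false instances.
#' @return List with `z` and `p`.
#' @export
auc_significance <- function(auc, n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  a <- 0.5
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  z <- (auc - 0.5) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' F-beta (beta = 2) and Matthews correlation for a binary prediction
#'
#' Confusion counts are taken over the full instance universe. F2 weights
#' recall twice as heavily as precision; MCC uses the standard determinant
#' formula and is defined as 0 when any confusion-table marginal is zero.
#'
#' @param predicted Logical/0-1 vector of predicted positives.
#' @param truth Logical/0-1 vector of true positives (same length).
#' @return List with `f2`, `mcc`, and the confusion counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
binary_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth); tn <- sum(!predicted & !truth)
  beta2 <- 4
  f2 <- if ((1 + beta2) * tp + beta2 * fn + fp == 0) 0 else
    (1 + beta2) * tp / ((1 + beta2) * tp + beta2 * fn + fp)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (tp * tn - fp * fn) / sqrt(denom)
  list(f2 = f2, mcc = mcc, tp = tp, fp = fp, fn = fn, tn = tn)
}

# flatten the off-diagonal of per-stage matrices of an inference result and
# the matching truth indicator; stage = NULL pools all stages
edge_instances <- function(nets, truth_net, stage = NULL,
                           score = c("coefficient", "confidence")) {
  score <- match.arg(score)
  stages <- stage %||% seq_along(nets$stage_labels)
  p <- length(nets$gene_ids)
  off <- row(matrix(0, p, p)) != col(matrix(0, p, p))
  sc <- lab <- pred <- numeric(0)
  for (s in stages) {
    m <- if (score == "confidence") nets$confidence[[s]] else
      abs(nets$coefficients[[s]])
    sc <- c(sc, m[off])
    lab <- c(lab, (truth_net$strengths[[s]] != 0)[off])
    pred <- c(pred, (nets$support[[s]] != 0)[off])
  }
  list(scores = sc, labels = as.logical(lab), predicted = as.logical(pred))
}

#' Score inferred networks against a ground-truth network
#'
#' Computes per-stage and pooled ("overall") AUC, Z, p, F2 and MCC. Truth is
#' the presence of a nonzero true edge, direction respected and sign
#' ignored; the pooled row concatenates the edge instances of all stages.
#'
#' @param nets A [stage_networks()].
#' @param truth_net A [kinetic_network()] with matching genes/stages.
#' @param score Edge score for the ROC: `"coefficient"` (|mean coefficient|,
#'   default) or `"confidence"`.
#' @return Data frame with one row per stage plus `"overall"`; columns
#'   stage, auc, z, p, f2, mcc.
#' @export
evaluate_networks <- function(nets, truth_net,
                              score = c("coefficient", "confidence")) {
  score <- match.arg(score)
  stopifnot(length(nets$gene_ids) == truth_net$n_genes,
            length(nets$stage_labels) == truth_net$n_stages)
  one_row <- function(stage, name) {
    ei <- edge_instances(nets, truth_net, stage, score)
    ra <- roc_auc(ei$scores, ei$labels)
    sig <- auc_significance(ra$auc, ra$n_pos, ra$n_neg)
    bm <- binary_metrics(ei$predicted, ei$labels)
    data.frame(stage = name, auc = ra$auc, z = sig$z, p = sig$p,
               f2 = bm$f2, mcc = bm$mcc, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(nets$stage_labels), function(s)
    one_row(s, nets$stage_labels[s]))
  rows[[length(rows) + 1L]] <- one_row(NULL, "overall")
  do.call(rbind, rows)
}

#' Score an inferred edge-list file against a ground-truth edge list
#'
#' File-level companion of [evaluate_networks()]: takes data frames as read
#' by [read_edges()] (columns stage, regulator, target, plus coefficient/
#' confidence for the inferred network and strength for the truth) and
#' returns the same per-stage and pooled metrics table. Every ordered
#' non-self gene pair of every stage is an instance; edges absent from the
#' network file score 0 and are not predicted.
#'
#' @param network Data frame of inferred edges.
#' @param truth Data frame of true edges (defines stages and, together with
#'   `genes`, the universe).
#' @param genes Optional character vector of all gene ids (default: union of
#'   ids seen in either file).
#' @param score Column used for ranking: `"coefficient"` (absolute value,
#'   default) or `"confidence"`.
#' @return Data frame with columns stage, auc, z, p, f2, mcc.
#' @export
evaluate_edge_lists <- function(network, truth, genes = NULL,
                                score = c("coefficient", "confidence")) {
  score <- match.arg(score)
  if (is.null(genes))
    genes <- sort(unique(c(truth$regulator, truth$target,
                           network$regulator, network$target)))
  stages <- unique(truth$stage)
  p <- length(genes)
  pair_key <- function(df) paste(df$regulator, df$target, sep = "\r")
  universe <- expand.grid(regulator = genes, target = genes,
                          stringsAsFactors = FALSE)
  universe <- universe[universe$regulator != universe$target, ]
  ukey <- pair_key(universe)
  per_stage <- lapply(stages, function(st) {
    tr <- truth[truth$stage == st, ]
    nw <- network[network$stage == st, ]
    sc <- rep(0, nrow(universe))
    idx <- match(pair_key(nw), ukey)
    val <- if (score == "coefficient") abs(nw$coefficient) else nw$confidence
    sc[idx[!is.na(idx)]] <- val[!is.na(idx)]
    list(scores = sc, labels = ukey %in% pair_key(tr),
         predicted = ukey %in% pair_key(nw))
  })
  one_row <- function(parts, name) {
    sc <- unlist(lapply(parts, `[[`, "scores"))
    lab <- unlist(lapply(parts, `[[`, "labels"))
    pred <- unlist(lapply(parts, `[[`, "predicted"))
    ra <- roc_auc(sc, lab)
    sig <- auc_significance(ra$auc, ra$n_pos, ra$n_neg)
    bm <- binary_metrics(pred, lab)
    data.frame(stage = name, auc = ra$auc, z = sig$z, p = sig$p,
               f2 = bm$f2, mcc = bm$mcc, stringsAsFactors = FALSE)
  }
  rows <- mapply(function(part, st) one_row(list(part), st),
                 per_stage, stages, SIMPLIFY = FALSE)
  rows[[length(rows) + 1L]] <- one_row(per_stage, "overall")
  do.call(rbind, rows)
}

#' Enrichment of a predicted edge set in known interactions
#'
#' Compares the proportion of known interactions among the predicted edges
#' with the baseline proportion of a random guess (known interactions over
#' the universe of all ordered non-self gene pairs), and tests the overlap
#' with a hypergeometric upper tail.
#'
#' @param predicted Data frame of predicted edges (columns regulator,
#'   target).
#' @param known Data frame of known interactions (columns regulator,
#'   target; orientation ignored when `directed = FALSE`).
#' @param n_genes Number of genes in the universe; universe size is
#'   n_genes * (n_genes - 1) ordered non-self pairs.
#' @param directed If `FALSE` (default, the convention for interaction
#'   databases) a known pair matches a predicted edge in either orientation.
#' @return Object of class `enrichment_result`: n_predicted, n_known,
#'   n_hits, universe_size, baseline, ratio, p_value, significant.
#' @export
enrichment <- function(predicted, known, n_genes, directed = FALSE) {
  if (nrow(predicted) == 0L) stop("empty predicted edge set")
  universe <- n_genes * (n_genes - 1)
  key <- function(df) paste(df$regulator, df$target, sep = "\r")
  known_keys <- unique(key(known))
  n_known <- length(known_keys)  # distinct known interactions
  match_keys <- known_keys
  if (!directed) {
    match_keys <- union(known_keys,
                        paste(known$target, known$regulator, sep = "\r"))
  }
  hits <- sum(key(predicted) %in% match_keys)
  baseline <- n_known / universe
  ratio <- (hits / nrow(predicted)) / baseline
  p <- stats::phyper(hits - 1, n_known, universe - n_known,
                     nrow(predicted), lower.tail = FALSE)
  structure(list(n_predicted = nrow(predicted), n_known = n_known,
                 n_hits = hits, universe_size = universe,
                 baseline = baseline, ratio = ratio, p_value = p,
                 significant = p < 0.05),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("enrichment: %d/%d predicted edges known ",
                     "(baseline %.4f, ratio %.2f, p = %.3g%s)\n"),
              x$n_hits, x$n_predicted, x$baseline, x$ratio, x$p_value,
              if (x$significant) ", significant" else ""))
  invisible(x)
}
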