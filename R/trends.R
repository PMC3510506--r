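#' Gene-evolving trend analysis
#'
#' Decides, per gene and per stage, whether expression evolves in an
#' ascending or a descending trend. Under the intra-stage steady-rate
#' assumption a stage's samples are draws from a linear-in-time profile, so
#' the stage's earliest and latest expression values are its extreme
#' empirical quantiles: the 0- and 1-quantile if the gene ascends, swapped
#' if it descends. The continuity assumption says the profile does not jump
#' at stage transitions, so for each gene the method picks the flag sequence
#' d_1..d_S minimising the total boundary mismatch
#' sum_s |end(s-1, d_{s-1}) - start(s, d_s)|,
#' solved exactly by dynamic programming over stages. Ties are broken toward
#' ascending (lexicographically smallest flag sequence among minimisers).
#'
#' @param data A [staged_expression()].
#' @param method `"dp_continuity"` (default; the boundary-mismatch dynamic
#'   program) or `"mean_diff"` (ascending in stage s iff its mean exceeds
#'   stage s-1's mean; the first stage copies the second stage's flag).
#' @param trim Fraction in [0, 0.5) trimmed from each end when estimating a
#'   stage's start/end quantiles (default 0 = min/max; a small positive trim
#'   makes the endpoints robust on noisy data).
#' @return Object of class `trend_assignment`: a genes x stages character
#'   matrix `direction` with entries "ascending"/"descending", and a per-gene
#'   `discontinuity` score (the minimised total boundary mismatch, in
#'   expression units).
#' @export
estimate_trends <- function(data, method = c("dp_continuity", "mean_diff"),
                            trim = 0) {
  stopifnot(inherits(data, "staged_expression"), trim >= 0, trim < 0.5)
  method <- match.arg(method)
  S <- data$n_stages
  if (any(vapply(data$matrices, ncol, 0L) < 2L))
    stop("every stage needs at least 2 samples for trend analysis")
  p <- data$n_genes
  dir_mat <- matrix("ascending", p, S,
                    dimnames = list(data$gene_ids, data$stage_labels))
  score <- numeric(p); names(score) <- data$gene_ids
  for (g in seq_len(p)) {
    lo <- vapply(data$matrices, function(m)
      stats::quantile(m[g, ], trim, names = FALSE, type = 7), 0)
    hi <- vapply(data$matrices, function(m)
      stats::quantile(m[g, ], 1 - trim, names = FALSE, type = 7), 0)
    if (method == "dp_continuity") {
      res <- trend_dp(lo, hi)
      dir_mat[g, ] <- ifelse(res$flags, "ascending", "descending")
      score[g] <- res$cost
    } else {
      mid <- (lo + hi) / 2
      asc <- c(NA, diff(mid) > 0)
      asc[1L] <- asc[2L]
      dir_mat[g, ] <- ifelse(asc, "ascending", "descending")
      score[g] <- NA_real_
    }
  }
  structure(list(direction = dir_mat, discontinuity = score,
                 method = method),
            class = "trend_assignment")
}

#' @export
print.trend_assignment <- function(x, ...) {
  cat("trend_assignment (", x$method, "): ", nrow(x$direction), " genes x ",
      ncol(x$direction), " stages\n", sep = "")
  invisible(x)
}

# Exact DP over flag sequences. lo/hi: per-stage extreme quantiles.
# flags: TRUE = ascending (start = lo, end = hi), FALSE = descending.
# Backward value iteration + forward walk preferring ascending on ties gives
# the lexicographically smallest minimiser (ascending < descending).
trend_dp <- function(lo, hi) {
  S <- length(lo)
  start_of <- function(s, asc) if (asc) lo[s] else hi[s]
  end_of   <- function(s, asc) if (asc) hi[s] else lo[s]
  if (S == 1L) return(list(flags = TRUE, cost = 0))
  # cost_to_go[s, d]: best total mismatch over boundaries s..S-1 given flag d
  # at stage s (d = 1 ascending, 2 descending)
  ctg <- matrix(0, S, 2L)
  for (s in (S - 1L):1L) {
    for (d in 1:2) {
      asc <- d == 1L
      cand <- vapply(1:2, function(d2) {
        abs(end_of(s, asc) - start_of(s + 1L, d2 == 1L)) + ctg[s + 1L, d2]
      }, 0)
      ctg[s, d] <- min(cand)
    }
  }
  flags <- logical(S)
  # exact ties are common (a stage whose range lies on one side of both
  # neighbours costs the same either way); prefer ascending within a small
  # tolerance so floating-point noise cannot flip the preference
  tol <- 1e-9
  flags[1L] <- ctg[1L, 1L] <= ctg[1L, 2L] + tol
  for (s in 2:S) {
    prev_end <- end_of(s - 1L, flags[s - 1L])
    cost_asc  <- abs(prev_end - start_of(s, TRUE))  + ctg[s, 1L]
    cost_desc <- abs(prev_end - start_of(s, FALSE)) + ctg[s, 2L]
    flags[s] <- cost_asc <= cost_desc + tol
  }
  list(flags = flags, cost = min(ctg[1L, ]))
}

# brute-force reference: enumerate all 2^S flag sequences (asc-first order)
trend_bruteforce <- function(lo, hi) {
  S <- length(lo)
  best <- NULL; best_cost <- Inf
  for (code in 0:(2^S - 1L)) {
    # bit 0 = ascending so counting order is lexicographic with asc first
    flags <- bitwAnd(code %/% 2^((S - 1L):0L), 1L) == 0L
    cost <- 0
    for (s in 2:S) {
      e <- if (flags[s - 1L]) hi[s - 1L] else lo[s - 1L]
      st <- if (flags[s]) lo[s] else hi[s]
      cost <- cost + abs(e - st)
    }
    if (cost < best_cost - 1e-9) { best <- flags; best_cost <- cost }
  }
  list(flags = best, cost = best_cost)
}

#' Write a trend table to TSV
#'
#' Columns: gene, stage, direction, score (per-gene discontinuity score,
#' repeated across that gene's rows).
#'
#' @param trends A `trend_assignment`.
#' @param path Output file path.
#' @export
write_trends <- function(trends, path) {
  d <- trends$direction
  df <- data.frame(gene = rep(rownames(d), times = ncol(d)),
                   stage = rep(colnames(d), each = nrow(d)),
                   direction = as.vector(d),
                   score = rep(trends$discontinuity, times = ncol(d)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
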