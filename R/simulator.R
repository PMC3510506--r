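#' Stage specification
#'
#' A stage of a multi-stage biological process: a label, a time span (in the
#' simulator's time unit) and a sampling cadence.
#'
#' @param label Stage label (character scalar).
#' @param time_span Positive real; duration of the stage.
#' @param samples_per_unit_time Positive integer; how many samples are
#'   recorded per unit time (default 1).
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(label, time_span, samples_per_unit_time = 1L) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(time_span), length(time_span) == 1L, time_span > 0,
            samples_per_unit_time >= 1)
  structure(list(label = label, time_span = as.numeric(time_span),
                 samples_per_unit_time = as.integer(samples_per_unit_time)),
            class = "stage_spec")
}

#' Multi-stage kinetic regulatory network
#'
#' Ground-truth object for the simulator: per-stage signed regulatory
#' strength matrices on top of first-order mRNA degradation. Within each
#' stage the expression vector x obeys
#' dx_i/dt = -deg_i * x_i + sum_j beta_ij^s * x_j,
#' where `strengths[[s]][i, j]` is beta_ij^s, the strength of regulator j
#' acting on target i.
#'
#' @param strengths List (one per stage) of P x P numeric matrices with zero
#'   diagonal.
#' @param degradation Numeric vector of P positive turnover rates.
#' @param initial_state Numeric vector of P starting expression levels.
#' @param stages List of [stage_spec()] objects, in process order.
#' @param gene_ids Optional character vector of gene names (default g1..gP).
#' @return An object of class `kinetic_network`.
#' @export
kinetic_network <- function(strengths, degradation, initial_state, stages,
                            gene_ids = NULL) {
  stopifnot(is.list(strengths), length(strengths) >= 1L,
            is.list(stages), length(stages) == length(strengths))
  p <- length(degradation)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  stopifnot(length(initial_state) == p, length(gene_ids) == p,
            all(degradation > 0))
  for (B in strengths) {
    stopifnot(is.matrix(B), nrow(B) == p, ncol(B) == p)
    if (any(diag(B) != 0))
      stop("strength matrices must have zero diagonal (no self-regulation)")
  }
  strengths <- lapply(strengths, function(B) {
    dimnames(B) <- list(gene_ids, gene_ids); B
  })
  structure(list(strengths = strengths,
                 degradation = as.numeric(degradation),
                 initial_state = as.numeric(initial_state),
                 stages = stages, gene_ids = gene_ids,
                 n_genes = p, n_stages = length(stages)),
            class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat("kinetic_network:", x$n_genes, "genes,", x$n_stages, "stages\n")
  for (s in seq_len(x$n_stages)) {
    cat(sprintf("  stage %s: span %.4g, %d edges\n", x$stages[[s]]$label,
                x$stages[[s]]$time_span, sum(x$strengths[[s]] != 0)))
  }
  invisible(x)
}

# expand a listed motif into directed edges (regulator -> target pairs)
motif_edges <- function(kind, nodes) {
  k <- length(nodes)
  edges <- switch(kind,
    loop = cbind(nodes, nodes[c(seq_len(k)[-1L], 1L)]),
    # feed-forward: the chain along the listed order plus the direct shortcut
    # from head to tail (for three nodes: a->b, b->c, a->c)
    feed_forward = rbind(cbind(nodes[-k], nodes[-1L]),
                         c(nodes[1L], nodes[k])),
    # central structure: the first listed node is a hub regulating the rest
    central = cbind(nodes[1L], nodes[-1L]),
    stop("unknown motif kind: ", kind))
  colnames(edges) <- c("regulator", "target")
  edges
}

benchmark_motifs <- function() {
  list(
    list(list("loop", c(3, 5, 4)), list("feed_forward", c(3, 5, 2)),
         list("feed_forward", c(3, 2, 1, 6)), list("central", c(3, 2, 5, 6))),
    list(list("loop", c(2, 6, 3)), list("loop", c(1, 4, 5))),
    list(list("loop", c(2, 6, 4, 3)), list("feed_forward", c(2, 6, 1)),
         list("feed_forward", c(5, 4, 3))),
    list(list("loop", c(2, 3, 4)), list("loop", c(1, 2, 3, 5, 6)),
         list("feed_forward", c(3, 5, 4)))
  )
}

#' Build the six-gene four-stage benchmark network
#'
#' Constructs the in-silico benchmark used throughout the package: six genes
#' evolving through four consecutive stages whose regulatory topologies are
#' assembled from common motifs (loops, feed-forward structures and a hub),
#' with degradation rate 0.05 for every gene, regulatory strengths drawn
#' uniformly from {+0.1, -0.1}, initial expression 1.0 and stage time spans
#' 20, 30, 20 and 30.
#'
#' @param seed Integer seed controlling the random +/-0.1 sign assignment.
#' @return A [kinetic_network()] with 6 genes and 4 stages.
#' @export
build_benchmark_network <- function(seed = 1L) {
  p <- 6L
  spans <- c(20, 30, 20, 30)
  labels <- c("I", "II", "III", "IV")
  motifs <- benchmark_motifs()
  rng <- local_seed(seed)
  strengths <- vector("list", 4L)
  for (s in 1:4) {
    B <- matrix(0, p, p)
    edges <- do.call(rbind, lapply(motifs[[s]],
                                   function(m) motif_edges(m[[1]], m[[2]])))
    edges <- unique(edges)
    for (e in seq_len(nrow(edges))) {
      j <- edges[e, 1L]; i <- edges[e, 2L]  # regulator j -> target i
      B[i, j] <- sample(c(0.1, -0.1), 1L)
    }
    strengths[[s]] <- B
  }
  stages <- mapply(stage_spec, labels, spans, SIMPLIFY = FALSE)
  kinetic_network(strengths, degradation = rep(0.05, p),
                  initial_state = rep(1.0, p), stages = stages)
}

#' Integrate the transcription kinetics across all stages
#'
#' Integrates dx_i/dt = -deg_i x_i + sum_j beta_ij^s x_j with a fixed-step
#' fourth-order Runge-Kutta scheme, switching the strength matrix at stage
#' boundaries while carrying the state over unchanged, so the profile is
#' continuous across the whole process. Samples are recorded at each stage's
#' cadence (every 1/samples_per_unit_time time units).
#'
#' @param net A [kinetic_network()].
#' @param dt Positive step size; must divide each stage span and the sampling
#'   interval (default 0.01).
#' @return An object of class `time_course` with fields `times`, `values`
#'   (genes x timepoints), `stage_of_timepoint` and `stage_labels`.
#' @export
integrate_kinetics <- function(net, dt = 0.01) {
  stopifnot(inherits(net, "kinetic_network"), dt > 0)
  p <- net$n_genes
  x <- net$initial_state
  t_now <- 0
  times <- numeric(0)
  stage_idx <- integer(0)
  values <- list()
  for (s in seq_len(net$n_stages)) {
    sp <- net$stages[[s]]
    n_steps <- round(sp$time_span / dt)
    if (abs(n_steps * dt - sp$time_span) > 1e-8)
      stop("dt must divide the span of stage ", sp$label)
    record_every <- round(1 / (dt * sp$samples_per_unit_time))
    if (record_every < 1) stop("sampling cadence finer than dt")
    A <- -diag(net$degradation, nrow = p) + net$strengths[[s]]
    for (k in seq_len(n_steps)) {
      k1 <- A %*% x
      k2 <- A %*% (x + dt / 2 * k1)
      k3 <- A %*% (x + dt / 2 * k2)
      k4 <- A %*% (x + dt * k3)
      x <- x + dt / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + dt
      if (!all(is.finite(x)))
        stop(sprintf("divergent dynamics: non-finite state at t = %.4f", t_now))
      if (k %% record_every == 0L) {
        times <- c(times, t_now)
        stage_idx <- c(stage_idx, s)
        values[[length(values) + 1L]] <- x
      }
    }
  }
  vals <- do.call(cbind, values)
  rownames(vals) <- net$gene_ids
  # snap accumulated fp error in recorded times to the sampling grid
  times <- round(times / dt) * dt
  structure(list(times = times, values = vals,
                 stage_of_timepoint = stage_idx,
                 stage_labels = vapply(net$stages, `[[`, "", "label"),
                 gene_ids = net$gene_ids),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("time_course:", nrow(x$values), "genes,", length(x$times),
      "timepoints over", length(x$stage_labels), "stages\n")
  invisible(x)
}

#' Stage-labelled sample-based expression data
#'
#' The central input type for inference: one genes x samples matrix per
#' ordered stage. Sample order within a stage carries no temporal meaning.
#'
#' @param matrices List (one per stage) of genes x samples numeric matrices.
#' @param stage_labels Character vector of stage labels, in process order.
#' @param gene_ids Optional gene identifiers (default taken from rownames).
#' @return An object of class `staged_expression`.
#' @export
staged_expression <- function(matrices, stage_labels, gene_ids = NULL) {
  stopifnot(is.list(matrices), length(matrices) == length(stage_labels))
  p <- nrow(matrices[[1L]])
  if (is.null(gene_ids)) gene_ids <- rownames(matrices[[1L]])
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  for (m in matrices) stopifnot(is.matrix(m), nrow(m) == p)
  matrices <- lapply(matrices, function(m) { rownames(m) <- gene_ids; m })
  names(matrices) <- stage_labels
  structure(list(matrices = matrices, stage_labels = stage_labels,
                 gene_ids = gene_ids, n_genes = p,
                 n_stages = length(stage_labels)),
            class = "staged_expression")
}

#' @export
print.staged_expression <- function(x, ...) {
  cat("staged_expression:", x$n_genes, "genes; samples per stage:",
      paste(sprintf("%s=%d", x$stage_labels,
                    vapply(x$matrices, ncol, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' Scramble a time course into sample-based data
#'
#' Discards the time sequence while keeping the staging information: within
#' each stage the timepoint columns are randomly permuted, producing
#' stage-labelled samples without temporal ordering.
#'
#' @param tc A `time_course`.
#' @param seed Integer seed for the per-stage permutations.
#' @return A [staged_expression()] object.
#' @export
to_sample_based <- function(tc, seed = 1L) {
  stopifnot(inherits(tc, "time_course"))
  rng <- local_seed(seed)
  mats <- lapply(seq_along(tc$stage_labels), function(s) {
    cols <- which(tc$stage_of_timepoint == s)
    if (length(cols) < 2L)
      stop("stage ", tc$stage_labels[s], " has fewer than 2 samples")
    m <- tc$values[, sample(cols), drop = FALSE]
    colnames(m) <- paste0(tc$stage_labels[s], "_", seq_along(cols))
    m
  })
  staged_expression(mats, tc$stage_labels, tc$gene_ids)
}

#' Corrupt sample-based data with scaled Gaussian noise
#'
#' Adds independent Gaussian noise to every entry. The noise standard
#' deviation for a gene is `noise_to_signal` times that gene's empirical
#' standard deviation across all samples of all stages, so the level is a
#' noise-to-signal ratio in the usual sense.
#'
#' @param data A [staged_expression()].
#' @param noise_to_signal Non-negative noise-to-signal level.
#' @param seed Integer seed.
#' @return A new [staged_expression()] with noise added.
#' @export
add_noise <- function(data, noise_to_signal, seed = 1L) {
  stopifnot(inherits(data, "staged_expression"), noise_to_signal >= 0)
  if (noise_to_signal == 0) return(data)
  all_mat <- do.call(cbind, data$matrices)
  gene_sd <- apply(all_mat, 1L, stats::sd)
  rng <- local_seed(seed)
  mats <- lapply(data$matrices, function(m) {
    noise <- matrix(stats::rnorm(length(m)), nrow(m), ncol(m)) *
      (noise_to_signal * gene_sd)
    m + noise
  })
  staged_expression(mats, data$stage_labels, data$gene_ids)
}

#' Extract the true edge set of a stage
#'
#' @param net A [kinetic_network()].
#' @param stage Stage index.
#' @return Data frame with columns regulator, target, strength (nonzero
#'   entries of the stage's strength matrix; directed regulator -> target).
#' @export
true_edges <- function(net, stage) {
  B <- net$strengths[[stage]]
  idx <- which(B != 0, arr.ind = TRUE)
  data.frame(regulator = net$gene_ids[idx[, "col"]],
             target = net$gene_ids[idx[, "row"]],
             strength = B[idx], stringsAsFactors = FALSE)
}
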