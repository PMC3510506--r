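# Benchmark driver: simulate -> infer -> evaluate, repeated to cancel the
# randomness effect, plus parameter sweeps (rho, bootstrap group size,
# noise-to-signal level).

simulate_benchmark_rep <- function(seed, noise = 0) {
  seeds <- derive_seeds(seed, 3L)
  net <- build_benchmark_network(seeds[1L])
  tc <- integrate_kinetics(net)
  samp <- to_sample_based(tc, seeds[2L])
  if (noise > 0) samp <- add_noise(samp, noise, seeds[3L])
  list(net = net, tc = tc, samp = samp)
}

run_method_once <- function(method, sim, seed, rho = 0.6, group_size = 16L,
                            n_bootstrap_groups = 200L, fc = fraction_config()) {
  nets <- switch(method,
    dcm = dcm_infer(sim$samp,
                    cfg = dcm_config(rho = rho, group_size = group_size,
                                     n_bootstrap_groups = n_bootstrap_groups,
                                     n_repetitions = 1L, seed = seed),
                    fc = fc),
    static = static_infer(sim$samp, baseline_config(seed = seed)),
    dynamic = dynamic_infer(sim$tc, baseline_config(seed = seed)),
    stop("unknown method: ", method))
  evaluate_networks(nets, sim$net, score = "coefficient")
}

#' Run the simulation benchmark
#'
#' Repeats simulate -> infer -> evaluate on the six-gene four-stage
#' benchmark. Each repetition draws a fresh benchmark network (new random
#' +/-0.1 edge signs), integrates the kinetics, scrambles the time course
#' into stage-labelled samples (optionally corrupted with noise), runs the
#' requested inference methods, and scores them against the ground truth.
#'
#' @param reps Number of modelling repetitions (>= 2).
#' @param seed Master seed; each repetition gets a derived sub-seed.
#' @param methods Subset of `c("dcm", "static", "dynamic")`.
#' @param rho,group_size,n_bootstrap_groups DCM settings (defaults 0.6, 16,
#'   200).
#' @param noise Noise-to-signal level applied to the sample-based data
#'   (default 0; the dynamic baseline always sees the noiseless course).
#' @param fc A [fraction_config()].
#' @return Object of class `benchmark_result`: `$per_rep` (one row per rep
#'   x method x stage) and `$summary` (mean and sd per method x stage).
#' @export
run_benchmark <- function(reps = 20L, seed = 1L,
                          methods = c("dcm", "static", "dynamic"),
                          rho = 0.6, group_size = 16L,
                          n_bootstrap_groups = 200L, noise = 0,
                          fc = fraction_config()) {
  stopifnot(reps >= 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, 2L * reps)
  rows <- list()
  for (r in seq_len(reps)) {
    sim <- simulate_benchmark_rep(rep_seeds[r], noise = noise)
    for (m in methods) {
      met <- run_method_once(m, sim, seed = rep_seeds[reps + r], rho = rho,
                             group_size = group_size,
                             n_bootstrap_groups = n_bootstrap_groups,
                             fc = fc)
      rows[[length(rows) + 1L]] <- cbind(rep = r, method = m, met)
    }
  }
  per_rep <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(auc, p, f2, mcc) ~ method + stage, data = per_rep,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  structure(list(per_rep = per_rep, summary = summary, seed = seed,
                 reps = reps, noise = noise, rho = rho,
                 group_size = group_size),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  ov <- x$per_rep[x$per_rep$stage == "overall", ]
  cat("benchmark_result:", x$reps, "repetitions; overall AUC (mean +/- sd):\n")
  for (m in unique(ov$method)) {
    v <- ov$auc[ov$method == m]
    cat(sprintf("  %-8s %.3f +/- %.3f\n", m, mean(v), stats::sd(v)))
  }
  invisible(x)
}

#' Mean pooled AUC of a benchmark result
#'
#' @param bench A `benchmark_result`.
#' @param method Method name.
#' @return Mean over repetitions of the pooled (all-stage) AUC.
#' @export
overall_auc <- function(bench, method = "dcm") {
  ov <- bench$per_rep[bench$per_rep$stage == "overall" &
                        bench$per_rep$method == method, ]
  mean(ov$auc)
}

#' Sweep a DCM parameter on the benchmark
#'
#' Runs the DCM over a grid of one parameter (`rho`, `group_size` or
#' `noise`), sharing the simulated datasets across grid values within each
#' repetition so grid points are compared on paired data.
#'
#' @param param One of `"rho"`, `"group_size"`, `"noise"`.
#' @param grid Numeric grid of parameter values.
#' @param reps Repetitions per grid value.
#' @param seed Master seed.
#' @param rho,group_size DCM settings held fixed while another parameter is
#'   swept.
#' @param n_bootstrap_groups Bootstrap groups per fit.
#' @return Data frame with columns value, mean_auc, sd_auc.
#' @export
sweep_dcm <- function(param = c("rho", "group_size", "noise"), grid,
                      reps = 10L, seed = 1L, rho = 0.6, group_size = 16L,
                      n_bootstrap_groups = 200L) {
  param <- match.arg(param)
  rep_seeds <- derive_seeds(seed, 2L * reps)
  auc <- matrix(NA_real_, reps, length(grid))
  for (r in seq_len(reps)) {
    base_sim <- simulate_benchmark_rep(rep_seeds[r], noise = 0)
    noise_seeds <- derive_seeds(rep_seeds[r] + 1L, length(grid))
    for (k in seq_along(grid)) {
      v <- grid[k]
      sim <- base_sim
      if (param == "noise" && v > 0)
        sim$samp <- add_noise(base_sim$samp, v, noise_seeds[k])
      met <- run_method_once(
        "dcm", sim, seed = rep_seeds[reps + r],
        rho = if (param == "rho") v else rho,
        group_size = if (param == "group_size") v else group_size,
        n_bootstrap_groups = n_bootstrap_groups)
      auc[r, k] <- met$auc[met$stage == "overall"]
    }
  }
  data.frame(value = grid, mean_auc = colMeans(auc),
             sd_auc = apply(auc, 2L, stats::sd))
}
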