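# shared fixtures, built once per test run

bench_net <- build_benchmark_network(1)
bench_tc <- integrate_kinetics(bench_net)
bench_samp <- to_sample_based(bench_tc, 2)

# small synthetic staged dataset with known monotone structure
make_toy_staged <- function(n_genes = 3, n_per_stage = c(8, 10, 8),
                            seed = 42) {
  set.seed(seed)
  S <- length(n_per_stage)
  mats <- lapply(seq_len(S), function(s) {
    base <- matrix(rep(seq_len(n_genes) + s, n_per_stage[s]), n_genes)
    base + matrix(runif(n_genes * n_per_stage[s]), n_genes)
  })
  staged_expression(mats, paste0("S", seq_len(S)))
}
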