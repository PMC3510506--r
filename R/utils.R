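# seed plumbing: every exported stochastic operation takes one seed and
# derives independent substream seeds from it, so a single manifest seed
# determines the whole run

local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# n reproducible child seeds below 2^31, derived from one parent seed
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
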