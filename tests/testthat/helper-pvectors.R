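# Deterministic battery of p-value vectors of varying length and signal
# strength, shared by the FDR tests and the frozen reference fixture
# (fixtures/bky_reference.tsv holds the rejection counts of an independent
# reference implementation of the two-stage step-up on exactly these
# vectors).
pvalue_battery <- function(n_vectors = 1000) {
  withr::with_seed(872634, {
    lapply(seq_len(n_vectors), function(i) {
      m <- sample(5:40, 1)
      stats::runif(m)^sample(1:4, 1)
    })
  })
}
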