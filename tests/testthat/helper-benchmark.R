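# The synthetic benchmark shared by the acceptance tests (assignment ratio
# and correct classification use the same 10 records); computed once per
# test run.
.acc_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.acc_cache$bench)) {
    .acc_cache$bench <- run_benchmark(n_records = 10, seed = 1,
                                      config = emg_config())
  }
  .acc_cache$bench
}
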