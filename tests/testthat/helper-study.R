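# The simulation-recovery study is the most expensive fixture; run it once
# per test session and share it across test files.
.study_cache <- new.env(parent = emptyenv())

get_recovery_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_recovery_study(seed = 42L)
  }
  .study_cache$study
}
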