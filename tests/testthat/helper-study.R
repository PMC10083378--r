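# Three full mini-profile study iterations, trained once and shared by the
# decoding, selectivity, and trainability acceptance checks.
get_mini_studies <- function() {
  if (is.null(.fixtures$mini_studies)) {
    .fixtures$mini_studies <- lapply(1:3, function(s)
      run_study(study_config("mini"), seed = s,
                stages = c("decode", "selectivity")))
  }
  .fixtures$mini_studies
}
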