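# Default phantom pair and preprocessed volumes, generated once per test
# run and shared across files (everything downstream is deterministic in
# the spec seed).
.cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.cache$ph))
    .cache$ph <- generate_phantom_pair(phantom_spec())
  .cache$ph
}

preprocessed_phantom <- function() {
  if (is.null(.cache$pp)) {
    ph <- default_phantom()
    .cache$pp <- list(pct = preprocess_volume(ph$pct, "pct"),
                      cbct = preprocess_volume(ph$cbct, "cbct"))
  }
  .cache$pp
}
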