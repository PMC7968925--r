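# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(code)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}
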