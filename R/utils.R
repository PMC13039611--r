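# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed just evaluates the code.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# Spawn `n` reproducible child seeds from one root seed (kept below 2^31).
spawn_seeds_ <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_num_ <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
          class = "rippleRT_invalid_configuration")
  }
  invisible(x)
}

# dB <-> linear power / amplitude
db_to_amp_ <- function(db) 10^(db / 20)
amp_to_db_ <- function(a) 20 * log10(a)
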