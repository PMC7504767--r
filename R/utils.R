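# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. Keeps seeded operations
# (MDS restarts, synthetic data) from perturbing the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = env) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = env)
      } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# round-half-up to nearest integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

stop_actland <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
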