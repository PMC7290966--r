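#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in a cohort analysis flows from one master seed; every
#' (subject, temperature, run, ...) context gets its own deterministic
#' sub-seed so that pipeline stages can be re-run in isolation and still
#' reproduce the full-run numbers. The derivation is a polynomial rolling
#' hash over the master seed and the context labels, reduced modulo a prime
#' below 2^31 so the result is always a valid R integer seed.
#'
#' @param master_seed Integer master seed.
#' @param ... Context labels (coerced to character): subject id, temperature
#'   index, run index, stage name, ...
#' @return A single integer in `[1, 2147483586]`.
#' @examples
#' derive_seed(42, "sub-01", 3, 1)
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  mod <- 2147483587  # prime < 2^31
  key <- paste(c(format(master_seed, scientific = FALSE),
                 vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1))),
               collapse = "\x1f")
  h <- (as.double(master_seed) %% mod + 17) %% mod
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h %% 2147483586) + 1L
}

# Run an expression under a local, seeded RNG without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
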