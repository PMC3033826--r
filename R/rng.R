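# Seed discipline: every stochastic entry point takes an integer `rng_seed`
# (NULL = use the caller's RNG stream) and restores the caller's RNG state on
# exit, so seeded calls never perturb the surrounding session.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    })
    set.seed(seed)
  }
  code
}

#' Derive independent child seeds from a master seed
#'
#' Fans one master seed out into `n` reproducible child seeds so that pipeline
#' stages (or ensemble runs) can be re-run in isolation with their own stream.
#'
#' @param master_seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  with_seed(as.integer(master_seed), sample.int(.Machine$integer.max, n))
}

# sample() with the length-1 surprise removed
sample1 <- function(x) {
  if (length(x) == 0L) stop("cannot sample from an empty set")
  x[[sample.int(length(x), 1L)]]
}
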