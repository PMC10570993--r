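# Named, independent random streams derived from one master seed.
#
# Each source of randomness (force field, axial offsets, tilt draws, ...)
# consumes its own derived seed so that switching one variability type on or
# off never perturbs the draws of another -- parameter sweeps stay
# comparable across cells that share a master seed.

.npcsim_streams <- c(
  params     = 1L,
  forces     = 2L,
  axial      = 3L,
  tilt       = 4L,
  shift      = 5L,
  elongation = 6L,
  labelling  = 7L,
  placement  = 8L
)

#' Derive a reproducible sub-seed from a master seed
#'
#' Combines a master seed, a named stream and an index (e.g. the NPC number
#' within a run) into a deterministic 31-bit seed. Distinct streams and
#' indices map to distinct seeds for all practical run sizes.
#'
#' @param master integer master seed.
#' @param stream one of `"params"`, `"forces"`, `"axial"`, `"tilt"`,
#'   `"shift"`, `"elongation"`, `"labelling"`, `"placement"`.
#' @param index non-negative integer, default 0 (e.g. per-NPC counter).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream = "params", index = 0L) {
  if (!stream %in% names(.npcsim_streams)) {
    stop("unknown random stream: ", stream)
  }
  sid <- as.double(.npcsim_streams[[stream]])
  # all intermediates stay below 2^53, so doubles carry them exactly
  x <- (as.double(master) %% 2147483647) * 48271 +
    sid * 1299709 + as.double(index) * 7919
  as.integer(x %% 2147483646) + 1L
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous global RNG
#' state, so library calls never disturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
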