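#' @keywords internal
"_PACKAGE"

# Stage offsets for the seed-derivation rule: every stochastic stage draws
# from its own stream seeded as (seed + offset) so stages can be re-run
# independently of each other. Offsets are < 1000 and seeds are kept < 2^31.
.seed_offsets <- c(
  genotypes   = 101L,
  status      = 211L,
  missingness = 307L,
  bmi         = 401L,
  phenotypes  = 503L
)

#' Derive a stage-specific seed from a global seed
#'
#' One global seed drives the whole simulation; each stochastic stage
#' (genotypes, status, missingness, BMI, phenotypes) uses the global seed
#' plus a fixed small offset, so any stage is reproducible on its own.
#'
#' @param seed integer global seed.
#' @param stage one of `"genotypes"`, `"status"`, `"missingness"`, `"bmi"`,
#'   `"phenotypes"`.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stage <- match.arg(stage, names(.seed_offsets))
  (as.integer(seed) + .seed_offsets[[stage]]) %% .Machine$integer.max
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_prop <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) .stopf("%s must be finite numeric", name)
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (any(!lo_ok | !hi_ok)) .stopf("%s must lie in %s0, 1%s", name,
                                   if (open_left) "(" else "[",
                                   if (open_right) ")" else "]")
  invisible(x)
}
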