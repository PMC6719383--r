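#' Derive a child seed from a master seed
#'
#' One master seed spawns per-stage child seeds by fixed, stage-keyed offsets,
#' so each pipeline stage can be regenerated independently and stage order
#' never changes results. Offsets hash the stage name; results stay below
#' 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed master seed (single integer).
#' @param stage character stage name.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 1))
}

#' @importFrom stats is.leaf
#' @keywords internal
"_PACKAGE"

#' @keywords internal
#' @noRd
msg <- function(...) message("[mitoarch] ", sprintf(...))

# Evaluate expr with a local RNG state seeded at `seed` (caller's RNG restored).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
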