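# Internal helpers shared across modules.

# Min-max scale a numeric vector to [0, 1]. A constant vector maps to all 1
# when positive, all 0 otherwise (used for seed labels and score fusion,
# where "everything tied and positive" must remain a live signal).
minmax01 <- function(x) {
  if (!length(x)) return(numeric(0))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep(if (rng[1] > 0) 1 else 0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Competition (minimum) rank on descending score.
rank_desc_min <- function(scores) {
  rank(-scores, ties.method = "min")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restore the caller's RNG state on exit; all seeded operations go through
# this so library code never clobbers the user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
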