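# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; all of the package's stochastic steps route through this so that
# identical inputs give bit-identical outputs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# angle (deg) between two directions, sign-insensitive
direction_angle_deg <- function(u, v) {
  u <- unitize(u); v <- unitize(v)
  rad2deg(acos(min(1, abs(sum(u * v)))))
}
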