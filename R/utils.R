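#' Evaluate an expression under a local RNG seed
#'
#' All generators in this package are pure functions of their inputs and a
#' seed: they set the seed locally and restore the caller's RNG state on
#' exit, so calling a generator never perturbs an enclosing simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rotation matrix about the y axis
#' @param theta_deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_y <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), 0, -sin(th),
           0,       1,  0,
           sin(th), 0,  cos(th)), 3, 3, byrow = TRUE)
}
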