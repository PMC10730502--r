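#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow; returns `-Inf` for an
#' all-`-Inf` input instead of `NaN`.
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return scalar numeric.
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    if (m == -Inf) return(-Inf)
    stop("non-finite values other than -Inf in logSumExp input")
  }
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [0,1], cached per node count.
.glCache <- new.env(parent = emptyenv())

glNodes <- function(n) {
  key <- as.character(n)
  if (is.null(.glCache[[key]])) {
    .glCache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .glCache[[key]]
}

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
withSeed <- function(seed, code) {
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

#' Distribution specification for simulator inputs
#'
#' A small serializable description of a univariate distribution, used for
#' every stochastic input of the cohort simulator.
#'
#' @param kind one of `"fixed"` (point mass at `value`), `"uniform"`
#'   (`min`, `max`), `"beta"` (`shape1`, `shape2`, optional `scale`,
#'   `offset`: draws `offset + scale * Beta(shape1, shape2)`), `"poisson"`
#'   (`lambda`, truncated below at `min`).
#' @param ... the parameters named above.
#' @return a `distSpec` list.
#' @examples
#' distSpec("beta", shape1 = 9.55, shape2 = 1)   # sorted-marrow purity
#' distSpec("poisson", lambda = 113, min = 20)   # WES-like depth
#' @export
distSpec <- function(kind = c("fixed", "uniform", "beta", "poisson"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  spec <- switch(kind,
    fixed   = list(kind = kind, value = p$value),
    uniform = list(kind = kind, min = p$min, max = p$max),
    beta    = list(kind = kind, shape1 = p$shape1, shape2 = p$shape2,
                   scale = if (is.null(p$scale)) 1 else p$scale,
                   offset = if (is.null(p$offset)) 0 else p$offset),
    poisson = list(kind = kind, lambda = p$lambda,
                   min = if (is.null(p$min)) 1 else p$min)
  )
  structure(spec, class = c("distSpec", "list"))
}

drawDist <- function(spec, n) {
  stopifnot(inherits(spec, "distSpec"))
  switch(spec$kind,
    fixed   = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    beta    = spec$offset + spec$scale * stats::rbeta(n, spec$shape1, spec$shape2),
    poisson = pmax(spec$min, stats::rpois(n, spec$lambda))
  )
}

.checkDistSpec <- function(spec, name, lo = -Inf, hi = Inf) {
  if (!inherits(spec, "distSpec"))
    return(sprintf("'%s' must be a distSpec()", name))
  rng <- switch(spec$kind,
    fixed   = c(spec$value, spec$value),
    uniform = c(spec$min, spec$max),
    beta    = c(spec$offset, spec$offset + spec$scale),
    poisson = c(spec$min, Inf)
  )
  if (rng[1] < lo || (is.finite(hi) && rng[2] > hi))
    return(sprintf("'%s' support [%g, %g] outside allowed [%g, %g]",
                   name, rng[1], rng[2], lo, hi))
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
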