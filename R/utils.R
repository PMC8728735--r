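# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All simulators and seeded fits go through this, which is what
# makes them bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Mean-one multiplicative log-normal factors with coefficient of variation cv.
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is_scalar_number(x)) {
    amk_domain_error(sprintf("`%s` must be a single finite number", name))
  }
  bad <- if (open_lower) x <= lower else x < lower
  bad <- bad || if (open_upper) x >= upper else x > upper
  if (bad) {
    amk_domain_error(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}

# 15-point Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch, used by
# the stretched-exponential transform (panel quadrature).
gl15 <- local({
  n <- 15L
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
})
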