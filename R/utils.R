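## Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic content fingerprint for leakage audits: a fixed-format text
## rendering of the numeric content, platform-independent at double precision.
content_hash <- function(x) {
  flat <- function(v) {
    if (is.list(v)) return(paste(vapply(v, flat, character(1)), collapse = "|"))
    paste(format(as.vector(v), digits = 17, trim = TRUE, scientific = TRUE),
          collapse = ",")
  }
  flat(x)
}

## population (divide-by-N) standard deviation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## Moore-Penrose pseudo-inverse via SVD (used for ICA reconstruction checks)
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
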