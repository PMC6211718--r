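# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

# square symmetric numeric matrix check
check_square_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop2(what, " must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop2(what, " must be square")
  if (max(abs(m - t(m))) > tol) stop2(what, " must be symmetric")
  invisible(m)
}

# deterministic seeded evaluation that never leaks RNG state to the caller
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
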