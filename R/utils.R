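# Internal helpers shared across modules.

stop_domain <- function(...) {
  stop(structure(class = c("radnano_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("radnano_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(name, " must be a single positive finite number (got ",
                deparse(substitute(x)), " = ", format(x), ")")
  invisible(x)
}

#' @noRd
#' Log-log linear interpolation on a strictly increasing grid.
#' Out-of-range queries are an error: coefficient tables must cover the
#' spectrum, extrapolating photoabsorption data is never safe.
loglog_interp <- function(x, y, xout) {
  if (any(xout < min(x) | xout > max(x)))
    stop_domain("energy out of tabulated range [", min(x), ", ", max(x), "]")
  exp(stats::approx(log(x), log(y), xout = log(xout), ties = "ordered")$y)
}

# Run an expression with a locally-set RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
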