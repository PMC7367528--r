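#' @keywords internal
"_PACKAGE"

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("liftlight_invalid_input", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) stop_input(name, " must be > ", lower)
  if (!strict_lower && x < lower) stop_input(name, " must be >= ", lower)
  if (x > upper) stop_input(name, " must be <= ", upper)
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators never perturb the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic 31-bit sub-seed from a master seed and integer tags.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (tag in tags) {
    h <- (h * 48271 + as.numeric(tag) + 1) %% 2147483647
  }
  as.integer(h)
}
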