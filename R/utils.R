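#' @keywords internal
"_PACKAGE"

# Validation failures carry condition class "stoichsi_validation_error" so
# callers can distinguish malformed input from programming errors.
stop_validation <- function(msg, class = "stoichsi_validation_error") {
  stop(errorCondition(msg, class = c(class, "stoichsi_error", "error")))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All randomised operations in the package go
# through this, so a master seed pins every draw without clobbering the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic sub-seed derivation: a small integer stream index folded into
# the master seed, kept inside the 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483647L)
}

# Lower median: for even n, the lower of the two middle order statistics.
median_lower <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[ceiling(n / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable small integer derived from a string, so per-gene seed streams do
# not depend on the gene's position in the matrix.
string_index <- function(s) {
  v <- utf8ToInt(s)
  as.integer(sum(v * seq_along(v)) %% 100003L)
}
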