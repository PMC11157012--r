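# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
mr_stop <- function(class, msg, data = NULL) {
  cond <- structure(
    class = c(class, "mr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

# Two-sided normal p, floored at the smallest positive double so the
# (0, 1] invariant survives extreme z-scores.
two_sided_p <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

two_sided_p_t <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
}

ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Evaluate `expr` under a private RNG stream; the caller's .Random.seed is
# untouched. All Monte-Carlo components route through this so seeds are
# explicit and no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    mr_stop("mr_config_error", "a single integer seed is required")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
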