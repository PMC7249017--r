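# internal helpers

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points funnel through this so that results are
# reproducible from their `seed` argument alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

# derive a child seed from a parent seed and a string tag, staying < 2^31
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
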