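# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("'%s' must be a single finite number", name))
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    stop_(sprintf("'%s' = %g is outside the allowed range [%g, %g]%s",
                  name, x, lower, upper, if (strict) " (exclusive)" else ""))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_(sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

# Deterministic per-stage seed fan-out from one global seed. Stage names are
# hashed to an offset so stages can be rerun independently; result kept below
# 2^31 - 1 so it is a valid R integer seed.
stage_seed <- function(seed, stage) {
  cv <- as.numeric(utf8ToInt(stage))
  h <- sum(cv * seq_along(cv) * 2654435) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

hash_obj <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12, force = TRUE), tf)
  unname(tools::md5sum(tf))
}
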