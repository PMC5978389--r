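# Internal helpers: seed management and input validation.

# Stable polynomial string hash mod (2^31 - 1). Used to fan a single global
# seed out to per-stage / per-site seeds so results do not depend on input
# order. Products stay below 2^53, so arithmetic is exact in doubles.
str_hash32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 17
  for (b in bytes) {
    h <- (h * 1159241 + b) %% 2147483647
  }
  h
}

# Derive a child seed (< 2^31) from a parent seed and a label.
derive_seed <- function(seed, label) {
  as.integer((str_hash32(paste0(label, ":", seed)) + seed) %% 2147483647)
}

# Run code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ..., class = "oefish_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stopf("`%s` must be a single number in [%s, %s]", name,
          format(lower), format(upper), class = "oefish_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (x > 0 || !positive) && x >= 0
  if (!ok) {
    stopf("`%s` must be a %s integer", name,
          if (positive) "positive" else "nonnegative",
          class = "oefish_config_error")
  }
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "), class = "oefish_schema_error")
  }
  invisible(df)
}
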