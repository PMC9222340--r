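# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "extrusim_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L) || anyNA(x))
    stopf("`%s` must be a %s numeric value", name,
          if (allow_vector) "non-missing" else "single")
  lo_ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (strict_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok)
    stopf("`%s` must be in %s%g, %g%s (got %s)", name,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]",
          paste(signif(x[!(if (strict_lower) x > lower else x >= lower) |
                          !(if (strict_upper) x < upper else x <= upper)], 4),
                collapse = ", "))
  invisible(x)
}

# "15%" -> 0.15; plain numerics pass through
parse_fraction <- function(x) {
  if (is.numeric(x)) return(x)
  s <- trimws(as.character(x))
  pct <- grepl("%$", s)
  v <- suppressWarnings(as.numeric(sub("%$", "", s)))
  if (anyNA(v)) stopf("cannot parse '%s' as a fraction or percentage", s[is.na(v)][1])
  ifelse(pct, v / 100, v)
}

# Celsius <-> Kelvin conversions are explicit at call sites
celsius_to_kelvin <- function(T_C) T_C + 273.15
kelvin_to_celsius <- function(T_K) T_K - 273.15

# run code with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
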