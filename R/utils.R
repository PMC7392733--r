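# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stopf("%s is missing required column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

TISSUES <- c("brain", "spinal", "other")
ORIENTATIONS <- c("+", "-")
TRANSPOSON_ENDS <- c("5p", "3p", "merged")
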