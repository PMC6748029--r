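# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation code never perturbs the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage substream seeds derived from one root seed.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 214013) %% 2147483629)
}

stop_serumir <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "serumir_error")))
}

assert_columns <- function(df, cols, file = NULL) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    where <- if (is.null(file)) "input table" else file
    stop_serumir("%s is missing required column(s): %s", where,
                 paste(missing, collapse = ", "), class = "serumir_parse_error")
  }
  invisible(df)
}

read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) {
    stop_serumir("file not found: %s", path, class = "serumir_parse_error")
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) {
      stop_serumir("failed to parse %s: %s", path, conditionMessage(e),
                   class = "serumir_parse_error")
    })
  if (!is.null(required)) assert_columns(df, required, file = path)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))
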