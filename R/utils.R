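# Internal helpers: error classes, delimited IO, quadrature node cache.

`%||%` <- function(a, b) if (is.null(a)) b else a

cra_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cra_error", "error", "condition")))
}

stop_validation <- function(msg) cra_error(msg, "cra_validation_error")
stop_missing_input <- function(msg) cra_error(msg, "cra_missing_input_error")
stop_schema <- function(msg) cra_error(msg, "cra_schema_error")

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_validation(msg)
  invisible(TRUE)
}

#' Read a tab-delimited table with a header row
#'
#' @param path file path
#' @return data.frame
#' @keywords internal
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_missing_input(sprintf("input file not found: %s", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fail with the column diff if a table does not match its documented schema.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_schema(sprintf(
      "%s: missing columns [%s]; found [%s]",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Gauss-Legendre reference nodes/weights on [-1, 1], cached by node count.
.quad_cache <- new.env(parent = emptyenv())

gl_reference <- function(n) {
  key <- as.character(n)
  if (is.null(.quad_cache[[key]])) {
    .quad_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .quad_cache[[key]]
}

# Deterministic 31-bit stream seed from a root seed and a parameter name.
# Keeps every intermediate exactly representable in a double.
stream_seed <- function(root_seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 94906249
  as.integer((h * 69069 + as.numeric(root_seed)) %% 2147483629)
}

# Short deterministic hex digest of a character string (used for run logs).
string_digest <- function(x) {
  h <- 0
  for (k in utf8ToInt(paste(x, collapse = "\n"))) h <- (h * 131 + k) %% 94906249
  sprintf("%08x", as.integer(h %% 4294967291))
}

fmt_count <- function(x) round(x)
fmt_rate <- function(x) round(x)
fmt_pct <- function(x) round(x, 1)

# Evaluate an expression with a private RNG state, restoring the caller's.
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
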