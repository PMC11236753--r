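#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx lm coef rnorm runif qnorm pnorm sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_num <- function(x, name, lower = -Inf, upper = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x))
    stopf("'%s' must be numeric without NA", name)
  if (!is.null(len) && length(x) != len)
    stopf("'%s' must have length %d", name, len)
  if (any(x < lower) || any(x > upper))
    stopf("'%s' must be in [%g, %g]", name, lower, upper)
  invisible(x)
}

# path to a packaged fixture file
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "festwin")
  if (!nzchar(p)) stopf("fixture '%s' not found in installed package", file)
  p
}

# parse values printed as fractions ("1/11") or plain numbers
parse_fraction <- function(x) {
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
      parts[1] / parts[2]
    } else as.numeric(s)
  }, numeric(1), USE.NAMES = FALSE)
}

# deterministic per-module seed derivation from a root seed (kept < 2^31)
derive_seed <- function(root, offset) {
  (as.integer(root) + 1000L * as.integer(offset)) %% 2147483587L
}
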