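#' @import data.table
#' @importFrom stats dhyper median p.adjust pgamma plogis pt qgamma qlogis
#'   rbinom rnbinom rnorm runif sd setNames uniroot
#' @importFrom utils head read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (reporting convention used for printed summary
# tables; base round() is half-to-even which disagrees at e.g. x.xx5).
round_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

ed_log <- function(fmt, ...) {
  if (!isTRUE(getOption("epidiff.quiet", FALSE))) {
    message("[epidiff] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

# Run `code` under a fixed RNG state, restoring the caller's stream afterwards.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s: missing required column(s): %s", what, paste(miss, collapse = ", "))
  }
}
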