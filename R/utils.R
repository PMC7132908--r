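#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's random stream. A `NULL` seed evaluates the code unmodified.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed and a stream index to a new 31-bit
#' seed, so independent pipeline stages get independent but reproducible
#' random streams.
#'
#' @param seed master integer seed.
#' @param k non-negative stream index.
#' @return an integer in `[0, 2^31)`.
#' @export
sub_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k))
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807 + 12345) %%
               2147483647)
}

# messaging gated on an option so pipelines can run quietly
sc_log <- function(fmt, ...) {
  if (!isTRUE(getOption("sparsecode.quiet", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

stop_sc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_sc("%s: missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  invisible(TRUE)
}

# full-precision numeric formatting so tables round-trip exactly through text
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}
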