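#' @keywords internal
#' @useDynLib sleepfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All randomness in the package flows through this so that every generator /
# trainer is a pure function of its seed argument.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a master seed; kept strictly below 2^31.
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' MD5 digest of a list of numeric arrays
#'
#' Used to verify the freeze contract during head-only adaptation: the
#' backbone parameters are serialized deterministically and hashed, so
#' "unchanged" is checked bit-for-bit rather than trusted.
#'
#' @param params named list of numeric arrays.
#' @return character scalar, the MD5 hex digest.
#' @export
params_digest <- function(params) {
  stopifnot(is.list(params))
  params <- params[order(names(params))]
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  serialize(params, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

# Shared stage coding: integer labels 0..4 in the order W, N1, N2, N3, REM.
STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Stage label helpers
#'
#' Stages are coded as integers 0..4 in the fixed order W, N1, N2, N3, REM
#' throughout the package.
#'
#' @param x integer labels in 0..4 (for `stage_name`) or stage names
#'   (for `stage_code`).
#' @return character names or integer codes.
#' @export
stage_name <- function(x) {
  stopifnot(all(x %in% 0:4))
  STAGES[x + 1L]
}

#' @rdname stage_name
#' @export
stage_code <- function(x) {
  i <- match(toupper(x), STAGES)
  if (anyNA(i)) stopf("unknown stage name(s): %s", paste(x[is.na(i)], collapse = ", "))
  i - 1L
}

check_labels <- function(labels) {
  if (!all(labels %in% 0:4)) stopf("labels must be integers in 0..4 (W, N1, N2, N3, REM)")
  as.integer(labels)
}
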