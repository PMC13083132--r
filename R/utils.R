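#' Derive a stage seed from a master seed
#'
#' Deterministically fans a single master seed out to independent per-stage
#' seeds so that pipeline stages can be rerun in isolation. The derived value
#' always fits a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483647L)
}

#' @keywords internal
#' @noRd
hash_config <- function(x) {
  # stable content hash without extra dependencies: md5 of a canonical
  # serialization of the (name-sorted) list
  canon <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm)) v <- v[order(nm)]
      lapply(v, canon)
    } else v
  }
  raw <- serialize(canon(x), connection = NULL, version = 2L)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
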