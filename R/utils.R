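# internal helpers shared across stages

#' Derive a stage-specific seed from a global seed
#'
#' Fans a single user-supplied seed out to independent per-stage seeds so each
#' pipeline stage is locally reproducible. The derivation is a fixed integer
#' hash of the stage name folded into the global seed, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[serocell] ", ...)

stop2 <- function(...) stop(..., call. = FALSE)

# column sums that work for both base and Matrix matrices
col_totals <- function(m) {
  if (inherits(m, "Matrix")) Matrix::colSums(m) else colSums(m)
}

row_detect <- function(m) {
  if (inherits(m, "Matrix")) Matrix::rowSums(m > 0) else rowSums(m > 0)
}

col_detect <- function(m) {
  if (inherits(m, "Matrix")) Matrix::colSums(m > 0) else colSums(m > 0)
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}
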