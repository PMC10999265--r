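#' Derive a reproducible stage/species seed from a global seed
#'
#' All randomness in the pipeline flows from one user-supplied seed; stage- and
#' species-local generators use seeds derived by a stable string hash so that
#' per-species work can be reordered (or parallelised) without changing
#' results.
#'
#' @param seed integer global seed.
#' @param ... character/numeric labels identifying the stage (and species).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double-precision ints
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Euclidean distances (km) between rows of two x/y matrices; small n only.
cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

bio_names <- function() paste0("bio", 1:19)
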