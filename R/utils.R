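# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards, so generator
#' functions are reproducible without disturbing the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# argument validation with a uniform error style
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# integer-pixel translation of a matrix (drow rows down, dcol columns
# right), padding the exposed area with `fill`
shift_matrix <- function(m, drow, dcol, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - drow
  src_c <- seq_len(nc) - dcol
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Otsu threshold on an arbitrary-range matrix (EBImage::otsu wants [0, 1])
otsu_threshold <- function(m) {
  rng <- range(m, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  m01 <- (m - rng[1]) / diff(rng)
  EBImage::otsu(m01, range = c(0, 1)) * diff(rng) + rng[1]
}
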