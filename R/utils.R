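## Internal helpers: seeded RNG scopes and input validation.

#' Run code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the default generator, evaluates
#' `expr`, and restores the state so library code never perturbs the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Deterministic substream derivation: mixes a user seed with an integer salt
# into a positive 31-bit seed.  Exact in double arithmetic (< 2^53).
mix_seed <- function(seed, salt) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  m <- (s * 48271 + (as.numeric(salt) %% 65536) * 16807) %% 2147483647
  as.integer(m %/% 1 + 1)
}

stop_input <- function(...) {
  stop(structure(class = c("dsclp_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_input(...)

# Coerce a single image (matrix), an H x W x C array, or an H x W x C x N
# array into the canonical batch layout c(H, W, 1, N).
as_batch <- function(x) {
  if (is.list(x)) {
    pix <- lapply(x, function(s) if (is.list(s)) s$pixels else s)
    H <- nrow(pix[[1]]); W <- ncol(pix[[1]])
    arr <- array(0, c(H, W, 1L, length(pix)))
    for (i in seq_along(pix)) arr[, , 1L, i] <- pix[[i]]
    return(arr)
  }
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) return(array(x, c(dim(as.matrix(x)), 1L, 1L)))
  if (length(d) == 3L) return(array(x, c(d[1], d[2], 1L, d[3])))
  if (length(d) == 4L) return(x)
  stop_input("cannot interpret input of dimension ", length(d), " as an image batch")
}

batch_to_matrix <- function(b, i = 1L) matrix(b[, , 1L, i], dim(b)[1], dim(b)[2])

check_pixels <- function(x, what = "image") {
  assert_that(all(is.finite(x)), what, " contains non-finite intensities")
  assert_that(min(x) >= 0 && max(x) <= 1, what, " intensities must lie in [0, 1]")
  invisible(x)
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

clamp01 <- function(x) pmin(pmax(x, 0), 1)

logistic <- function(x) 1 / (1 + exp(-x))
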