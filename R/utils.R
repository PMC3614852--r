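# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) {
  # keeps dim/names, unlike pmin(1, pmax(0, x)) with scalar first arguments
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, runs `code`, and
#' restores the previous state, so seeded generators never perturb the
#' session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Natural (numeric-aware) ordering of file names
#'
#' Orders `slice_2` before `slice_10`: names are tokenised into digit and
#' non-digit runs and digit runs compare numerically.
#' @param x character vector of names.
#' @return integer permutation ordering `x` naturally.
#' @export
#' @examples
#' natural_order(c("slice_10.png", "slice_2.png"))
natural_order <- function(x) {
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  ntok <- max(lengths(toks), 1L)
  keys <- lapply(seq_len(ntok), function(i) {
    tk <- vapply(toks, function(v) if (length(v) >= i) v[[i]] else "", "")
    num <- suppressWarnings(as.numeric(tk))
    if (all(!is.na(num) | tk == "")) {
      num[tk == ""] <- -Inf
      num
    } else {
      tk
    }
  })
  do.call(order, keys)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0
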