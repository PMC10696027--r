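#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically fans a master seed out into independent sub-seeds for
#' parallel-safe replicate loops (one sub-seed per threshold/replicate
#' pair, per CV iteration, ...). Result is always a valid 32-bit R seed.
#'
#' @param master integer master seed.
#' @param ... integer stream identifiers (indices, replicate numbers).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(as.numeric(master), as.numeric(unlist(list(...))))
  h <- 0
  for (x in ids) h <- (h * 69069 + x * 362437 + 1) %% 2147483647
  as.integer(h)
}

#' Min-max rescale a series to the unit interval
#'
#' Applies `(x - min) / (max - min)` elementwise; a constant series maps to
#' all zeros (degenerate convention). `NA`s are ignored for the range and
#' preserved in the output.
#'
#' @param x numeric vector, length >= 1.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @examples
#' scale_unit(c(2, 4, 6))   # 0.0 0.5 1.0
#' scale_unit(c(5, 5, 5))   # 0 0 0
#' @export
scale_unit <- function(x) {
  stopifnot(length(x) >= 1)
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    out <- rep(0, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
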