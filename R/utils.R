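# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest-remainder apportionment of n items to proportions
#'
#' Deterministically rounds `n * props` to integers summing exactly to `n`,
#' assigning leftover units to the largest fractional remainders.
#'
#' @param n total number of items.
#' @param props numeric vector of proportions summing to 1.
#' @return integer vector, same names as `props`, summing to `n`.
#' @keywords internal
largest_remainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    frac <- raw - base
    # ties broken by position for determinism
    idx <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# row variances of a matrix (unbiased, denominator n-1)
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# stable id padding: g0001, g0002, ...
gene_ids <- function(n, prefix = "g") {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}
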