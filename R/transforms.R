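#' Rank-based inverse normal transform
#'
#' Maps values through `qnorm((rank - 0.5) / n)` using mean ranks for ties
#' (the offset variant `"blom"` uses `(rank - 3/8) / (n + 1/4)`). Missing
#' values are preserved in place. The output is invariant to any monotone
#' transform of the input.
#'
#' @param x Numeric vector with at least 3 non-missing, non-constant values.
#' @param offset `"half"` (default) or `"blom"`.
#' @return Transformed numeric vector.
#' @export
inverse_normal <- function(x, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values")
  if (stats::sd(x[ok]) == 0) stop("cannot transform a constant vector")
  r <- rank(x[ok], ties.method = "average")
  n <- sum(ok)
  q <- if (offset == "half") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
  out <- x
  out[ok] <- stats::qnorm(q)
  out
}

#' Centre predictors and scale numeric ones by two standard deviations
#'
#' Numeric columns become `(x - mean) / (2 sd)` so their coefficients are
#' directly comparable to those of centred (but unscaled) binary
#' predictors; binary columns are centred only.
#'
#' @param x Data frame or matrix of predictors.
#' @param types Character vector (`"numeric"`/`"binary"`), one per column.
#' @return Matrix of standardized predictors (numeric columns end up with
#'   SD 0.5).
#' @export
two_sd_standardize <- function(x, types) {
  x <- as.matrix(x)
  stopifnot(length(types) == ncol(x), all(types %in% c("numeric", "binary")))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    mu <- mean(v, na.rm = TRUE)
    if (types[j] == "numeric") {
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        stop(sprintf("numeric column %d has zero variance", j))
      }
      out[, j] <- (v - mu) / (2 * s)
    } else {
      out[, j] <- v - mu
    }
  }
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`; returns monotone adjusted p-values and
#' rejection flags.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q Target FDR (default 0.05).
#' @return List with `adjusted` and logical `reject` (both empty for empty
#'   input).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}
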