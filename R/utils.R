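# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic child seed (< 2^31) from a global seed and a label.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435761 + h * 7919) %% 2147483629L)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name))
  }
}

# Intersect two sets of half-open intervals on the same chromosome.
# Each argument is a two-column matrix/data.frame of (start, end), 0-based
# half-open, assumed disjoint and sorted. Returns a matrix of (start, end).
intersect_intervals <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  out_s <- numeric(0)
  out_e <- numeric(0)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(cbind(start = out_s, end = out_e))
  }
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1L], b[j, 1L])
    e <- min(a[i, 2L], b[j, 2L])
    if (s < e) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
    }
    if (a[i, 2L] <= b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  cbind(start = out_s, end = out_e)
}

# Merge adjacent/overlapping half-open intervals (start sorted).
merge_adjacent <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  keep_s <- m[1L, 1L]
  keep_e <- m[1L, 2L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (k in seq_len(nrow(m))[-1L]) {
    if (m[k, 1L] <= keep_e) {
      keep_e <- max(keep_e, m[k, 2L])
    } else {
      out_s <- c(out_s, keep_s)
      out_e <- c(out_e, keep_e)
      keep_s <- m[k, 1L]
      keep_e <- m[k, 2L]
    }
  }
  cbind(start = c(out_s, keep_s), end = c(out_e, keep_e))
}
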