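## Sobol' low-discrepancy sequence (Joe & Kuo direction numbers,
## Gray-code construction), used by the Saltelli sampling design.
## Quasi-random points cut the error of the Sobol-index estimators by
## an order of magnitude relative to pseudo-random sampling at the same
## base sample size.
##
## Direction-number table: degree s and primitive-polynomial code a per
## dimension, plus the initial m values, for dimensions 2..21
## (dimension 1 is the van der Corput sequence, all m = 1).  Supports
## up to 21 dimensions, ample for the (2k)-dimensional Saltelli designs
## used here.

JOE_KUO <- list(
  list(s = 1, a = 0,  m = c(1)),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1,  m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 15, 13, 25)),
  list(s = 6, a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(s = 7, a = 1,  m = c(1, 3, 7, 11, 23, 15, 103)),
  list(s = 7, a = 4,  m = c(1, 3, 7, 13, 13, 15, 69)))

SOBOL_BITS <- 30L

## direction vectors v_1..v_nbits for one dimension, as integers
## scaled by 2^SOBOL_BITS
sobol_directions <- function(dim, nbits = SOBOL_BITS) {
  if (dim == 1) {
    return(bitwShiftL(1L, nbits - seq_len(nbits)))
  }
  entry <- JOE_KUO[[dim - 1]]
  s <- entry$s
  a <- entry$a
  m <- as.integer(entry$m)
  if (nbits > s) {
    m <- c(m, integer(nbits - s))
    for (i in (s + 1):nbits) {
      ## m_i = m_{i-s} XOR 2^s m_{i-s} XOR_{t=1..s-1} 2^t a_t m_{i-t}
      val <- bitwXor(m[i - s], bitwShiftL(m[i - s], s))
      for (t in seq_len(s - 1)) {
        a_t <- bitwAnd(bitwShiftR(a, s - 1 - t), 1L)
        if (a_t == 1L)
          val <- bitwXor(val, bitwShiftL(m[i - t], t))
      }
      m[i] <- val
    }
  }
  bitwShiftL(m[seq_len(nbits)], nbits - seq_len(nbits))
}

#' Sobol' low-discrepancy sequence
#'
#' First `n` points (after `skip`) of the Sobol' sequence in `dim`
#' dimensions, Gray-code order, in `[0, 1)^dim`.  The first point of
#' the unskipped sequence is the origin, as in standard
#' implementations.
#'
#' @param n Number of points.
#' @param dim Number of dimensions (1..21).
#' @param skip Points to drop from the start of the sequence
#'   (default 0).
#' @return An `n` x `dim` matrix.
#' @export
sobol_sequence <- function(n, dim, skip = 0) {
  stopifnot(n >= 1, dim >= 1, dim <= length(JOE_KUO) + 1, skip >= 0)
  nbits <- SOBOL_BITS
  V <- vapply(seq_len(dim), sobol_directions, integer(nbits))
  denom <- 2^nbits
  out <- matrix(0, n, dim)
  x <- integer(dim)
  total <- n + skip
  for (i in seq_len(total)) {
    if (i > 1) {
      ## c = index (1-based) of lowest zero bit of i - 2
      j <- i - 2
      c <- 1L
      while (bitwAnd(j, 1L) == 1L) {
        j <- bitwShiftR(j, 1L)
        c <- c + 1L
      }
      x <- bitwXor(x, V[c, ])
    }
    if (i > skip) out[i - skip, ] <- x / denom
  }
  out
}
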