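# Minimal periodized orthogonal discrete wavelet transform.
#
# Only what the motion-correction stage needs: a Daubechies-5 analysis /
# synthesis pair with periodic boundary handling, exact perfect
# reconstruction, and per-level access to detail coefficients. Signal
# lengths are padded internally to a multiple of 2^levels by reflection.

# Daubechies-5 (10-tap) scaling filter, unit energy.
.db5_lo <- c(0.0033357252854737712, -0.012580751999081999,
             -0.006241490212798274, 0.07757149384004572,
             -0.032244869584638375, -0.24229488706638203,
             0.13842814590132074, 0.7243085284377729,
             0.6038292697971896, 0.16010239797419293)

.db5_hi <- local({
  L <- length(.db5_lo)
  (-1)^(0:(L - 1)) * rev(.db5_lo)
})

# One analysis step on an even-length vector (periodic).
.dwt_step <- function(x, lo = .db5_lo, hi = .db5_hi) {
  N <- length(x)
  K <- N %/% 2L
  L <- length(lo)
  idx <- (outer(2L * (seq_len(K) - 1L), 0:(L - 1L), `+`)) %% N + 1L
  X <- matrix(x[idx], K, L)
  list(approx = drop(X %*% lo), detail = drop(X %*% hi))
}

# One synthesis step (adjoint of the orthogonal analysis map).
.idwt_step <- function(approx, detail, lo = .db5_lo, hi = .db5_hi) {
  K <- length(approx)
  N <- 2L * K
  L <- length(lo)
  x <- numeric(N)
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_len(L)) {
    pos <- (base + (m - 1L)) %% N + 1L
    contrib <- lo[m] * approx + hi[m] * detail
    # pos may repeat when filters wrap; accumulate safely
    acc <- rowsum(contrib, pos)
    x[as.integer(rownames(acc))] <- x[as.integer(rownames(acc))] + acc[, 1]
  }
  x
}

#' Periodized Daubechies-5 wavelet decomposition
#'
#' @param x numeric vector; padded internally by reflection to a multiple
#'   of `2^levels`.
#' @param levels decomposition depth (default 4).
#' @return list with `approx` (coarsest approximation), `details` (list of
#'   detail coefficient vectors, finest first), and padding bookkeeping.
#' @export
dwt_periodic <- function(x, levels = 4L) {
  n0 <- length(x)
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  if (pad > 0) {
    # reflect the tail; for very short signals recycle
    tail_ref <- rev(x)[seq_len(min(pad, n0))]
    while (length(tail_ref) < pad) tail_ref <- c(tail_ref, rev(tail_ref))
    x <- c(x, tail_ref[seq_len(pad)])
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details, n = n0, pad = pad, levels = levels)
}

#' Inverse of [dwt_periodic()]
#' @param w decomposition as returned by [dwt_periodic()].
#' @return numeric vector of the original length.
#' @export
idwt_periodic <- function(w) {
  a <- w$approx
  for (j in rev(seq_len(w$levels)))
    a <- .idwt_step(a, w$details[[j]])
  a[seq_len(w$n)]
}

# Zero detail coefficients lying beyond iqr_factor * IQR from the
# quartiles, per level. iqr_factor = Inf disables thresholding (pure
# perfect-reconstruction pass-through).
wavelet_despike <- function(x, levels = 4L, iqr_factor = 1.5) {
  if (length(x) < 2^levels * 2L) return(x)
  w <- dwt_periodic(x, levels)
  if (is.finite(iqr_factor)) {
    for (j in seq_len(levels)) {
      d <- w$details[[j]]
      q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - iqr_factor * iqr
      hi <- q[2] + iqr_factor * iqr
      out <- d < lo | d > hi
      d[out] <- 0
      w$details[[j]] <- d
    }
  }
  idwt_periodic(w)
}
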