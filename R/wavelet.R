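# Separable 2D discrete wavelet transform with periodized boundaries, used
# by denoise_map(). Symlet-4 (least-asymmetric, 8 taps) analysis/synthesis
# filter banks; coefficient values are the standard published ones.

.sym4_dec_lo <- c(
  -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
  0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
  -0.012603967262037833, 0.0322231006040427
)
.sym4_dec_hi <- c(
  -0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
  0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
  0.02963552764599851, -0.07576571478927333
)
# One analysis level along columns, periodized:
#   c[n] = sum_k h[k] x[(2(n-1) + k - 1) mod N + 1].
# The analysis operator rows are orthonormal (QMF pair), so synthesis is
# its transpose and reconstruction is exact for even N.
.dwt_cols <- function(x) {
  n <- nrow(x); half <- n %/% 2L; L <- length(.sym4_dec_lo)
  lo <- matrix(0, half, ncol(x)); hi <- lo
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(L)) {
    idx <- ((base + k - 1L) %% n) + 1L
    xs <- x[idx, , drop = FALSE]
    lo <- lo + .sym4_dec_lo[k] * xs
    hi <- hi + .sym4_dec_hi[k] * xs
  }
  list(lo = lo, hi = hi)
}

# transpose (adjoint) of .dwt_cols
.idwt_cols <- function(lo, hi) {
  half <- nrow(lo); n <- 2L * half; L <- length(.sym4_dec_lo)
  out <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(L)) {
    idx <- ((base + k - 1L) %% n) + 1L
    out[idx, ] <- out[idx, ] + .sym4_dec_lo[k] * lo + .sym4_dec_hi[k] * hi
  }
  out
}

# full separable 2D DWT, `levels` deep; input dims must be multiples of
# 2^levels. Returns list(approx, details = list of list(lh, hl, hh)).
.dwt2 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    cb <- .dwt_cols(a)
    ll <- t(.dwt_cols(t(cb$lo))$lo); lh <- t(.dwt_cols(t(cb$lo))$hi)
    hl <- t(.dwt_cols(t(cb$hi))$lo); hh <- t(.dwt_cols(t(cb$hi))$hi)
    details[[l]] <- list(lh = lh, hl = hl, hh = hh)
    a <- ll
  }
  list(approx = a, details = details)
}

.idwt2 <- function(w) {
  a <- w$approx
  for (l in rev(seq_along(w$details))) {
    d <- w$details[[l]]
    lo <- t(.idwt_cols(t(a), t(d$lh)))
    hi <- t(.idwt_cols(t(d$hl), t(d$hh)))
    a <- .idwt_cols(lo, hi)
  }
  a
}

# pad a matrix (symmetric reflection) so both dims are multiples of 2^levels
.pad_dyadic <- function(x, levels) {
  m <- 2^levels
  pr <- (m - nrow(x) %% m) %% m
  pc <- (m - ncol(x) %% m) %% m
  if (pr > 0) x <- rbind(x, x[nrow(x):(nrow(x) - pr + 1L), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, ncol(x):(ncol(x) - pc + 1L), drop = FALSE])
  list(x = x, pr = pr, pc = pc)
}

# sym4 soft-threshold denoising: universal threshold scaled by `strength`,
# noise sigma estimated from the finest diagonal subband (MAD / 0.6745)
.wavelet_denoise <- function(x, levels = 3L, strength = 1) {
  pad <- .pad_dyadic(x, levels)
  w <- .dwt2(pad$x, levels)
  # stats::mad already applies the 1/0.6745 consistency factor
  sigma <- mad(as.vector(w$details[[1]]$hh), center = 0)
  thr <- strength * sigma * sqrt(2 * log(length(pad$x)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  w$details <- lapply(w$details, function(d) lapply(d, soft))
  out <- .idwt2(w)
  out[seq_len(nrow(x)), seq_len(ncol(x)), drop = FALSE]
}
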