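# Internal numerical utilities shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls never perturb a caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Derive a child seed from a parent seed and a stream label, keeping the
## result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

#' Wrap angles into (-pi, pi]
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to the principal interval.
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi)
  # %% maps exact multiples of 2*pi to 0; keep the upper boundary closed
  y[y == 0] <- 2 * pi
  y - pi
}

#' Circular mean of a sample of angles
#' @param x Angles in radians.
#' @return Mean direction in (-pi, pi]; `NA` for an empty sample or zero
#'   resultant.
#' @export
circ_mean <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  s <- sum(exp(1i * x))
  if (Mod(s) < .Machine$double.eps * length(x)) return(NA_real_)
  Arg(s)
}

## Mean resultant length.
circ_r <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  Mod(mean(exp(1i * x)))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Real-valued vector (one channel) or matrix (channels in rows).
#' @return Complex vector/matrix whose real part is `x` and whose imaginary
#'   part is the Hilbert transform of `x`.
#' @export
analytic_signal <- function(x) {
  one_channel <- function(v) {
    n_orig <- length(v)
    # pad to a highly composite length (R's FFT is O(n^2) for prime n),
    # reflecting the tail to limit edge leakage, then truncate
    m <- stats::nextn(n_orig, c(2, 3, 5))
    if (m > n_orig) {
      pad <- m - n_orig
      tail_ref <- v[n_orig - seq_len(min(pad, n_orig - 1L)) + 0L]
      if (length(tail_ref) < pad) {
        tail_ref <- rep(tail_ref, length.out = pad)
      }
      v <- c(v, tail_ref)
    }
    n <- length(v)
    f <- stats::fft(v)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[c(1, n / 2 + 1)] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1
      h[2:((n + 1) / 2)] <- 2
    }
    (stats::fft(f * h, inverse = TRUE) / n)[seq_len(n_orig)]
  }
  if (is.matrix(x)) {
    t(apply(x, 1L, one_channel))
  } else {
    one_channel(x)
  }
}

## Symmetric Hann window (periodic = FALSE), unit peak.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the eigendecomposition of the symmetric tridiagonal
#' matrix whose eigenvectors are the Slepian sequences. Tapers are scaled to
#' unit energy and oriented so each taper's mean (first taper) or leading
#' lobe is non-negative.
#'
#' @param n Taper length in samples.
#' @param k Number of tapers.
#' @param nw Time-bandwidth product (default 4, supporting up to 7 tapers).
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, k = 7L, nw = 4) {
  stopifnot(n >= 2L, k >= 1L, k <= n)
  if (k > 2 * nw - 1 + 1e-9) {
    warning("requesting more tapers than 2*nw - 1; trailing tapers are poorly concentrated")
  }
  w <- nw / n
  tt <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  diag_off <- (tt[-1] * (n - tt[-1])) / 2
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), seq_len(n))] <- diag_main
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- diag_off
  m[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- diag_off
  e <- eigen(m, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0 || (abs(sum(tap[, j])) < 1e-12 && tap[2, j] < 0)) {
      tap[, j] <- -tap[, j]
    }
  }
  tap
}

## Ratio I1(kappa)/I0(kappa), computed with exponentially scaled Bessel
## functions so large kappa does not overflow.
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Expected pairwise phase consistency of a von Mises phase sample
#'
#' For spike phases drawn from a von Mises distribution with concentration
#' `kappa`, the population PPC equals the squared mean resultant
#' `(I1(kappa)/I0(kappa))^2`.
#'
#' @param kappa Non-negative concentration parameter(s).
#' @return Expected PPC value(s) in `[0, 1)`.
#' @export
ppc_expected_vonmises <- function(kappa) {
  stopifnot(all(kappa >= 0))
  bessel_ratio(kappa)^2
}

## Invert R = I1(kappa)/I0(kappa) for kappa (maximum-likelihood von Mises
## concentration). Standard piecewise seed + Newton refinement.
vm_kappa_from_r <- function(r, kappa_max = 1e3) {
  if (!is.finite(r) || r <= 0) return(0)
  if (r >= 1) return(kappa_max)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  k <- min(max(k, 1e-8), kappa_max)
  for (i in 1:25) {
    a <- bessel_ratio(k)
    # d/dk A(k) = 1 - A/k - A^2
    da <- 1 - a / k - a^2
    if (!is.finite(da) || abs(da) < 1e-14) break
    step <- (a - r) / da
    k <- k - step
    if (!is.finite(k) || k <= 0) {
      k <- 1e-8
      break
    }
    if (k > kappa_max) {
      k <- kappa_max
      break
    }
    if (abs(step) < 1e-12 * (1 + k)) break
  }
  k
}

## Draw n angles from a von Mises distribution (Best-Fisher rejection
## sampler); mu in radians, kappa >= 0. Uses the current RNG stream.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-9) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk > 0) {
      out[got + seq_len(nk)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + nk
    }
  }
  wrap_phase(mu + out)
}

## Gaussian-kernel smoothing with reflected-edge padding; kernel length in
## samples (truncated support), sd in samples.
gauss_smooth <- function(x, len, sd) {
  len <- max(1L, as.integer(len))
  if (len %% 2 == 0L) len <- len + 1L
  half <- (len - 1L) / 2L
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  pad <- min(half, n - 1L)
  xp <- c(x[pad:1], x, x[n:(n - pad + 1L)])
  if (pad < half) { # very short traces: extend by repetition
    xp <- c(rep(xp[1], half - pad), xp, rep(xp[length(xp)], half - pad))
  }
  y <- stats::convolve(xp, rev(k), type = "filter")
  # convolve(type = "filter") returns length(xp) - len + 1 centred samples
  y[seq_len(n)]
}
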