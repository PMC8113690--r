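# Circular and numerical helpers shared across the package.

#' Wrap angles into (-pi, pi]
#'
#' @param x Angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps exact odd multiples of pi to -pi; convention here is (-pi, pi]
  w[w <= -pi + .Machine$double.eps * 4 & abs(w + pi) < 1e-12] <- pi
  w
}

#' Circular distance between two angles
#'
#' @param a,b Angles in radians.
#' @return Absolute angular separation in \[0, pi\].
#' @export
circ_dist <- function(a, b) {
  abs(wrap_phase(a - b))
}

# Mean resultant length of a von Mises distribution, A(kappa) = I1/I0.
# besselI overflows for large kappa; use exponentially scaled ratios.
vm_resultant <- function(kappa) {
  ifelse(kappa <= 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Von Mises concentration for a target mean resultant length
#'
#' Inverts the mean-resultant-length function A(kappa) = I1(kappa)/I0(kappa),
#' which links the concentration of segmentwise phase jitter to the
#' normalized phase coherence the jitter produces in the large-sample limit.
#'
#' @param r Target mean resultant length in \[0, 1\].
#' @return Concentration parameter kappa (Inf for r = 1, 0 for r = 0).
#' @examples
#' vm_kappa(0.6)
#' vm_resultant_of <- function(k) besselI(k, 1) / besselI(k, 0)
#' vm_resultant_of(vm_kappa(0.6)) # ~0.6
#' @export
vm_kappa <- function(r) {
  stopifnot(all(r >= 0 & r <= 1))
  vapply(r, function(ri) {
    if (ri == 0) return(0)
    if (ri >= 1 - 1e-12) return(Inf)
    # asymptotic branches: A(k) ~ k/2 near 0, A(k) ~ 1 - 1/(2k) near 1
    if (ri < 1e-6) return(2 * ri)
    if (ri > 1 - 1e-4) return(1 / (2 * (1 - ri)))
    stats::uniroot(function(k) vm_resultant(k) - ri,
                   interval = c(1e-8, 1e4), tol = 1e-10)$root
  }, numeric(1))
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler. Used for the per-segment phase jitter of
#' the synthetic EEG generator; no installed package provides the sampler.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0; 0 is circular uniform, Inf degenerate).
#' @return n angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_phase(mu), n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_phase(out + mu)
}

# 1/f^alpha ("pink" for alpha = 1) Gaussian noise via spectral shaping.
# Returns a zero-mean series of length n scaled to unit standard deviation.
pink_noise <- function(n, alpha = 1) {
  stopifnot(n >= 2)
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(full[nf + 1]), imaginary = 0)
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Derive a stage seed from a master seed; keeps results < 2^31 so they are
# valid R integers.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 1009 + 1) %%
               2147483647)
}
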