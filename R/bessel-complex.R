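# Bessel functions of the first kind at complex argument.
#
# The Womersley solution needs J0 and J1 evaluated at Lambda_n = alpha
# sqrt(n) i^(3/2), which lies on the ray arg(z) = 3*pi/4.  Base R's besselJ
# is real-only, so J0/J1 are computed here by Miller's downward recurrence,
# normalised with the Jacobi-Anger identity
#   e^(-iz) = J0(z) + 2 * sum_k (-i)^k Jk(z)        (Im z >= 0)
#   e^(+iz) = J0(z) + 2 * sum_k (+i)^k Jk(z)        (Im z <  0)
# chosen so the normalising sum has the same magnitude as its largest term
# (the classical even-order sum cancels catastrophically off the real axis).
# For |Im z| beyond the double-precision overflow horizon only the ratios
# J1(z)/J0(z) and J0(zs)/J0(z) are representable; those switch to Hankel
# asymptotic expansions.

# largest |Im z| for which J0 ~ e^|Im z| stays inside double range,
# with margin for the recurrence's intermediate values
.bessel_im_max <- 600

#' @noRd
besselj01 <- function(z) {
  stopifnot(length(z) == 1L)
  z <- as.complex(z)
  if (!is.finite(Re(z)) || !is.finite(Im(z))) {
    stop("besselj01: non-finite argument", call. = FALSE)
  }
  if (abs(Im(z)) > .bessel_im_max) {
    stop("besselj01: |Im(z)| too large for direct evaluation; use ratio forms",
         call. = FALSE)
  }
  if (abs(z) < 1e-12) {
    # two-term series; |z|^2 < 1e-24 terms are below double precision
    return(list(j0 = 1 - z^2 / 4, j1 = z / 2 - z^3 / 16))
  }
  az <- abs(z)
  m <- ceiling(1.25 * az + 18 * az^(1 / 3) + 20)
  m <- as.integer(m + (m %% 2L))          # even start order
  # downward recurrence f_{k-1} = (2k/z) f_k - f_{k+1}
  fp1 <- 0 + 0i                            # f_{m+1}
  f <- 1e-280 + 0i                         # f_m (arbitrary seed)
  w <- if (Im(z) >= 0) -1i else 1i         # phase weight in normalisation
  s <- 0 + 0i                              # sum of w^k f_k, k = m .. 1
  j1u <- 0 + 0i
  wk <- w^m
  for (k in seq.int(m, 1L)) {
    fm1 <- (2 * k / z) * f - fp1
    s <- s + wk * f
    if (k == 1L) j1u <- f
    fp1 <- f
    f <- fm1
    wk <- wk / w
    if (Mod(f) > 1e250) {                  # rescale to avoid overflow
      f <- f * 1e-250
      fp1 <- fp1 * 1e-250
      s <- s * 1e-250
      j1u <- j1u * 1e-250
    }
  }
  norm <- f + 2 * s                        # = c * e^(-i w_sign z)
  scale <- if (Im(z) >= 0) exp(-1i * z) else exp(1i * z)
  cc <- norm / scale
  list(j0 = f / cc, j1 = j1u / cc)
}

# Hankel asymptotic P/Q series coefficients (order 0 and 1)
.hankel_pq <- function(nu, z) {
  mu <- 4 * nu^2
  a1 <- (mu - 1) / 8
  a2 <- (mu - 1) * (mu - 9) / (2 * 64)
  a3 <- (mu - 1) * (mu - 9) * (mu - 25) / (6 * 512)
  a4 <- (mu - 1) * (mu - 9) * (mu - 25) * (mu - 49) / (24 * 4096)
  p <- 1 - a2 / z^2 + a4 / z^4
  q <- a1 / z - a3 / z^3
  list(p = p, q = q)
}

#' Ratio J1(z)/J0(z) at complex argument
#' @noRd
besselj1_over_j0 <- function(z) {
  z <- as.complex(z)
  if (abs(Im(z)) <= .bessel_im_max) {
    j <- besselj01(z)
    if (Mod(j$j0) < 1e-300) {
      stop("besselj1_over_j0: J0(z) vanishes to double precision", call. = FALSE)
    }
    return(j$j1 / j$j0)
  }
  # half-plane asymptotics: J_nu ~ sqrt(2/(pi z)) (P -+ iQ) e^(-+ i chi)/2
  pq0 <- .hankel_pq(0, z)
  pq1 <- .hankel_pq(1, z)
  if (Im(z) >= 0) {
    1i * (pq1$p - 1i * pq1$q) / (pq0$p - 1i * pq0$q)
  } else {
    -1i * (pq1$p + 1i * pq1$q) / (pq0$p + 1i * pq0$q)
  }
}

# log J0(z) in the large-|Im z| half-plane approximation
.log_j0_asym <- function(z) {
  pq <- .hankel_pq(0, z)
  chi <- z - pi / 4
  if (Im(z) >= 0) {
    0.5 * log(2 / (pi * z)) - log(2) + log(pq$p - 1i * pq$q) - 1i * chi
  } else {
    0.5 * log(2 / (pi * z)) - log(2) + log(pq$p + 1i * pq$q) + 1i * chi
  }
}

#' Ratio J0(z*s)/J0(z) for s in [0, 1], vectorised over s
#' @noRd
besselj0_ratio <- function(z, s) {
  z <- as.complex(z)
  stopifnot(all(s >= -1e-12), all(s <= 1 + 1e-12))
  s <- pmin(pmax(s, 0), 1)
  if (abs(Im(z)) <= .bessel_im_max) {
    j0z <- besselj01(z)$j0
    if (Mod(j0z) < 1e-300) {
      stop("besselj0_ratio: J0(z) vanishes to double precision", call. = FALSE)
    }
    num <- vapply(s, function(si) besselj01(z * si)$j0, complex(1))
    return(num / j0z)
  }
  lj0 <- .log_j0_asym(z)
  vapply(s, function(si) {
    zi <- z * si
    if (abs(Im(zi)) <= .bessel_im_max) {
      lnum <- log(besselj01(zi)$j0)
    } else {
      lnum <- .log_j0_asym(zi)
    }
    d <- lnum - lj0
    if (Re(d) < -700) 0 + 0i else exp(d)   # underflow: true ratio ~ e^{-Im z (1-s)}
  }, complex(1))
}
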