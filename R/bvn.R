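# Vectorized bivariate standard normal CDF (Drezner-Wesolowsky as refined by
# Genz), accurate to ~1e-15. Vectorization over the (h, k) limits matters here:
# every pairwise-likelihood evaluation touches all genotype x phenotype
# threshold corners at once.

# Gauss-Legendre half-interval nodes/weights, selected by |rho|
.gl <- list(
  lo = list(
    w = c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
    x = c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)
  ),
  mid = list(
    w = c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
          0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
    x = c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
          0.5873179542866171, 0.3678314989981802, 0.1252334085114692)
  ),
  hi = list(
    w = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
          0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
          0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
          0.1527533871307259),
    x = c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
          0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
          0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
          0.07652652113349734)
  )
)

# Pr(X <= h, Y <= k) for standard bivariate normal with correlation rho,
# finite h, k, scalar rho with |rho| < 0.925: quadrature over sin(asin(rho)).
.pbvn_mod <- function(h, k, rho) {
  gl <- if (abs(rho) < 0.3) .gl$lo else if (abs(rho) < 0.75) .gl$mid else .gl$hi
  hk <- h * k
  hs <- (h * h + k * k) / 2
  asr <- asin(rho)
  acc <- 0
  for (i in seq_along(gl$x)) {
    for (s in c(-1, 1)) {
      sn <- sin(asr * (s * gl$x[i] + 1) / 2)
      acc <- acc + gl$w[i] * exp((sn * hk - hs) / (1 - sn * sn))
    }
  }
  acc * asr / (4 * pi) + stats::pnorm(h) * stats::pnorm(k)
}

# |rho| >= 0.925 branch (Genz): works on the upper tail of (-h, -k).
.pbvn_high <- function(h, k, rho) {
  gl <- .gl$hi
  # upper-tail variables: P(X <= h, Y <= k) = P(X' > -h, Y' > -k)
  dh <- -h
  dk <- -k
  hk <- dh * dk
  bvn <- 0
  if (rho < 0) {
    dk <- -dk
    hk <- -hk
  }
  if (abs(rho) < 1) {
    as_ <- (1 - rho) * (1 + rho)
    a <- sqrt(as_)
    bs <- (dh - dk)^2
    cc <- (4 - hk) / 8
    d <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    if (asr > -100) {
      bvn <- a * exp(asr) *
        (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_ * as_ / 5)
    }
    if (-hk < 100) {
      b <- sqrt(bs)
      sp <- sqrt(2 * pi) * stats::pnorm(-b / a)
      bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3)
    }
    a2 <- a / 2
    for (i in seq_along(gl$x)) {
      for (s in c(-1, 1)) {
        xs <- (a2 * (s * gl$x[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr <- -(bs / xs + hk) / 2
        if (asr > -100) {
          sp <- 1 + cc * xs * (1 + d * xs)
          ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
          bvn <- bvn + a2 * gl$w[i] * exp(asr) * (ep - sp)
        }
      }
    }
    bvn <- -bvn / (2 * pi)
  }
  if (rho > 0) {
    bvn <- bvn + stats::pnorm(-max(dh, dk))
  } else {
    bvn <- -bvn
    if (dk > dh) bvn <- bvn + stats::pnorm(dk) - stats::pnorm(dh)
  }
  bvn
}

#' Bivariate standard normal distribution function
#'
#' `pbvn()` evaluates \eqn{\Phi_2(h, k; \rho) = \Pr(X \le h, Y \le k)} for a
#' standard bivariate normal vector with correlation \eqn{\rho}, vectorized
#' over `h` and `k` (recycled against each other); `rho` must be a single
#' value in \eqn{(-1, 1)}. Infinite limits are allowed.
#'
#' The moderate-correlation branch integrates the tent-transformed density
#' with Gauss-Legendre quadrature; for \eqn{|\rho| \ge 0.925} an asymptotic
#' expansion around \eqn{|\rho| = 1} is used. Absolute accuracy is around
#' 1e-15.
#'
#' @param h,k Numeric vectors of upper limits (may contain `-Inf`/`Inf`).
#' @param rho Scalar latent correlation, `|rho| < 1`.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' pbvn(0, 0, 0.5) # 1/4 + asin(0.5)/(2*pi) = 1/3
#' @export
pbvn <- function(h, k, rho) {
  if (length(rho) != 1L || is.na(rho) || abs(rho) >= 1) {
    stop("`rho` must be a single value with |rho| < 1", call. = FALSE)
  }
  nn <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), nn)
  k <- rep_len(as.numeric(k), nn)
  out <- numeric(nn)
  # infinite limits reduce to univariate margins
  lo <- h == -Inf | k == -Inf
  hi_h <- !lo & h == Inf
  hi_k <- !lo & k == Inf & !hi_h
  out[lo] <- 0
  out[hi_h] <- stats::pnorm(k[hi_h])
  out[hi_k] <- stats::pnorm(h[hi_k])
  fin <- !(lo | hi_h | hi_k)
  if (any(fin)) {
    hf <- h[fin]
    kf <- k[fin]
    if (abs(rho) < 0.925) {
      out[fin] <- .pbvn_mod(hf, kf, rho)
    } else {
      out[fin] <- vapply(seq_along(hf),
                         function(i) .pbvn_high(hf[i], kf[i], rho),
                         numeric(1))
    }
  }
  pmin(1, pmax(0, out))
}

#' Bivariate standard normal density
#'
#' \eqn{\phi_2(h, k; \rho)}, vectorized over `h` and `k`. By Plackett's
#' identity this is also \eqn{\partial \Phi_2(h, k; \rho) / \partial \rho},
#' which the score of the pairwise likelihood uses at rectangle corners.
#' Infinite coordinates give density 0.
#'
#' @inheritParams pbvn
#' @return Numeric vector of densities.
#' @export
dbvn <- function(h, k, rho) {
  nn <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), nn)
  k <- rep_len(as.numeric(k), nn)
  out <- numeric(nn)
  fin <- is.finite(h) & is.finite(k)
  om <- 1 - rho^2
  out[fin] <- exp(-(h[fin]^2 - 2 * rho * h[fin] * k[fin] + k[fin]^2) /
                    (2 * om)) / (2 * pi * sqrt(om))
  out
}

#' Bivariate normal rectangle probability
#'
#' Probability that a standard bivariate normal vector with correlation `rho`
#' falls in the rectangle `(lower1, upper1] x (lower2, upper2]`, computed by
#' four-corner inclusion-exclusion of [pbvn()]. Sentinel bounds
#' `-Inf`/`Inf` are allowed; vectorized over the limits.
#'
#' @param lower1,upper1,lower2,upper2 Rectangle limits (extended reals).
#' @inheritParams pbvn
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' bvn_rect_prob(-Inf, 0, -Inf, 0, rho = 0) # 0.25
#' @export
bvn_rect_prob <- function(lower1, upper1, lower2, upper2, rho) {
  if (any(lower1 >= upper1) || any(lower2 >= upper2)) {
    stop("rectangle limits must satisfy lower < upper on both axes",
         call. = FALSE)
  }
  p <- pbvn(upper1, upper2, rho) - pbvn(lower1, upper2, rho) -
    pbvn(upper1, lower2, rho) + pbvn(lower1, lower2, rho)
  pmin(1, pmax(0, p))
}
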