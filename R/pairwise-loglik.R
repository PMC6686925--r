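# Pairwise log-likelihood building blocks of the latent model. Thresholds
# and the covariate covariance are plug-in estimates treated as fixed; the
# free parameters are delta0 = (delta12, zeta1, zeta2).

#' Dependence parameters of the latent model
#'
#' The parameter vector the estimating equation solves for:
#' `delta12`, the latent genotype-phenotype correlation, and `zeta1`,
#' `zeta2`, the latent correlations of genotype and phenotype with the
#' covariates. Feasibility requires `|delta12| < 1` and positive conditional
#' variances `1 - zeta' solve(delta22) zeta > 0` for both zeta vectors.
#'
#' @param delta12 Scalar in (-1, 1).
#' @param zeta1,zeta2 Numeric vectors of length equal to the number of
#'   covariates (may be length 0 for the covariate-free escape hatch).
#' @param cov22 Optional [estimate_cov22()] result; when supplied the
#'   conditional-variance feasibility conditions are checked.
#' @return A list of class `dependence_params`.
#' @export
dependence_params <- function(delta12, zeta1 = numeric(0),
                              zeta2 = numeric(0), cov22 = NULL) {
  if (abs(delta12) >= 1) stop("|delta12| must be < 1", call. = FALSE)
  if (length(zeta1) != length(zeta2)) {
    stop("zeta1 and zeta2 must have the same length", call. = FALSE)
  }
  if (!is.null(cov22) && length(zeta1)) {
    M <- cov22$inverse
    if (1 - drop(crossprod(zeta1, M %*% zeta1)) <= 0 ||
        1 - drop(crossprod(zeta2, M %*% zeta2)) <= 0) {
      stop("invalid dependence parameters: conditional variance <= 0",
           call. = FALSE)
    }
  }
  structure(list(delta12 = delta12, zeta1 = as.numeric(zeta1),
                 zeta2 = as.numeric(zeta2)),
            class = "dependence_params")
}

# flatten / unflatten between the class and the optimizer's vector
.dp_to_vec <- function(dp) c(dp$delta12, dp$zeta1, dp$zeta2)
.vec_to_dp <- function(par, q) {
  list(delta12 = par[1],
       zeta1 = if (q) par[2:(q + 1)] else numeric(0),
       zeta2 = if (q) par[(q + 2):(2 * q + 1)] else numeric(0))
}

.extend <- function(cuts) c(-Inf, cuts, Inf)

# genotype x phenotype cell probabilities under latent correlation delta12
.cell_probs_gy <- function(xi, eta, delta12) {
  xe <- .extend(xi)
  ye <- .extend(eta)
  C <- matrix(pbvn(rep(xe, times = length(ye)),
                   rep(ye, each = length(xe)), delta12),
              nrow = length(xe))
  C[-1, -1, drop = FALSE] - C[-nrow(C), -1, drop = FALSE] -
    C[-1, -ncol(C), drop = FALSE] + C[-nrow(C), -ncol(C), drop = FALSE]
}

# d/d(delta12) of the cell probabilities (Plackett: corner densities)
.cell_dprobs_gy <- function(xi, eta, delta12) {
  xe <- .extend(xi)
  ye <- .extend(eta)
  D <- matrix(dbvn(rep(xe, times = length(ye)),
                   rep(ye, each = length(xe)), delta12),
              nrow = length(xe))
  D[-1, -1, drop = FALSE] - D[-nrow(D), -1, drop = FALSE] -
    D[-1, -ncol(D), drop = FALSE] + D[-nrow(D), -ncol(D), drop = FALSE]
}

#' Per-subject log-likelihood of the (genotype, phenotype) pair
#'
#' Log of the bivariate-normal rectangle probability of each subject's
#' (g, y) cell under latent correlation `delta12`, with genotype cut-points
#' `xi` and phenotype cut-points `eta`. Vectorized over subjects.
#'
#' @param g Integer vector of 0-based genotype codes (0..J-1).
#' @param y Integer vector of phenotype levels (1..m).
#' @param xi,eta Threshold vectors from [estimate_thresholds()].
#' @param delta12 Latent correlation in (-1, 1).
#' @return Numeric vector of per-subject log-likelihood contributions.
#' @export
loglik_gy <- function(g, y, xi, eta, delta12) {
  P <- .cell_probs_gy(xi, eta, delta12)
  idx <- cbind(g + 1L, y)
  pv <- P[idx]
  if (any(pv < 1e-300)) {
    bad <- which(pv < 1e-300)[1]
    stop(sprintf("zero-probability cell (g = %d, y = %d)", g[bad], y[bad]),
         call. = FALSE)
  }
  log(pv)
}

# conditional mean coefficients and sd of one latent coordinate given Z
.cond_moments <- function(zeta, cov22) {
  Mz <- drop(cov22$inverse %*% zeta)
  s2 <- 1 - sum(zeta * Mz)
  if (s2 <= 0) {
    stop("invalid dependence parameters: conditional variance <= 0",
         call. = FALSE)
  }
  list(coef = Mz, sd = sqrt(s2))
}

# shared worker: log Pr(level interval | z) for one latent coordinate
.loglik_cond <- function(idx, lo_cut, hi_cut, Z, zeta, cov22) {
  cm <- .cond_moments(zeta, cov22)
  mu <- if (length(zeta)) drop(Z %*% cm$coef) else rep(0, length(idx))
  a <- (lo_cut - mu) / cm$sd
  b <- (hi_cut - mu) / cm$sd
  pv <- stats::pnorm(b) - stats::pnorm(a)
  if (any(pv < 1e-300)) {
    stop("zero-probability cell in conditional interval probability",
         call. = FALSE)
  }
  log(pv)
}

#' Per-subject conditional log-likelihood of genotype given covariates
#'
#' Log probability that the latent genotype coordinate, conditionally normal
#' given covariates `z` with mean `zeta1' solve(delta22) z` and variance
#' `1 - zeta1' solve(delta22) zeta1`, falls in the subject's genotype
#' interval. The marginal covariate density factor is constant in the
#' dependence parameters and omitted, so sums of this term differ from the
#' full pairwise log-likelihood by an additive constant only.
#'
#' @inheritParams loglik_gy
#' @param Z Matrix of standardized covariates (n x q).
#' @param zeta1 Latent genotype-covariate correlation vector.
#' @param cov22 [estimate_cov22()] result.
#' @return Numeric vector of per-subject contributions.
#' @export
loglik_gz <- function(g, Z, xi, zeta1, cov22) {
  xe <- .extend(xi)
  .loglik_cond(g, xe[g + 1L], xe[g + 2L], as.matrix(Z), zeta1, cov22)
}

#' Per-subject conditional log-likelihood of phenotype given covariates
#'
#' Mirror of [loglik_gz()] for the phenotype coordinate: conditional mean
#' `zeta2' solve(delta22) z`, variance `1 - zeta2' solve(delta22) zeta2`,
#' phenotype cut-points `eta`.
#'
#' @inheritParams loglik_gz
#' @param zeta2 Latent phenotype-covariate correlation vector.
#' @return Numeric vector of per-subject contributions.
#' @export
loglik_yz <- function(y, Z, eta, zeta2, cov22) {
  ye <- .extend(eta)
  .loglik_cond(y, ye[y], ye[y + 1L], as.matrix(Z), zeta2, cov22)
}

# score of one conditional block w.r.t. its zeta: n x q matrix
.score_cond <- function(lo_cut, hi_cut, Z, zeta, cov22) {
  cm <- .cond_moments(zeta, cov22)
  mu <- drop(Z %*% cm$coef)
  s <- cm$sd
  a <- (lo_cut - mu) / s
  b <- (hi_cut - mu) / s
  pv <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  # x * dnorm(x) -> 0 at +-Inf
  ada <- ifelse(is.finite(a), a * da, 0)
  bdb <- ifelse(is.finite(b), b * db, 0)
  # d log P / d zeta = [ (da - db)/s * Z + (bdb - ada)/s^2 * (Minv zeta)' ] / P
  sweep(Z, 1, (da - db) / (s * pv), "*") +
    tcrossprod((bdb - ada) / (s^2 * pv), cm$coef)
}

#' Per-subject score of the composite pairwise log-likelihood
#'
#' The estimating-function vector: partial derivatives of the three pairwise
#' log-likelihood terms with respect to `delta0 = (delta12, zeta1, zeta2)`.
#' The `delta12` component applies the identity
#' \eqn{\partial \Phi_2(h,k;\rho)/\partial\rho = \phi_2(h,k;\rho)} at the
#' four corners of each subject's (g, y) rectangle; the zeta components
#' differentiate the conditional interval probabilities.
#'
#' @inheritParams loglik_gz
#' @param y Integer vector of phenotype levels (1..m).
#' @param eta Phenotype thresholds.
#' @param params A [dependence_params()] object (or plain list with the same
#'   fields).
#' @return An n x (2q + 1) matrix; columns ordered (delta12, zeta1, zeta2).
#' @export
score_phi <- function(g, y, Z, params, xi, eta, cov22 = NULL) {
  Z <- as.matrix(Z)
  q <- ncol(Z)
  P <- .cell_probs_gy(xi, eta, params$delta12)
  dP <- .cell_dprobs_gy(xi, eta, params$delta12)
  idx <- cbind(g + 1L, y)
  pv <- P[idx]
  if (any(pv < 1e-300)) {
    stop("zero-probability cell in score evaluation", call. = FALSE)
  }
  s12 <- dP[idx] / pv
  if (q == 0L) return(matrix(s12, ncol = 1))
  xe <- .extend(xi)
  ye <- .extend(eta)
  s_z1 <- .score_cond(xe[g + 1L], xe[g + 2L], Z, params$zeta1, cov22)
  s_z2 <- .score_cond(ye[y], ye[y + 1L], Z, params$zeta2, cov22)
  cbind(s12, s_z1, s_z2, deparse.level = 0)
}
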