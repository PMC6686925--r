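# Estimation and testing: solve the pairwise-likelihood estimating equation
# for delta0, form the M-estimation sandwich variance, and Wald-test the
# conditional latent correlation rho(delta0) = delta12 - zeta1' D22^-1 zeta2.

# Precompute everything the optimizer touches repeatedly.
.lvm_prepare <- function(sample) {
  counts_g <- tabulate(sample$g + 1L, nbins = length(sample$g_levels))
  counts_y <- tabulate(sample$y, nbins = length(sample$y_levels))
  xi <- estimate_thresholds(counts_g)
  eta <- estimate_thresholds(counts_y)
  N <- matrix(0, length(counts_g), length(counts_y))
  tb <- table(factor(sample$g, levels = seq_along(counts_g) - 1L),
              factor(sample$y, levels = seq_along(counts_y)))
  N[] <- as.numeric(tb)
  q <- ncol(sample$Z)
  cov22 <- if (q) estimate_cov22(sample$Z) else NULL
  xe <- .extend(xi)
  ye <- .extend(eta)
  list(sample = sample, xi = xi, eta = eta, N = N, q = q, n = sample$n,
       cov22 = cov22,
       glo = xe[sample$g + 1L], ghi = xe[sample$g + 2L],
       ylo = ye[sample$y], yhi = ye[sample$y + 1L])
}

# Composite objective h(delta0) (to MAXIMIZE) and its gradient. Returns
# closures sharing the prepared context. Cell probabilities are floored at
# 1e-300 inside the optimizer; the orchestrator re-checks the optimum.
.lvm_objective <- function(ctx) {
  feas_eps <- 1e-6
  cond_part <- function(zeta, lo, hi) {
    Mz <- drop(ctx$cov22$inverse %*% zeta)
    s2 <- 1 - sum(zeta * Mz)
    if (s2 <= feas_eps) return(NULL)
    mu <- drop(ctx$sample$Z %*% Mz)
    s <- sqrt(s2)
    a <- (lo - mu) / s
    b <- (hi - mu) / s
    pv <- pmax(stats::pnorm(b) - stats::pnorm(a), 1e-300)
    list(Mz = Mz, s = s, a = a, b = b, pv = pv)
  }
  fn <- function(par) {
    dp <- .vec_to_dp(par, ctx$q)
    P <- pmax(.cell_probs_gy(ctx$xi, ctx$eta, dp$delta12), 1e-300)
    h <- sum(ctx$N * log(P))
    if (ctx$q) {
      for (blk in list(list(z = dp$zeta1, lo = ctx$glo, hi = ctx$ghi),
                       list(z = dp$zeta2, lo = ctx$ylo, hi = ctx$yhi))) {
        cp <- cond_part(blk$z, blk$lo, blk$hi)
        if (is.null(cp)) {
          Mz <- drop(ctx$cov22$inverse %*% blk$z)
          viol <- feas_eps - (1 - sum(blk$z * Mz))
          return(1e8 * (1 + viol)) # infeasible: large, increasing in violation
        }
        h <- h + sum(log(cp$pv))
      }
    }
    -h
  }
  gr <- function(par) {
    dp <- .vec_to_dp(par, ctx$q)
    P <- pmax(.cell_probs_gy(ctx$xi, ctx$eta, dp$delta12), 1e-300)
    dP <- .cell_dprobs_gy(ctx$xi, ctx$eta, dp$delta12)
    g12 <- sum(ctx$N * dP / P)
    if (!ctx$q) return(-g12)
    grad_cond <- function(zeta, lo, hi) {
      cp <- cond_part(zeta, lo, hi)
      if (is.null(cp)) {
        # push back toward feasibility
        return(-1e8 * 2 * drop(ctx$cov22$inverse %*% zeta))
      }
      da <- stats::dnorm(cp$a)
      db <- stats::dnorm(cp$b)
      ada <- ifelse(is.finite(cp$a), cp$a * da, 0)
      bdb <- ifelse(is.finite(cp$b), cp$b * db, 0)
      w1 <- (da - db) / (cp$s * cp$pv)
      w2 <- (bdb - ada) / (cp$s^2 * cp$pv)
      drop(crossprod(ctx$sample$Z, w1)) + sum(w2) * cp$Mz
    }
    -c(g12,
       grad_cond(dp$zeta1, ctx$glo, ctx$ghi),
       grad_cond(dp$zeta2, ctx$ylo, ctx$yhi))
  }
  list(fn = fn, gr = gr)
}

#' Solve the generalized estimating equation for the dependence parameters
#'
#' Maximizes the composite pairwise log-likelihood (whose gradient is the
#' summed estimating function), under box constraints `|delta12| <= 1 - 1e-6`
#' and a feasibility guard on the conditional variances. Equivalent to
#' root-finding on the summed score, but more stable.
#'
#' @param sample An [ordinal_sample()].
#' @param init Optional numeric start `c(delta12, zeta1, zeta2)`; defaults
#'   to the zero vector.
#' @param grad_tol Convergence tolerance on the max-abs component of the
#'   mean score (summed score / n).
#' @param max_iter Maximum optimizer iterations.
#' @return A list with `params` ([dependence_params()]), the prepared model
#'   context, mean-score vector at the solution, iteration count and
#'   convergence flag.
#' @export
solve_gee <- function(sample, init = NULL, grad_tol = 1e-8, max_iter = 200) {
  ctx <- .lvm_prepare(sample)
  p <- 2 * ctx$q + 1
  obj <- .lvm_objective(ctx)
  bound <- 1 - 1e-6
  start <- if (is.null(init)) rep(0, p) else rep_len(as.numeric(init), p)

  run <- function(st) {
    stats::nlminb(st, obj$fn, gradient = obj$gr,
                  lower = rep(-bound, p), upper = rep(bound, p),
                  control = list(iter.max = max_iter, eval.max = 3 * max_iter,
                                 rel.tol = 1e-12))
  }
  # Newton polish on the mean-score root: nlminb stops on function-change
  # criteria, so a few damped Newton steps drive the score to tolerance.
  polish <- function(par) {
    ms <- -obj$gr(par) / ctx$n
    for (it in seq_len(25)) {
      if (max(abs(ms)) <= grad_tol) break
      Jms <- matrix(0, p, p)
      for (j in seq_len(p)) {
        hstep <- 1e-6 * max(1, abs(par[j]))
        ep <- em <- par
        ep[j] <- min(ep[j] + hstep, bound)
        em[j] <- max(em[j] - hstep, -bound)
        Jms[, j] <- (-obj$gr(ep) + obj$gr(em)) / (ctx$n * (ep[j] - em[j]))
      }
      step <- tryCatch(solve(Jms, ms), error = function(e) NULL)
      if (is.null(step)) break
      cand <- pmin(pmax(par - step, -bound), bound)
      msc <- -obj$gr(cand) / ctx$n
      if (!all(is.finite(msc)) || max(abs(msc)) >= max(abs(ms))) break
      par <- cand
      ms <- msc
    }
    list(par = par, ms = ms)
  }
  fit <- run(start)
  pol <- polish(fit$par)
  fit$par <- pol$par
  mean_score <- pol$ms
  if (max(abs(mean_score)) > grad_tol) {
    fit2 <- run(start / 2 + 1e-3) # one restart from a shrunk/perturbed init
    pol2 <- polish(fit2$par)
    if (max(abs(pol2$ms)) < max(abs(mean_score))) {
      fit <- fit2
      fit$par <- pol2$par
      mean_score <- pol2$ms
    }
  }
  converged <- max(abs(mean_score)) <= max(grad_tol, 1e-6)
  if (!converged && max(abs(mean_score)) > 1e-4) {
    stop(sprintf(
      "estimating equation did not converge: max |mean score| = %.3e at (%s)",
      max(abs(mean_score)), paste(signif(fit$par, 4), collapse = ", ")),
      call. = FALSE)
  }
  dp <- .vec_to_dp(fit$par, ctx$q)
  params <- dependence_params(dp$delta12, dp$zeta1, dp$zeta2, ctx$cov22)
  list(params = params, par = fit$par, ctx = ctx,
       mean_score = mean_score, objective = -fit$objective,
       n_iter = fit$iterations, converged = converged)
}

#' Sandwich (M-estimation) covariance of the dependence-parameter estimator
#'
#' The "meat" `I` is the average outer product of the per-subject scores;
#' the "bread" `J` is minus the average Jacobian of the score, obtained by
#' central finite differences of the analytic score (step
#' `1e-5 * max(1, |par|)` per coordinate). `V = J^-1 I J^-1`, symmetrized.
#'
#' @param ctx Prepared model context from [solve_gee()]'s return value.
#' @param par Numeric parameter vector at the solution.
#' @param fd_step Relative finite-difference step for the Jacobian.
#' @return List with matrices `I_mat`, `J_mat`, `V`.
#' @export
sandwich_variance <- function(ctx, par, fd_step = 1e-5) {
  dp <- .vec_to_dp(par, ctx$q)
  S <- score_phi(ctx$sample$g, ctx$sample$y, ctx$sample$Z, dp,
                 ctx$xi, ctx$eta, ctx$cov22)
  n <- ctx$n
  I_mat <- crossprod(S) / n
  p <- length(par)
  mean_score_at <- function(v) {
    d <- .vec_to_dp(v, ctx$q)
    colMeans(score_phi(ctx$sample$g, ctx$sample$y, ctx$sample$Z, d,
                       ctx$xi, ctx$eta, ctx$cov22))
  }
  J_mat <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hstep <- fd_step * max(1, abs(par[j]))
    ep <- em <- par
    ep[j] <- ep[j] + hstep
    em[j] <- em[j] - hstep
    J_mat[, j] <- -(mean_score_at(ep) - mean_score_at(em)) / (2 * hstep)
  }
  Jinv <- tryCatch(solve(J_mat),
                   error = function(e) stop("non-invertible Jacobian",
                                            call. = FALSE))
  V <- Jinv %*% I_mat %*% t(Jinv)
  V <- (V + t(V)) / 2
  list(I_mat = I_mat, J_mat = J_mat, V = V)
}

#' Conditional latent correlation rho(delta0)
#'
#' `rho = delta12 - zeta1' solve(delta22) zeta2`: the partial correlation of
#' the genotype and phenotype latent coordinates given the covariates. The
#' null hypothesis of conditional independence is `rho = 0`.
#'
#' @param params A [dependence_params()] object (or compatible list).
#' @param cov22 [estimate_cov22()] result; may be `NULL` when there are no
#'   covariates, in which case `rho = delta12`.
#' @return Scalar.
#' @export
lvm_rho <- function(params, cov22 = NULL) {
  if (!length(params$zeta1)) return(params$delta12)
  params$delta12 - drop(crossprod(params$zeta1,
                                  cov22$inverse %*% params$zeta2))
}

#' Gradient of rho(delta0)
#'
#' Exact gradient `(1, -(solve(delta22) zeta2)', -(solve(delta22) zeta1)')`
#' used by the delta method.
#'
#' @inheritParams lvm_rho
#' @return Numeric vector of length `2q + 1`.
#' @export
lvm_rho_grad <- function(params, cov22 = NULL) {
  if (!length(params$zeta1)) return(1)
  c(1, -drop(cov22$inverse %*% params$zeta2),
    -drop(cov22$inverse %*% params$zeta1))
}

#' Delta-method Wald test of conditional independence
#'
#' `TW = rho_hat / sqrt(grad' V grad / n)`, asymptotically standard normal
#' under `rho = 0`; the p-value is the two-sided normal tail.
#'
#' @param rho_hat Estimated conditional latent correlation.
#' @param rho_grad Gradient of rho at the estimate.
#' @param V Sandwich covariance matrix (scale of `sqrt(n) * delta0_hat`).
#' @param n Sample size.
#' @return List with `TW`, `se_rho` and `p_value`.
#' @export
wald_test <- function(rho_hat, rho_grad, V, n) {
  qf <- drop(crossprod(rho_grad, V %*% rho_grad))
  if (!is.finite(qf) || qf <= 0) {
    stop("nonpositive variance quadratic form in Wald test", call. = FALSE)
  }
  se <- sqrt(qf / n)
  TW <- rho_hat / se
  list(TW = TW, se_rho = se, p_value = 2 * stats::pnorm(-abs(TW)))
}

#' Latent-variable-model association test for an ordinal trait
#'
#' Full test pipeline: validate and standardize the data, estimate latent
#' thresholds from marginal category frequencies and the covariate
#' covariance by maximum likelihood, solve the pairwise-likelihood
#' estimating equation for `delta0 = (delta12, zeta1, zeta2)`, form the
#' sandwich covariance, and Wald-test the conditional latent correlation
#' `rho = delta12 - zeta1' solve(delta22) zeta2` (zero if and only if
#' genotype and phenotype are conditionally independent given covariates).
#'
#' @param data A data frame (one row per subject) or an [ordinal_sample()].
#' @param genotype,phenotype,covariates Column names when `data` is a data
#'   frame; see [ordinal_sample()].
#' @param allow_no_covariates If `TRUE`, permits the covariate-free
#'   polychoric-only test `rho = delta12` (escape hatch used mainly for
#'   cross-checks); the main path requires at least one covariate.
#' @param ... Passed to [solve_gee()] (`init`, `grad_tol`, `max_iter`).
#' @return An object of class `lvm_fit` with the estimate, sandwich
#'   covariance `V` (with `I_mat`, `J_mat`), `rho_hat`, `se_rho`, Wald
#'   statistic `TW`, `p_value` and convergence diagnostics. Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance], `print()`.
#' @examples
#' d <- simulate_ordinal(sim_config("nd", n = 300, maf = 0.3, seed = 1))
#' fit <- lvm_test(d)
#' glance(fit)
#' @export
lvm_test <- function(data, genotype = "g", phenotype = "y",
                     covariates = NULL, allow_no_covariates = FALSE, ...) {
  sample <- if (inherits(data, "ordinal_sample")) data else
    ordinal_sample(data, genotype, phenotype, covariates)
  if (ncol(sample$Z) == 0L && !allow_no_covariates) {
    stop("no covariate columns: the model requires >= 1 continuous ",
         "covariate (set allow_no_covariates = TRUE for the polychoric-only ",
         "test)", call. = FALSE)
  }
  stage <- function(lab, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", lab, conditionMessage(e)), call. = FALSE)
    })
  }
  sol <- stage("gee", solve_gee(sample, ...))
  # re-check observed cell probabilities at the optimum (no silent clipping)
  stage("gee", {
    P <- .cell_probs_gy(sol$ctx$xi, sol$ctx$eta, sol$params$delta12)
    if (any(P[sol$ctx$N > 0] < 1e-12)) {
      stop("zero-probability cell at the solution")
    }
  })
  sw <- stage("sandwich", sandwich_variance(sol$ctx, sol$par))
  rho_hat <- lvm_rho(sol$params, sol$ctx$cov22)
  grad <- lvm_rho_grad(sol$params, sol$ctx$cov22)
  wt <- stage("wald", wald_test(rho_hat, grad, sw$V, sample$n))

  structure(
    list(params = sol$params, par = sol$par,
         thresholds = list(xi = sol$ctx$xi, eta = sol$ctx$eta),
         cov22 = sol$ctx$cov22,
         V = sw$V, I_mat = sw$I_mat, J_mat = sw$J_mat,
         rho_hat = rho_hat, rho_grad = grad,
         se_rho = wt$se_rho, TW = wt$TW, p_value = wt$p_value,
         n = sample$n, converged = sol$converged, n_iter = sol$n_iter,
         objective = sol$objective, mean_score = sol$mean_score),
    class = "lvm_fit"
  )
}

#' @export
print.lvm_fit <- function(x, ...) {
  cat("Latent-variable-model association test\n")
  cat(sprintf("  n = %d, delta12 = %.4f, rho = %.4f (se %.4f)\n",
              x$n, x$params$delta12, x$rho_hat, x$se_rho))
  cat(sprintf("  TW = %.4f, p = %.4g%s\n", x$TW, x$p_value,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the dependence-parameter estimates of an lvm fit
#'
#' One row per element of `delta0` with the estimate and its asymptotic
#' standard error `sqrt(V_jj / n)` from the sandwich covariance.
#'
#' @param x An `lvm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy lvm_fit
#' @export
tidy.lvm_fit <- function(x, ...) {
  q <- length(x$params$zeta1)
  terms <- c("delta12",
             if (q) paste0("zeta1_", seq_len(q)),
             if (q) paste0("zeta2_", seq_len(q)))
  tibble::tibble(
    term = terms,
    estimate = x$par,
    std.error = sqrt(pmax(diag(as.matrix(x$V)), 0) / x$n)
  )
}

#' One-row summary of an lvm fit
#'
#' @param x An `lvm_fit`.
#' @param ... Unused.
#' @return A tibble with `rho`, `se_rho`, `statistic` (TW), `p.value`, `n`,
#'   `n_iter`, `converged`, `objective`.
#' @method glance lvm_fit
#' @export
glance.lvm_fit <- function(x, ...) {
  tibble::tibble(
    rho = x$rho_hat, se_rho = x$se_rho, statistic = x$TW,
    p.value = x$p_value, n = x$n, n_iter = x$n_iter,
    converged = x$converged, objective = x$objective
  )
}
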