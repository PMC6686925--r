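# Seeded generators for the two study mechanisms:
#  - ND: (U1, U2, U3) trivariate normal; genotype and phenotype are
#    quantile discretizations of U1 and U2, the covariate is U3.
#  - PO: genotype multinomial, covariate standard normal, phenotype from a
#    proportional-odds (cumulative logit) model.

#' Simulation configuration
#'
#' Bundles one simulation scenario. Under the ND mechanism `effect = NULL`
#' selects the null latent covariance (off-diagonals 0.4, 0.5, 0.8, for
#' which the conditional latent correlation is exactly
#' 0.4 - 0.5 * 0.8 = 0), and a numeric `effect` (theta) selects the
#' alternative covariance with off-diagonals (theta, 0.1, 0.1), for which
#' rho = theta - 0.01. Under the PO mechanism `effect` is the nonnegative
#' multiplier v of the per-genotype effects `v * c(0, 0.15, 0.3)` attached
#' to the three underlying genotypes AA/Aa/aa; `effect = NULL` means v = 0
#' (the null).
#'
#' @param mechanism `"nd"` or `"po"`.
#' @param genetic_model `"co-dominant"` (coding 0/1/2), `"dominant"`
#'   (0/1/1) or `"recessive"` (0/0/1).
#' @param maf Minor allele frequency in (0, 0.5]; genotype cell
#'   probabilities are the Hardy-Weinberg `((1-p)^2, 2p(1-p), p^2)`.
#'   Exactly one of `maf` and `probs` must be given.
#' @param probs Explicit probabilities for (AA, Aa, aa), summing to 1
#'   (non-HWE scenarios).
#' @param effect Effect parameter (theta for ND, v for PO); `NULL` = null.
#' @param n Number of subjects.
#' @param seed Optional integer seed; generation is reproducible given the
#'   config.
#' @param y_probs ND phenotype marginal probabilities (must sum to 1).
#' @param alphas PO cumulative-logit intercepts, strictly increasing.
#' @param beta_scale PO per-genotype effect pattern multiplied by v.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mechanism = c("nd", "po"),
                       genetic_model = c("co-dominant", "dominant",
                                         "recessive"),
                       maf = NULL, probs = NULL, effect = NULL, n = 300,
                       seed = NULL,
                       y_probs = c(0.7, 0.1, 0.08, 0.07, 0.05),
                       alphas = c(0.85, 1.39, 1.99, 2.94),
                       beta_scale = c(0, 0.15, 0.3)) {
  mechanism <- match.arg(mechanism)
  genetic_model <- match.arg(genetic_model)
  if (is.null(maf) == is.null(probs)) {
    stop("give exactly one of `maf` or `probs`", call. = FALSE)
  }
  if (!is.null(maf)) {
    if (maf <= 0 || maf > 0.5) stop("`maf` must be in (0, 0.5]",
                                    call. = FALSE)
    probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  }
  if (length(probs) != 3L || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-12) {
    stop("`probs` must be 3 nonnegative values summing to 1", call. = FALSE)
  }
  if (abs(sum(y_probs) - 1) > 1e-12 || any(y_probs <= 0)) {
    stop("`y_probs` must be positive and sum to 1", call. = FALSE)
  }
  if (is.unsorted(alphas, strictly = TRUE)) {
    stop("`alphas` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(effect) && mechanism == "po" && effect < 0) {
    stop("PO effect v must be nonnegative", call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  structure(
    list(mechanism = mechanism, genetic_model = genetic_model,
         maf = maf, probs = probs, effect = effect, n = as.integer(n),
         seed = seed, y_probs = y_probs, alphas = alphas,
         beta_scale = beta_scale),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s | %s | probs (%.3f, %.3f, %.3f) | effect %s | n = %d\n",
    toupper(x$mechanism), x$genetic_model,
    x$probs[1], x$probs[2], x$probs[3],
    if (is.null(x$effect)) "null" else format(x$effect), x$n))
  invisible(x)
}

#' Genotype cell probabilities and coding map
#'
#' Probabilities of the three underlying genotypes (AA, Aa, aa) and the
#' coding applied under the configured genetic model: co-dominant (0, 1, 2),
#' dominant (0, 1, 1), recessive (0, 0, 1). `coded_probs` aggregates over
#' the coding.
#'
#' @param config A [sim_config()].
#' @return List with `probs` (length 3), `coding` (length 3), and
#'   `coded_probs` (named by coded level).
#' @export
genotype_cell_probs <- function(config) {
  coding <- switch(config$genetic_model,
                   "co-dominant" = c(0L, 1L, 2L),
                   "dominant" = c(0L, 1L, 1L),
                   "recessive" = c(0L, 0L, 1L))
  coded <- vapply(split(config$probs, coding), sum, numeric(1))
  list(probs = config$probs, coding = coding, coded_probs = coded)
}

# latent covariance of (U1, U2, U3) for the ND mechanism
.nd_sigma <- function(effect) {
  if (is.null(effect)) {
    off <- c(0.4, 0.5, 0.8) # (12, 13, 23): null since 0.4 = 0.5 * 0.8
  } else {
    off <- c(effect, 0.1, 0.1)
  }
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- off[1]
  S[1, 3] <- S[3, 1] <- off[2]
  S[2, 3] <- S[3, 2] <- off[3]
  S
}

#' Simulate under the latent-normal discretization (ND) mechanism
#'
#' Draws `(U1, U2, U3)` from a trivariate normal with unit variances and the
#' configured covariance, then discretizes `U1` at the population quantile
#' cut-points of the genotype cell probabilities (coded per the genetic
#' model) and `U2` at the quantiles of `y_probs`; the covariate is `U3`.
#'
#' @param config A [sim_config()] with `mechanism = "nd"`.
#' @return A tibble with columns `g` (coded genotype), `y` (1..m), `z`.
#' @export
simulate_nd <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$mechanism == "nd")
  S <- .nd_sigma(config$effect)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent covariance is not positive definite",
                         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  U <- matrix(stats::rnorm(3 * config$n), ncol = 3) %*% chol(S)
  gp <- genotype_cell_probs(config)
  cuts_g <- stats::qnorm(cumsum(gp$probs)[1:2])
  cuts_y <- stats::qnorm(cumsum(config$y_probs))
  cuts_y <- cuts_y[seq_len(length(config$y_probs) - 1)]
  g3 <- findInterval(U[, 1], cuts_g) # 0, 1, 2
  y <- 1L + findInterval(U[, 2], cuts_y)
  tibble::tibble(g = gp$coding[g3 + 1L], y = as.integer(y), z = U[, 3])
}

#' Simulate under the proportional-odds (PO) mechanism
#'
#' Underlying genotypes AA/Aa/aa are multinomial with the configured cell
#' probabilities; `Z ~ N(0, 1)`; the phenotype is drawn from the cumulative
#' logit model `Pr(Y <= j) = plogis(alpha_j - Z - beta[G + 1])` with
#' `beta = v * beta_scale` indexed by the *coded* genotype value G (so a
#' 2-level dominant/recessive coding uses only the first two effects).
#' `Pr(Y <= m) = 1`.
#'
#' @param config A [sim_config()] with `mechanism = "po"`.
#' @return A tibble with columns `g`, `y`, `z`.
#' @export
simulate_po <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$mechanism == "po")
  if (!is.null(config$seed)) set.seed(config$seed)
  v <- if (is.null(config$effect)) 0 else config$effect
  beta <- v * config$beta_scale
  gp <- genotype_cell_probs(config)
  g3 <- sample.int(3L, config$n, replace = TRUE, prob = gp$probs) - 1L
  g <- gp$coding[g3 + 1L]
  z <- stats::rnorm(config$n)
  # n x (m-1) cumulative probabilities; row-monotone since alphas ascend
  lin <- outer(-z - beta[g + 1L], config$alphas, "+")
  cum <- stats::plogis(lin)
  u <- stats::runif(config$n)
  y <- 1L + rowSums(u > cum)
  tibble::tibble(g = g, y = as.integer(y), z = z)
}

#' Simulate one dataset from a configuration
#'
#' Dispatches to [simulate_nd()] or [simulate_po()].
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `g`, `y`, `z`.
#' @examples
#' simulate_ordinal(sim_config("nd", n = 5, maf = 0.3, seed = 1))
#' @export
simulate_ordinal <- function(config) {
  switch(config$mechanism, nd = simulate_nd(config), po = simulate_po(config))
}

# A draw is unusable when the coded genotype or the phenotype collapses to a
# single observed level (no association test is defined there).
.is_degenerate <- function(d) {
  length(unique(d$g)) < 2L || length(unique(d$y)) < 2L
}
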