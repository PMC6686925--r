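# Shared oracles and small fixtures, all built in code.

# Reference bivariate normal CDF (deterministic TVPACK algorithm).
ref_pbvn <- function(h, k, rho) {
  mvtnorm::pmvnorm(upper = c(h, k),
                   corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::TVPACK())[1]
}

# Brute-force polychoric MLE for a 2x2 count table by grid search + local
# refinement; independent of the package's optimizer.
grid_polychoric <- function(counts, xi, eta) {
  cell_ll <- function(rho) {
    p11 <- pbvn(xi, eta, rho)
    p1. <- stats::pnorm(xi)
    p.1 <- stats::pnorm(eta)
    P <- matrix(c(p11, p.1 - p11, p1. - p11, 1 - p1. - p.1 + p11), 2, 2)
    sum(counts * log(pmax(P, 1e-300)))
  }
  grid <- seq(-0.995, 0.995, by = 0.005)
  best <- grid[which.max(vapply(grid, cell_ll, numeric(1)))]
  fine <- seq(max(-0.999, best - 0.01), min(0.999, best + 0.01), by = 1e-5)
  fine[which.max(vapply(fine, cell_ll, numeric(1)))]
}

# Composite objective evaluated through the user-facing loglik blocks;
# used as the finite-difference reference for the analytic score.
composite_h <- function(g, y, Z, par, xi, eta, cov22) {
  q <- ncol(Z)
  dp <- list(delta12 = par[1], zeta1 = par[2:(q + 1)],
             zeta2 = par[(q + 2):(2 * q + 1)])
  sum(loglik_gy(g, y, xi, eta, dp$delta12)) +
    sum(loglik_gz(g, Z, xi, dp$zeta1, cov22)) +
    sum(loglik_yz(y, Z, eta, dp$zeta2, cov22))
}

# Iterated grid search maximizer of the composite objective for the
# one-covariate case (3 parameters); independent of nlminb and of the
# package's analytic gradient.
iterated_grid_max <- function(g, y, Z, xi, eta, cov22,
                              lower = rep(-0.9, 3), upper = rep(0.9, 3),
                              rounds = 4, pts = 11) {
  centre <- (lower + upper) / 2
  width <- (upper - lower) / 2
  for (r in seq_len(rounds)) {
    axes <- lapply(1:3, function(j) {
      seq(max(-0.99, centre[j] - width[j]),
          min(0.99, centre[j] + width[j]), length.out = pts)
    })
    gr <- as.matrix(expand.grid(axes))
    vals <- apply(gr, 1, function(p) {
      tryCatch(composite_h(g, y, Z, p, xi, eta, cov22),
               error = function(e) -Inf)
    })
    centre <- gr[which.max(vals), ]
    width <- width * 2.2 / (pts - 1)
  }
  unname(centre)
}

# Expand a 2x2 count table into subject-level vectors.
counts_to_sample <- function(counts) {
  g <- rep(c(0L, 0L, 1L, 1L), times = as.vector(t(counts)))
  y <- rep(c(1L, 2L, 1L, 2L), times = as.vector(t(counts)))
  list(g = g, y = y)
}
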