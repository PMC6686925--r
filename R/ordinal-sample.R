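# Subject-level data container: ordinal genotype, ordinal phenotype,
# standardized continuous covariates.

#' Validate and standardize subject-level ordinal association data
#'
#' Builds the sample object the latent-variable test operates on: an ordinal
#' genotype with 2 or 3 ordered levels, an ordinal phenotype with at least 2
#' levels, and one or more continuous covariates. Covariates are z-scored
#' column-wise with the n-denominator standard deviation so that the latent
#' covariance of the covariate block has unit diagonal, matching the
#' correlation-scale parameterization of the model.
#'
#' @param data A data frame with one row per subject.
#' @param genotype,phenotype,covariates Column names (character). `covariates`
#'   defaults to every column not named as genotype or phenotype.
#' @return An object of class `ordinal_sample`: a list with integer vectors
#'   `g` (0-based consecutive genotype codes) and `y` (1-based consecutive
#'   phenotype levels), matrix `Z` of standardized covariates, the original
#'   level labels (`g_levels`, `y_levels`), and the centering/scaling applied
#'   to each covariate.
#' @examples
#' d <- data.frame(g = c(0, 1, 1, 2), y = c(1, 2, 1, 3),
#'                 z = c(1, -1, 2, -2))
#' s <- ordinal_sample(d, genotype = "g", phenotype = "y")
#' colMeans(s$Z) # ~0
#' @export
ordinal_sample <- function(data, genotype = "g", phenotype = "y",
                           covariates = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("`data` has no rows", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(genotype, phenotype))
  }
  missing_cols <- setdiff(c(genotype, phenotype, covariates), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(data), collapse = ", "), call. = FALSE)
  }
  cols <- data[, c(genotype, phenotype, covariates), drop = FALSE]
  bad <- which(!stats::complete.cases(cols))
  if (length(bad)) {
    stop("missing values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }

  g_raw <- cols[[genotype]]
  y_raw <- cols[[phenotype]]
  g_levels <- sort(unique(g_raw))
  y_levels <- sort(unique(y_raw))
  if (length(g_levels) < 2L || length(y_levels) < 2L) {
    stop("degenerate category structure: genotype and phenotype each need ",
         ">= 2 observed levels", call. = FALSE)
  }
  if (length(g_levels) > 3L) {
    stop("genotype must have 2 or 3 ordered levels, found ",
         length(g_levels), call. = FALSE)
  }
  g <- match(g_raw, g_levels) - 1L # 0-based codes
  y <- match(y_raw, y_levels)      # 1..m

  if (length(covariates) == 0L) {
    Z <- matrix(numeric(0), nrow = nrow(cols), ncol = 0)
    center <- scale_ <- numeric(0)
  } else {
    Z <- as.matrix(cols[, covariates, drop = FALSE])
    if (!is.numeric(Z)) {
      stop("covariate columns must be numeric", call. = FALSE)
    }
    n <- nrow(Z)
    center <- colMeans(Z)
    # n-denominator sd: keeps the plug-in covariate covariance unit-diagonal
    scale_ <- sqrt(colMeans(sweep(Z, 2, center)^2))
    if (any(scale_ < 1e-12)) {
      stop("constant covariate column: ",
           paste(covariates[scale_ < 1e-12], collapse = ", "), call. = FALSE)
    }
    Z <- sweep(sweep(Z, 2, center), 2, scale_, "/")
    dimnames(Z) <- list(NULL, covariates)
  }

  structure(
    list(g = g, y = y, Z = Z, n = length(g),
         g_levels = g_levels, y_levels = y_levels,
         center = center, scale = scale_),
    class = "ordinal_sample"
  )
}

#' @export
print.ordinal_sample <- function(x, ...) {
  cat(sprintf(
    "<ordinal_sample> n = %d, genotype levels = %d, phenotype levels = %d, covariates = %d\n",
    x$n, length(x$g_levels), length(x$y_levels), ncol(x$Z)))
  invisible(x)
}

#' Latent-scale thresholds from category counts
#'
#' Cut-points on the standard normal scale whose interval probabilities
#' reproduce the observed category proportions: cut-point j is the normal
#' quantile of the cumulative proportion through category j. Sentinel bounds
#' at \eqn{\pm\infty} are implicit and not returned.
#'
#' @param counts Nonnegative integer vector of category counts in level
#'   order; every category must be observed (a zero count makes the model
#'   degenerate for that sample).
#' @return Strictly increasing numeric vector of length
#'   `length(counts) - 1`.
#' @examples
#' estimate_thresholds(c(150, 150)) # 0
#' @export
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need >= 2 categories", call. = FALSE)
  if (any(counts <= 0)) {
    stop("empty category: all levels must be observed (counts: ",
         paste(counts, collapse = ", "), ")", call. = FALSE)
  }
  p <- cumsum(counts) / sum(counts)
  stats::qnorm(p[-length(p)])
}

#' Covariance of the standardized covariate block
#'
#' Maximum-likelihood (n-denominator) sample covariance of the standardized
#' covariates — the plug-in estimate of the covariate block of the latent
#' correlation matrix. With n-denominator z-scoring the diagonal is exactly 1.
#'
#' @param Z Numeric matrix of standardized covariates (n x q, q >= 1).
#' @return A list of class `cov22` with elements `delta22`, its `inverse`,
#'   and `log_det`.
#' @export
estimate_cov22 <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 1L) stop("need at least one covariate column", call. = FALSE)
  n <- nrow(Z)
  delta22 <- crossprod(Z) / n
  ev <- eigen(delta22, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    stop("collinear covariates: covariance matrix is rank-deficient",
         call. = FALSE)
  }
  structure(
    list(delta22 = delta22, inverse = solve(delta22),
         log_det = determinant(delta22, logarithm = TRUE)$modulus[[1]]),
    class = "cov22"
  )
}
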