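# Reference Monte-Carlo rejection rates (1000 replicates, n = 300,
# alpha = 0.05) from the original simulation study of the latent-variable
# test, attached by reproduce_table() for side-by-side comparison. NA marks
# cells that study left unavailable.

#' Reference rejection rates for the simulation study grid
#'
#' Published Monte-Carlo rejection rates (1000 replicates of n = 300 at
#' nominal alpha 0.05) for every scenario of the four-table study grid:
#' Type I error and power of the probit, logit and lvm tests under the ND
#' and PO mechanisms, with and without Hardy-Weinberg equilibrium. `NA`
#' marks scenarios reported as unavailable.
#'
#' @return A tibble with columns `table`, `effect_label`, `dist`, `model`,
#'   `method`, `reference`.
#' @export
reference_rates <- function() {
  tab <- c(
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    2, 2, 2, 2, 2, 2, 2, 2,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 3, 3, 3, 3, 3, 3,
    3, 3, 4, 4, 4, 4, 4, 4,
    4, 4, 4, 4, 4, 4, 4, 4,
    4, 4, 4, 4, 4, 4, 4, 4,
    4, 4, 4, 4, 4, 4, 4, 4,
    4, 4, 4, 4, 4, 4, 4, 4,
    4, 4, 4, 4, 4, 4, 4, 4,
    4, 4, 4, 4, 4, 4, 4, 4)
  eff <- c(
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2",
    "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.2", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1", "-0.1",
    "-0.1", "-0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "null", "null", "null",
    "null", "null", "null", "null", "null", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta",
    "beta", "beta", "beta", "beta", "beta", "beta", "beta", "beta")
  dst <- c(
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3",
    "0.3", "0.3", "0.3", "0.4", "0.4", "0.4", "0.4", "0.4",
    "0.4", "0.4", "0.4", "0.4", "0.5", "0.5", "0.5", "0.5",
    "0.5", "0.5", "0.5", "0.5", "0.5", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.3",
    "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3",
    "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4",
    "0.4", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5",
    "0.5", "0.5", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.3", "0.3", "0.3", "0.3",
    "0.3", "0.3", "0.3", "0.3", "0.3", "0.4", "0.4", "0.4",
    "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.5", "0.5",
    "0.5", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3",
    "0.3", "0.3", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4",
    "0.4", "0.4", "0.4", "0.5", "0.5", "0.5", "0.5", "0.5",
    "0.5", "0.5", "0.5", "0.5", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.3", "0.3",
    "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.4",
    "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4",
    "0.5", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5",
    "0.5", "P1", "P1", "P1", "P1", "P1", "P1", "P1",
    "P1", "P1", "P2", "P2", "P2", "P2", "P2", "P2",
    "P2", "P2", "P2", "P3", "P3", "P3", "P3", "P3",
    "P3", "P3", "P3", "P3", "P1", "P1", "P1", "P1",
    "P1", "P1", "P1", "P1", "P1", "P2", "P2", "P2",
    "P2", "P2", "P2", "P2", "P2", "P2", "P3", "P3",
    "P3", "P3", "P3", "P3", "P3", "P3", "P3", "P1",
    "P1", "P1", "P1", "P1", "P1", "P1", "P1", "P1",
    "P2", "P2", "P2", "P2", "P2", "P2", "P2", "P2",
    "P2", "P3", "P3", "P3", "P3", "P3", "P3", "P3",
    "P3", "P3", "P1", "P1", "P1", "P1", "P1", "P1",
    "P1", "P1", "P1", "P2", "P2", "P2", "P2", "P2",
    "P2", "P2", "P2", "P2", "P3", "P3", "P3", "P3",
    "P3", "P3", "P3", "P3", "P3", "P1", "P1", "P1",
    "P1", "P1", "P1", "P1", "P1", "P1", "P2", "P2",
    "P2", "P2", "P2", "P2", "P2", "P2", "P2", "P3",
    "P3", "P3", "P3", "P3", "P3", "P3", "P3", "P3",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.1",
    "0.1", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2",
    "0.2", "0.2", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3",
    "0.3", "0.3", "0.3", "0.4", "0.4", "0.4", "0.4", "0.4",
    "0.4", "0.4", "0.4", "0.4", "0.5", "0.5", "0.5", "0.5",
    "0.5", "0.5", "0.5", "0.5", "0.5", "0.1", "0.1", "0.1",
    "0.1", "0.1", "0.1", "0.1", "0.1", "0.1", "0.2", "0.2",
    "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.2", "0.3",
    "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3", "0.3",
    "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4", "0.4",
    "0.4", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5", "0.5",
    "0.5", "0.5", "P1", "P1", "P1", "P1", "P1", "P1",
    "P1", "P1", "P1", "P2", "P2", "P2", "P2", "P2",
    "P2", "P2", "P2", "P2", "P3", "P3", "P3", "P3",
    "P3", "P3", "P3", "P3", "P3", "P1", "P1", "P1",
    "P1", "P1", "P1", "P1", "P1", "P1", "P2", "P2",
    "P2", "P2", "P2", "P2", "P2", "P2", "P2", "P3",
    "P3", "P3", "P3", "P3", "P3", "P3", "P3", "P3")
  mdl <- c(
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive",
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive",
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive",
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive",
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive",
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive",
    "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive",
    "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive",
    "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant", "dominant",
    "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant", "dominant",
    "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant", "dominant",
    "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant", "co-dominant",
    "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant", "co-dominant",
    "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive", "co-dominant",
    "co-dominant", "co-dominant", "dominant", "dominant", "dominant", "recessive", "recessive", "recessive")
  mth <- c(
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm",
    "probit", "logit", "lvm", "probit", "logit", "lvm", "probit", "logit",
    "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm", "probit",
    "logit", "lvm", "probit", "logit", "lvm", "probit", "logit", "lvm")
  rate <- c(
    0.051, 0.046, 0.044, 0.040, 0.040, 0.034, NA, NA,
    NA, 0.049, 0.049, 0.040, 0.053, 0.054, 0.048, 0.049,
    0.058, 0.069, 0.048, 0.051, 0.046, 0.048, 0.054, 0.049,
    0.056, 0.059, 0.058, 0.049, 0.052, 0.041, 0.050, 0.042,
    0.041, 0.046, 0.046, 0.045, 0.046, 0.050, 0.037, 0.054,
    0.048, 0.060, 0.055, 0.056, 0.050, 0.514, 0.481, 0.557,
    0.503, 0.459, 0.544, NA, NA, NA, 0.636, 0.620,
    0.668, 0.654, 0.630, 0.670, 0.075, 0.013, 0.253, 0.713,
    0.685, 0.736, 0.657, 0.654, 0.668, 0.309, 0.246, 0.390,
    0.765, 0.742, 0.778, 0.665, 0.657, 0.678, 0.445, 0.403,
    0.500, 0.757, 0.747, 0.768, 0.605, 0.607, 0.617, 0.580,
    0.556, 0.610, 0.183, 0.162, 0.228, 0.163, 0.146, 0.190,
    NA, NA, NA, 0.250, 0.237, 0.267, 0.218, 0.209,
    0.233, 0.031, 0.006, 0.138, 0.289, 0.288, 0.309, 0.223,
    0.217, 0.237, 0.126, 0.094, 0.166, 0.240, 0.234, 0.251,
    0.233, 0.239, 0.244, 0.158, 0.128, 0.195, 0.284, 0.274,
    0.299, 0.192, 0.194, 0.199, 0.196, 0.173, 0.220, 0.135,
    0.147, 0.148, 0.172, 0.169, 0.180, NA, NA, NA,
    0.195, 0.197, 0.202, 0.162, 0.161, 0.169, 0.083, 0.094,
    0.128, 0.208, 0.202, 0.217, 0.184, 0.183, 0.192, 0.098,
    0.103, 0.113, 0.210, 0.196, 0.217, 0.174, 0.159, 0.190,
    0.131, 0.132, 0.138, 0.208, 0.197, 0.218, 0.141, 0.125,
    0.165, 0.171, 0.166, 0.176, 0.494, 0.488, 0.509, 0.484,
    0.477, 0.493, NA, NA, NA, 0.590, 0.586, 0.598,
    0.585, 0.573, 0.595, 0.237, 0.248, 0.269, 0.646, 0.644,
    0.662, 0.577, 0.569, 0.599, 0.350, 0.364, 0.370, 0.675,
    0.665, 0.685, 0.546, 0.533, 0.573, 0.446, 0.448, 0.446,
    0.683, 0.670, 0.704, 0.458, 0.416, 0.486, 0.495, 0.495,
    0.504, 0.060, 0.061, 0.055, 0.049, 0.039, 0.052, 0.054,
    0.054, 0.049, 0.042, 0.050, 0.043, 0.043, 0.037, 0.060,
    0.059, 0.056, 0.050, 0.050, 0.045, 0.053, 0.040, 0.032,
    0.046, 0.059, 0.058, 0.059, 0.745, 0.741, 0.754, 0.556,
    0.551, 0.564, 0.653, 0.627, 0.662, 0.775, 0.759, 0.788,
    0.570, 0.581, 0.586, 0.613, 0.587, 0.642, 0.684, 0.667,
    0.700, 0.583, 0.575, 0.589, 0.351, 0.299, 0.428, 0.248,
    0.247, 0.266, 0.194, 0.195, 0.198, 0.243, 0.232, 0.256,
    0.302, 0.286, 0.315, 0.197, 0.194, 0.199, 0.220, 0.205,
    0.244, 0.238, 0.224, 0.253, 0.192, 0.192, 0.198, 0.161,
    0.120, 0.198, 0.172, 0.163, 0.188, 0.146, 0.130, 0.175,
    0.175, 0.180, 0.189, 0.191, 0.184, 0.202, 0.123, 0.107,
    0.148, 0.193, 0.191, 0.195, 0.180, 0.176, 0.201, 0.150,
    0.133, 0.171, 0.133, 0.133, 0.136, 0.638, 0.620, 0.669,
    0.479, 0.440, 0.523, 0.564, 0.542, 0.579, 0.669, 0.665,
    0.687, 0.465, 0.429, 0.499, 0.535, 0.519, 0.545, 0.615,
    0.605, 0.633, 0.442, 0.411, 0.471, 0.383, 0.399, 0.401,
    0.047, 0.039, 0.056, 0.051, 0.051, 0.062, NA, NA,
    NA, 0.057, 0.054, 0.063, 0.055, 0.050, 0.058, 0.030,
    0.035, 0.070, 0.050, 0.049, 0.054, 0.051, 0.049, 0.054,
    0.042, 0.039, 0.057, 0.044, 0.038, 0.043, 0.052, 0.042,
    0.055, 0.046, 0.038, 0.059, 0.048, 0.044, 0.055, 0.059,
    0.056, 0.063, NA, NA, NA, 0.580, 0.563, 0.598,
    0.519, 0.512, 0.534, NA, NA, NA, 0.806, 0.813,
    0.822, 0.715, 0.722, 0.725, 0.087, 0.053, 0.233, 0.897,
    0.900, 0.901, 0.763, 0.776, 0.775, 0.291, 0.254, 0.349,
    0.929, 0.933, 0.936, 0.746, 0.749, 0.759, 0.515, 0.497,
    0.532, 0.929, 0.932, 0.929, 0.682, 0.694, 0.697, 0.647,
    0.646, 0.655, 0.050, 0.054, 0.063, 0.054, 0.053, 0.059,
    0.055, 0.051, 0.057, 0.052, 0.051, 0.053, 0.048, 0.046,
    0.050, 0.058, 0.059, 0.058, 0.054, 0.057, 0.060, 0.056,
    0.060, 0.061, 0.056, 0.053, 0.068, 0.968, 0.975, 0.972,
    0.589, 0.624, 0.599, 0.755, 0.774, 0.765, 0.936, 0.937,
    0.926, 0.595, 0.608, 0.602, 0.698, 0.706, 0.713, 0.737,
    0.761, 0.756, 0.605, 0.632, 0.620, 0.329, 0.293, 0.375)
  tibble::tibble(table = as.integer(tab), effect_label = eff,
                 dist = dst, model = mdl, method = mth, reference = rate)
}
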