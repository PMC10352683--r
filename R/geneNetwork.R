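#' Activation function of the gene network
#'
#' \eqn{\gamma(\xi) = \xi / (1 + \nu \xi^2)}: odd, linear near 0, with a
#' single maximum of \eqn{1/(2\sqrt\nu)} at \eqn{\xi = 1/\sqrt\nu} and decay
#' for larger inputs. Applied element-wise.
#'
#' @param xi numeric input (vectorized).
#' @param nu positive activation parameter.
#' @return numeric of the same length as \code{xi}.
#' @examples
#' activation(1e-3, 1e6)  # 5e-4, the maximum for nu = 1e6
#' @export
activation <- function(xi, nu = 1e6) {
  stopifnot(nu > 0)
  xi / (1 + nu * xi^2)
}

#' Network parameter constructor
#'
#' @param nu activation parameter (default 1e6).
#' @param beta mutation-bias magnitude (default 1e-3).
#' @param bernoulliP success probability of the age-sign flips (default 0.5).
#' @return A [NetworkParams-class].
#' @export
networkParams <- function(nu = 1e6, beta = 1e-3, bernoulliP = 0.5) {
  new("NetworkParams", nu = nu, beta = beta, bernoulliP = bernoulliP)
}

#' Draw per-gene signs for the age weight
#'
#' Each sign is \eqn{2b - 1} with \eqn{b \sim} Bernoulli(\code{p}),
#' independently per gene, redrawn every time-step.
#'
#' @param G number of genes.
#' @param p success probability.
#' @return vector of G values in \{-1, +1\}.
#' @export
drawAgeSigns <- function(G, p = 0.5) {
  stopifnot(G >= 1, p >= 0, p <= 1)
  2L * rbinom(G, 1L, p) - 1L
}

#' Forward pass of the per-cell gene network
#'
#' Maps carcinogen exposure and cell age to the vector of maximum possible
#' per-gene expression changes: fresh age signs are drawn, the input weight
#' matrix is assembled, the hidden layer \eqn{H = \gamma(W_X X)} is computed,
#' and the output is \eqn{Y = \gamma(W_Y H + b)}. Every output is bounded by
#' \eqn{1/(2\sqrt\nu)} in magnitude.
#'
#' @param carcinogenLevels nonnegative exposure vector (length C).
#' @param age nonnegative cell age in time-steps.
#' @param panel a [GenePanel-class].
#' @param bias bias vector (length G), entries in \{-beta, 0, +beta\};
#'   see [mutationBias()].
#' @param params a [NetworkParams-class].
#' @return vector of G maximum expression changes.
#' @examples
#' p <- hnsccPanel()
#' mlpForward(c(0, 0), 0, p, numeric(10))  # exactly zero
#' @export
mlpForward <- function(carcinogenLevels, age, panel, bias = NULL,
                       params = networkParams()) {
  G <- nGenes(panel)
  if (is.null(bias)) bias <- numeric(G)
  if (any(carcinogenLevels < 0) || age < 0)
    stop("network-error: inputs must be nonnegative")
  .cppMlpForward(c(carcinogenLevels, age), panel@WXsigns, panel@ageWeight,
                 panel@WY, bias, params@nu, params@bernoulliP)
}

#' Stochastic expression update
#'
#' Each gene moves by an independent uniform fraction of its maximum change:
#' \eqn{e_j \leftarrow e_j + z_j \bar\delta_j}, \eqn{z_j \sim U(0,1)}.
#' \code{scale} is the calibration factor recorded in run metadata
#' (see the vignette); the default leaves changes unscaled.
#'
#' @param E expression vector.
#' @param deltaBar output of [mlpForward()].
#' @param scale global expression-change calibration factor.
#' @return updated expression vector.
#' @export
updateExpression <- function(E, deltaBar, scale = 1) {
  .cppUpdateExpression(E, deltaBar, scale)
}

#' Mutation bias from current expression
#'
#' Memoryless: \eqn{+\beta} for genes at or above the mutation threshold,
#' \eqn{-\beta} at or below its negative, 0 otherwise. A gene past the
#' threshold therefore drives the network output for itself to the activation
#' maximum, reinforcing the mutation.
#'
#' @param E expression vector.
#' @param MBar positive mutation threshold.
#' @param beta bias magnitude.
#' @return bias vector.
#' @export
mutationBias <- function(E, MBar = 0.1, beta = 1e-3) {
  stopifnot(MBar > 0)
  ifelse(E >= MBar, beta, ifelse(E <= -MBar, -beta, 0))
}

setMethod("show", "NetworkParams", function(object) {
  cat("NetworkParams: nu =", object@nu, " beta =", object@beta,
      " bernoulliP =", object@bernoulliP, "\n")
  cat("  output bound 1/(2*sqrt(nu)) =", 1 / (2 * sqrt(object@nu)), "\n")
})
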