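#' Gaussian carcinogen concentration field
#'
#' \eqn{c(x, y) = \exp(-((x-\mu)^2 + (y-\mu)^2) / (2\sigma^2))} with
#' \eqn{\mu = N/2 - 1} and \eqn{\sigma = N/15}, on 0-based lattice
#' coordinates: peak concentration 1 at the domain middle, decaying radially.
#'
#' @param N lattice size (N x N), at least 2.
#' @param mu center coordinate (default the domain middle, \code{N/2 - 1}).
#' @param sigma width (default \code{N/15}); wider fields expose a larger
#'   share of the tissue.
#' @return N x N matrix with values in (0, 1].
#' @examples
#' f <- gaussianField(128)
#' f[64, 64]  # 1 at (x, y) = (63, 63)
#' @export
gaussianField <- function(N, mu = N / 2 - 1, sigma = N / 15) {
  if (N < 2) stop("config-error: N must be at least 2")
  d <- (seq_len(N) - 1 - mu)^2
  exp(-outer(d, d, "+") / (2 * sigma^2))
}

#' Uniform carcinogen concentration field
#'
#' @param N lattice size.
#' @param level constant concentration in [0, 1].
#' @return N x N constant matrix.
#' @export
uniformField <- function(N, level = 1) {
  if (level < 0 || level > 1) stop("config-error: level must be in [0,1]")
  matrix(level, N, N)
}

#' Carcinogen field constructor
#'
#' @param name label, e.g. "alcohol" or "smoking".
#' @param concentration N x N nonnegative matrix (see
#'   [CarcinogenField-class] for the coordinate convention), or one of the
#'   builders [gaussianField()] / [uniformField()].
#' @param activeFrom,activeTo inclusive step window in which the field is on;
#'   the default schedule is always active.
#' @return A [CarcinogenField-class].
#' @export
carcinogenField <- function(name, concentration, activeFrom = 0,
                            activeTo = Inf) {
  new("CarcinogenField", name = name, concentration = concentration,
      activeFrom = activeFrom, activeTo = activeTo)
}

#' Read a concentration field from a plain-text matrix file
#'
#' Whitespace-separated numeric rows, one lattice row per line.
#'
#' @param file path.
#' @return numeric matrix.
#' @export
readConcentrationField <- function(file) {
  as.matrix(utils::read.table(file, header = FALSE))
}

#' Carcinogen exposure at a lattice site and time
#'
#' Returns one concentration per field, zeroed while the field's schedule is
#' inactive at step \code{t}.
#'
#' @param fields list of [CarcinogenField-class] objects.
#' @param x,y 0-based lattice coordinates ((x, y) = (column, row)).
#' @param t time-step.
#' @return named nonnegative vector, one entry per field.
#' @export
exposureAt <- function(fields, x, y, t) {
  out <- vapply(fields, function(f) {
    if (t >= f@activeFrom && t <= f@activeTo) f@concentration[y + 1, x + 1]
    else 0
  }, numeric(1))
  names(out) <- vapply(fields, function(f) f@name, character(1))
  out
}

setMethod("show", "CarcinogenField", function(object) {
  cat("CarcinogenField '", object@name, "': ",
      nrow(object@concentration), " x ", ncol(object@concentration),
      ", range [", signif(min(object@concentration), 3), ", ",
      signif(max(object@concentration), 3), "], active [",
      object@activeFrom, ", ", object@activeTo, "]\n", sep = "")
})
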