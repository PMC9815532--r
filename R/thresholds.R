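# All policy thresholds are defined as exact roots of the incentive
# differences G, H, P in the variable of interest, so substituting a
# threshold back into its incentive function always yields zero.

new_threshold <- function(value, variable, context, interpretation) {
  structure(list(value = value, variable = variable,
                 context = context, interpretation = interpretation),
            class = "threshold")
}

#' @export
print.threshold <- function(x, ...) {
  ctx <- paste(sprintf("%s = %g", names(x$context), unlist(x$context)),
               collapse = ", ")
  cat(sprintf("threshold %s = %g  (at %s)\n", x$variable, x$value, ctx))
  cat(" ", x$interpretation, "\n")
  invisible(x)
}

#' Online-evaluation threshold steering the provider
#'
#' The critical online-evaluation probability \eqn{w_0} at which the
#' provider's incentive difference \eqn{G(y, z, w)} changes sign, for
#' fixed platform and government probabilities. Above the threshold the
#' provider population evolves to high-quality service; below it, to
#' low-quality service. A threshold outside \eqn{[0,1]} means one strategy
#' dominates for every feasible \eqn{w}.
#'
#' @param p a \code{\link{game_params}} object.
#' @param y platform positive-return-visit probability.
#' @param z government positive-regulation probability.
#' @return A \code{"threshold"} object with fields \code{value},
#'   \code{variable}, \code{context}, \code{interpretation}.
#' @examples
#' threshold_w0(game_params(), y = 0, z = 0)
#' @export
threshold_w0 <- function(p, y, z) {
  den <- (1 - p$gamma) * (p$Is + p$Ds)
  if (abs(den) < 1e-12)
    stop("degenerate coefficient: (1 - gamma) * (Is + Ds) is zero, ",
         "G does not depend on w")
  num <- p$Csh - p$Csl - p$Is * p$gamma - p$Ds * p$gamma - z * p$Fs -
    y * p$Io - (1 - y) * z * p$Io -
    (1 - y) * (1 - z) * (p$beta * p$Fs + p$beta * p$Io)
  new_threshold(num / den, "w0", list(y = y, z = z),
    "w > w0: providers evolve to high-quality service; w < w0: to low-quality service")
}

#' Online-evaluation threshold steering the platform
#'
#' The critical \eqn{w_1} at which the platform's incentive difference
#' \eqn{H(x, z, w)} vanishes for fixed provider and government
#' probabilities. Above it the platform population evolves to positive
#' return visits.
#'
#' @param p a \code{\link{game_params}} object.
#' @param x provider high-quality probability.
#' @param z government positive-regulation probability.
#' @return A \code{"threshold"} object.
#' @export
threshold_w1 <- function(p, x, z) {
  den <- (1 - p$gamma) * (p$Ie + p$De)
  if (abs(den) < 1e-12)
    stop("degenerate coefficient: (1 - gamma) * (Ie + De) is zero, ",
         "H does not depend on w")
  num <- p$Cei - p$S - p$Ie * p$gamma - p$De * p$gamma -
    (1 - x) * (z * p$Fe + (1 - z) * p$beta * p$Fe)
  new_threshold(num / den, "w1", list(x = x, z = z),
    "w > w1: platforms evolve to positive return visits; w < w1: to negative return visits")
}

#' Provider-quality threshold steering the government
#'
#' The critical provider probability \eqn{x_0} at which the government's
#' incentive difference \eqn{P(x, y)} vanishes:
#' \eqn{x_0 = 1 - Cg / [Fs + (1-y) m]} with
#' \eqn{m = Fe - \beta Fs - \beta Fe + \beta Fg}. When providers are
#' mostly high-quality (\eqn{x > x_0}) regulation no longer pays and the
#' government drifts to negative regulation.
#'
#' @param p a \code{\link{game_params}} object.
#' @param y platform positive-return-visit probability.
#' @return A \code{"threshold"} object.
#' @examples
#' threshold_x0(game_params(), y = 1)  # 0.5 at the baseline
#' @export
threshold_x0 <- function(p, y) {
  m <- p$Fe - p$beta * p$Fs - p$beta * p$Fe + p$beta * p$Fg
  den <- p$Fs + (1 - y) * m
  if (abs(den) < 1e-12)
    stop("degenerate coefficient: Fs + (1 - y) * m is zero, ",
         "P has no root in x")
  new_threshold(1 - p$Cg / den, "x0", list(y = y),
    "x > x0: government evolves to negative regulation; x < x0: to positive regulation")
}

#' Minimum provider fine keeping high quality attractive
#'
#' The fine level \eqn{F'_s} at which the provider's incentive difference
#' \eqn{G} vanishes at the given opposing state; fines above it make the
#' high-quality strategy the attractor. The coefficient of \code{Fs} in
#' \eqn{G} is \eqn{z + (1-y)(1-z)\beta}: with no positive regulation and
#' no complaints the fine never bites and no finite threshold exists.
#'
#' @param p a \code{\link{game_params}} object.
#' @param w,y,z opposing-strategy probabilities.
#' @return A \code{"threshold"} object.
#' @export
penalty_threshold_Fs <- function(p, w, y, z) {
  coef <- z + (1 - y) * (1 - z) * p$beta
  if (abs(coef) < 1e-12)
    stop("no finite fine threshold: the coefficient z + (1-y)(1-z)*beta of Fs is zero")
  num <- p$Csh - p$Csl - w * (1 - p$gamma) * (p$Is + p$Ds) -
    p$Is * p$gamma - p$Ds * p$gamma - y * p$Io -
    (1 - y) * ((1 - z) * p$beta * p$Io + z * p$Io)
  new_threshold(num / coef, "Fs'", list(w = w, y = y, z = z),
    "Fs > Fs': providers evolve to high-quality service")
}

#' Minimum platform subsidy keeping positive visits attractive
#'
#' The subsidy \eqn{S'} making the platform's incentive difference
#' \eqn{H} vanish; subsidies above it steer platforms to positive return
#' visits. \eqn{S} enters \eqn{H} with unit coefficient, so the threshold
#' always exists (a negative value means any non-negative subsidy
#' suffices).
#'
#' @param p a \code{\link{game_params}} object.
#' @param w,x,z opposing-strategy probabilities.
#' @return A \code{"threshold"} object.
#' @export
subsidy_threshold_S <- function(p, w, x, z) {
  val <- p$Cei - p$Ie * p$gamma - p$De * p$gamma -
    w * (1 - p$gamma) * (p$Ie + p$De) -
    (1 - x) * (z * p$Fe + (1 - z) * p$beta * p$Fe)
  new_threshold(val, "S'", list(w = w, x = x, z = z),
    "S > S': platforms evolve to positive return visits")
}

#' Minimum superior-government penalty enforcing positive regulation
#'
#' The penalty \eqn{F'_g} imposed by the superior government on the junior
#' government at which the government's incentive difference \eqn{P}
#' vanishes; larger penalties make positive regulation the attractor. The
#' coefficient of \code{Fg} in \eqn{P} is \eqn{(1-x)(1-y)\beta}, so with
#' fully compliant providers, fully active platforms, or no complaints the
#' penalty never reaches the junior government and no finite threshold
#' exists.
#'
#' @param p a \code{\link{game_params}} object.
#' @param x,y opposing-strategy probabilities.
#' @return A \code{"threshold"} object.
#' @export
superior_penalty_threshold_Fg <- function(p, x, y) {
  coef <- (1 - x) * (1 - y) * p$beta
  if (abs(coef) < 1e-12)
    stop("no finite superior-penalty threshold: the coefficient (1-x)(1-y)*beta of Fg is zero")
  num <- p$Cg - (1 - x) * (p$Fs + (1 - y) * (p$Fe - p$beta * p$Fs - p$beta * p$Fe))
  new_threshold(num / coef, "Fg'", list(x = x, y = y),
    "Fg > Fg': government evolves to positive regulation")
}
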