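#' Strategy-volume probabilities
#'
#' Integrates a player's threshold surface over the opposing-probability
#' cube to obtain the volume-based probability of the player settling on
#' each of its two strategies. For providers the surface is the
#' online-evaluation threshold \eqn{w_0(z)} (at a fixed platform
#' probability \code{y}), for platforms \eqn{w_1(x)} (at fixed government
#' probability \code{z}), and for the government the provider threshold
#' \eqn{x_0(y)}, whose integral has the closed form
#' \deqn{V_{z1} = 1 - Cg \ln|1 + m/Fs| / m,\quad
#'       m = Fe - \beta Fs - \beta Fe + \beta Fg,}
#' with the \eqn{m \to 0} limit \eqn{1 - Cg/Fs}.
#'
#' The raw integrals can fall outside \eqn{[0,1]} because the threshold
#' surface itself is unclamped; both the raw (analytically exact) pair,
#' which sums to 1, and the \eqn{[0,1]}-clamped, probability-interpretable
#' pair are returned.
#'
#' \code{V0} is the probability mass of the \emph{second} strategy
#' (low-quality service, negative return visits, negative regulation) and
#' \code{V1} of the first.
#'
#' @param p a \code{\link{game_params}} object.
#' @param which \code{"provider"}, \code{"platform"} or
#'   \code{"government"}.
#' @param fixed the fixed opposing probability: \code{y} for provider
#'   volumes, \code{z} for platform volumes; ignored for the government.
#' @return A list of class \code{"strategy_volumes"} with elements
#'   \code{V0}, \code{V1}, \code{V0_clamped}, \code{V1_clamped},
#'   \code{which}, \code{fixed}.
#' @examples
#' strategy_volumes(game_params(), "government")
#' strategy_volumes(game_params(), "provider", fixed = 0)
#' @export
strategy_volumes <- function(p, which = c("provider", "platform", "government"),
                             fixed = NULL) {
  which <- match.arg(which)
  if (which == "government") {
    if (p$Fs == 0)
      stop("government strategy volume undefined at Fs = 0")
    m <- p$Fe - p$beta * p$Fs - p$beta * p$Fe + p$beta * p$Fg
    V1 <- if (abs(m) < 1e-10) 1 - p$Cg / p$Fs
          else 1 - p$Cg * log(abs(1 + m / p$Fs)) / m
    V0 <- 1 - V1
    fixed <- NULL
  } else if (which == "provider") {
    if (is.null(fixed))
      stop("provider volumes need the fixed platform probability y")
    y <- fixed
    den <- 2 * (1 - p$gamma) * (p$Is + p$Ds)
    if (abs(den) < 1e-12)
      stop("degenerate coefficient: (1 - gamma) * (Is + Ds) is zero")
    a <- p$Csh - p$Csl - p$Is * p$gamma - p$Ds * p$gamma - y * p$Io -
      p$beta * (1 - y) * (p$Fs + p$Io)
    b <- (1 - y) * (p$beta * p$Fs + p$beta * p$Io - p$Io) - p$Fs
    V0 <- (2 * a + b) / den
    V1 <- 1 - V0
  } else {
    if (is.null(fixed))
      stop("platform volumes need the fixed government probability z")
    z <- fixed
    den <- 2 * (1 - p$gamma) * (p$Ie + p$De)
    if (abs(den) < 1e-12)
      stop("degenerate coefficient: (1 - gamma) * (Ie + De) is zero")
    cc <- p$Cei - p$S - p$Ie * p$gamma - p$De * p$gamma
    d <- z * p$Fe + (1 - z) * p$beta * p$Fe
    V0 <- (2 * cc - d) / den
    V1 <- 1 - V0
  }
  clamp01 <- function(v) min(1, max(0, v))
  structure(list(V0 = V0, V1 = V1,
                 V0_clamped = clamp01(V0), V1_clamped = clamp01(V1),
                 which = which, fixed = fixed),
            class = "strategy_volumes")
}

#' @export
print.strategy_volumes <- function(x, ...) {
  lab <- switch(x$which,
    provider = c("low-quality service", "high-quality service"),
    platform = c("negative return visits", "positive return visits"),
    government = c("negative regulation", "positive regulation"))
  cat(sprintf("%s strategy volumes%s\n", x$which,
              if (is.null(x$fixed)) "" else sprintf(" (fixed opposing prob = %g)", x$fixed)))
  cat(sprintf("  V0 (%s): raw %.6f, clamped %.6f\n", lab[1], x$V0, x$V0_clamped))
  cat(sprintf("  V1 (%s): raw %.6f, clamped %.6f\n", lab[2], x$V1, x$V1_clamped))
  invisible(x)
}
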