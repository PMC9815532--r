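#' Simulate the four-party game by fixed-step integration
#'
#' Forward-integrates the replicator vector field on a fixed time grid,
#' reproducing the system-dynamics treatment of the model (the original
#' analysis ran the equivalent stock-flow model in Vensim). The default
#' grid is \code{t = 0} to \code{3} in steps of \code{0.0125} with the
#' forward Euler scheme that fixed-step SD engines use; a classical
#' fourth-order Runge-Kutta scheme is available for verification. After
#' every step each probability is projected back to \eqn{[0,1]} (Euler
#' overshoot at the cube boundary must not produce invalid
#' probabilities); disable with \code{clamp = FALSE}.
#'
#' @param p a \code{\link{game_params}} object.
#' @param init initial \code{\link{strategy_profile}} or length-4 vector;
#'   default \code{c(0.5, 0.5, 0.5, 0.5)}.
#' @param t_initial,t_final,step time grid (defaults 0, 3, 0.0125).
#' @param method \code{"euler"} (default) or \code{"rk4"}.
#' @param clamp project the state to \eqn{[0,1]^4} after every step
#'   (default \code{TRUE}).
#' @param hold optional character vector among \code{c("x","y","z","w")}
#'   naming components to freeze at their initial value (their derivative
#'   is forced to zero), e.g. to study the system at an exogenously fixed
#'   online-evaluation share.
#' @param label optional scenario label stored with the trajectory.
#' @return An object of class \code{"trajectory"}: a \code{data.frame}
#'   with columns \code{t, x, y, z, w} and attributes \code{params},
#'   \code{method}, \code{step}, \code{init}, \code{label}, \code{hold}.
#' @examples
#' tr <- simulate_game(game_params(), t_final = 1)
#' tail(tr, 2)
#' @export
simulate_game <- function(p, init = c(0.5, 0.5, 0.5, 0.5),
                          t_initial = 0, t_final = 3, step = 0.0125,
                          method = c("euler", "rk4"), clamp = TRUE,
                          hold = NULL, label = NULL) {
  method <- match.arg(method)
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  if (t_final <= t_initial) stop("t_final must exceed t_initial")
  s <- as_profile(init)
  if (any(s < 0 | s > 1)) stop("initial state must lie in [0, 1]^4")
  free <- rep(TRUE, 4L)
  if (!is.null(hold)) {
    idx <- match(hold, c("x", "y", "z", "w"))
    if (any(is.na(idx))) stop("hold must name components among x, y, z, w")
    free[idx] <- FALSE
  }
  n <- floor((t_final - t_initial) / step) + 1L
  times <- t_initial + step * (seq_len(n) - 1L)
  out <- matrix(NA_real_, nrow = n, ncol = 4L,
                dimnames = list(NULL, c("x", "y", "z", "w")))
  out[1L, ] <- s
  f <- function(state) as.numeric(replicator_rhs(p, state)) * free
  for (i in seq_len(n - 1L)) {
    s <- if (method == "euler") {
      s + step * f(s)
    } else {
      k1 <- f(s)
      k2 <- f(s + step / 2 * k1)
      k3 <- f(s + step / 2 * k2)
      k4 <- f(s + step * k3)
      s + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(s)))
      stop("integration failure: non-finite state at step ", i,
           " (t = ", format(times[i + 1L]), ")")
    if (clamp) s <- pmin(1, pmax(0, s))
    out[i + 1L, ] <- s
  }
  traj <- data.frame(t = times, out)
  structure(traj, class = c("trajectory", "data.frame"),
            params = p, method = method, step = step,
            init = as_profile(init), label = label, hold = hold)
}

#' @export
print.trajectory <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("replicator trajectory%s: %d steps of %g (%s), t in [%g, %g]\n",
              if (is.null(lbl)) "" else paste0(" '", lbl, "'"),
              nrow(x) - 1L, attr(x, "step"), attr(x, "method"),
              x$t[1L], x$t[nrow(x)]))
  cat("final state: ")
  cat(sprintf("%s = %.4f", c("x", "y", "z", "w"),
              unlist(x[nrow(x), c("x", "y", "z", "w")])), sep = ", ")
  cat("\n")
  invisible(x)
}

#' Plot a trajectory
#'
#' Line plot of the four strategy probabilities against time.
#'
#' @param x a \code{"trajectory"}.
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @export
plot.trajectory <- function(x, ...) {
  graphics::matplot(x$t, as.matrix(x[, c("x", "y", "z", "w")]),
                    type = "l", lty = 1, lwd = 2,
                    col = c("firebrick", "steelblue", "darkgreen", "orange"),
                    xlab = "time", ylab = "strategy probability",
                    ylim = c(0, 1), main = attr(x, "label"), ...)
  graphics::legend("right",
    legend = c("x (provider HQ)", "y (platform PV)",
               "z (government PR)", "w (elderly ON)"),
    col = c("firebrick", "steelblue", "darkgreen", "orange"),
    lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

.strategy_labels <- list(
  x = c("HQ", "LQ"), y = c("PV", "NV"), z = c("PR", "NR"), w = c("ON", "OF"))

#' Which pure strategy has each population converged to?
#'
#' A population counts as converged to its first strategy if its
#' probability stays at or above \code{1 - tol} over the trailing
#' \code{window} grid points, and to its second strategy if it stays at or
#' below \code{tol}; otherwise it is \code{"unresolved"}.
#'
#' @param traj a \code{"trajectory"}.
#' @param tol convergence tolerance (default 0.01).
#' @param window number of trailing grid points that must agree
#'   (default 40).
#' @return Named character vector over \code{x, y, z, w} with values among
#'   the strategy labels (\code{HQ/LQ}, \code{PV/NV}, \code{PR/NR},
#'   \code{ON/OF}) or \code{"unresolved"}.
#' @export
detect_converged_strategy <- function(traj, tol = 0.01, window = 40L) {
  if (window > nrow(traj)) stop("window exceeds trajectory length")
  tail_rows <- traj[seq(nrow(traj) - window + 1L, nrow(traj)),
                    c("x", "y", "z", "w")]
  vapply(c("x", "y", "z", "w"), function(v) {
    col <- tail_rows[[v]]
    if (all(col >= 1 - tol)) .strategy_labels[[v]][1L]
    else if (all(col <= tol)) .strategy_labels[[v]][2L]
    else "unresolved"
  }, character(1))
}

#' Time for a population to cross a probability level
#'
#' First grid time at which the named population's probability crosses
#' \code{level} in the direction of its eventual limit (the trajectory's
#' final value): an upward crossing (\code{>= level}) when the limit lies
#' above the level, a downward crossing (\code{<= level}) otherwise.
#'
#' @param traj a \code{"trajectory"}.
#' @param player \code{"provider"}, \code{"platform"},
#'   \code{"government"}, \code{"elderly"} (or the state names
#'   \code{"x","y","z","w"}).
#' @param level probability level in (0, 1).
#' @return The crossing time, or \code{NA} if the level is never reached.
#' @export
time_to_threshold <- function(traj, player, level = 0.99) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  v <- if (player %in% c("x", "y", "z", "w")) player
       else c(provider = "x", platform = "y",
              government = "z", elderly = "w")[[player]]
  col <- traj[[v]]
  hit <- if (col[length(col)] >= level) col >= level else col <= level
  if (!any(hit)) return(NA_real_)
  traj$t[which(hit)[1L]]
}
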