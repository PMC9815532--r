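#' The sixteen pure-strategy corner equilibria
#'
#' Every vertex of \eqn{[0,1]^4} is a fixed point of the replicator
#' dynamics. Corners are returned in the conventional E1..E16 order used
#' by the model's stability tables: E1-E8 on the offline-evaluation face
#' (\code{w = 0}), E9-E16 on the online face (\code{w = 1}), with the same
#' (x, y, z) sequence within each face.
#'
#' @return A 16 x 4 numeric matrix with rownames \code{E1..E16} and
#'   columns \code{x, y, z, w}.
#' @export
corner_profiles <- function() {
  xyz <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 1))
  m <- rbind(cbind(xyz, 0), cbind(xyz, 1))
  dimnames(m) <- list(paste0("E", 1:16), c("x", "y", "z", "w"))
  m
}

#' Jacobian of the replicator field at a corner
#'
#' At a pure-strategy corner the Jacobian of the replicator system is
#' diagonal: the cross-partials all carry a factor \eqn{x(1-x)} (or its
#' analogue) which vanishes, and the diagonal entries reduce to
#' \eqn{(1-2x)G}, \eqn{(1-2y)H}, \eqn{(1-2z)P}, \eqn{(1-2w)(Cm-Cw)}
#' evaluated at the corner. Its eigenvalues are therefore read off the
#' diagonal.
#'
#' @param p a \code{\link{game_params}} object.
#' @param corner numeric state with every component 0 or 1.
#' @return A 4 x 4 diagonal matrix.
#' @examples
#' corner_jacobian(game_params(), c(1, 1, 0, 1))
#' @export
corner_jacobian <- function(p, corner) {
  corner <- as.numeric(corner)
  if (length(corner) != 4L || any(!(corner %in% c(0, 1))))
    stop("corner_jacobian needs a pure-strategy corner (components 0 or 1); ",
         "for interior states differentiate replicator_rhs numerically")
  diag(as.numeric(replicator_rhs_derivative(p, corner)))
}

#' Classify an equilibrium from its eigenvalues
#'
#' Lyapunov's first method at a hyperbolic fixed point: all eigenvalues
#' negative means local asymptotic stability (an evolutionarily stable
#' strategy, ESS); any positive eigenvalue means instability. Eigenvalues
#' within \code{tol} of zero make the corner non-hyperbolic and the
#' linearization inconclusive, reported as \code{"indeterminate"}.
#'
#' @param eigs numeric vector of (real) eigenvalues.
#' @param tol classification tolerance (default \code{1e-9}).
#' @return \code{"ESS"}, \code{"unstable"} or \code{"indeterminate"}.
#' @export
classify_eigenvalues <- function(eigs, tol = 1e-9) {
  if (any(!is.finite(eigs))) stop("eigenvalues must be finite")
  if (any(eigs > tol)) return("unstable")
  if (all(eigs < -tol)) return("ESS")
  "indeterminate"
}

#' Stability report over all sixteen corner equilibria
#'
#' Evaluates the corner Jacobian eigenvalues at \code{p}, classifies each
#' corner by Lyapunov's first method, and flags the corners that are
#' unstable for \emph{every} admissible calibration. The latter is decided
#' by sign-sampling: an eigenvalue slot (such as the government entry
#' \eqn{+Cg} at the corners where a high-quality provider meets positive
#' regulation) that is positive in all of \code{n_draws} random admissible
#' parameter sets marks the corner unconditionally unstable. At the
#' all-cooperate corner the first eigenvalue is taken as
#' \eqn{-G(1,1,1) = Csh-Csl-Is-Ds-Fs-Io} from the incentive algebra; some
#' published tabulations carry an extra \eqn{-S} term there that the
#' model's own expected-utility layer does not produce.
#'
#' @param p a \code{\link{game_params}} object.
#' @param tol classification tolerance, see
#'   \code{\link{classify_eigenvalues}}.
#' @param n_draws number of random admissible parameter draws used for the
#'   \code{always_unstable} flags (default 1000).
#' @return An object of class \code{"stability_report"}: a list with a
#'   16-row \code{data.frame} (\code{$table}) holding corner name,
#'   coordinates, the four eigenvalues, the stability label and the
#'   \code{always_unstable} flag, plus \code{$ess} (names of the ESS
#'   corners) and the parameter set used.
#' @examples
#' rep <- stability(game_params(), n_draws = 200)
#' rep$ess
#' @export
stability <- function(p, tol = 1e-9, n_draws = 1000L) {
  corners <- corner_profiles()
  eigs <- t(apply(corners, 1L, function(cr)
    as.numeric(replicator_rhs_derivative(p, cr))))
  colnames(eigs) <- paste0("lambda", 1:4)
  label <- apply(eigs, 1L, classify_eigenvalues, tol = tol)
  always <- always_unstable_flags(n_draws)
  tab <- data.frame(corner = rownames(corners), corners, eigs,
                    label = label, always_unstable = always,
                    row.names = NULL, check.names = FALSE)
  structure(list(table = tab, ess = tab$corner[tab$label == "ESS"],
                 params = p, tol = tol, n_draws = n_draws),
            class = "stability_report")
}

# Sign-sample the symbolic eigenvalue pattern: a corner is flagged when some
# eigenvalue slot is positive in every random admissible draw.
always_unstable_flags <- function(n_draws) {
  corners <- corner_profiles()
  draws <- random_game_params(n_draws)
  pos_all <- matrix(TRUE, nrow = 16L, ncol = 4L)
  for (q in draws) {
    e <- t(apply(corners, 1L, function(cr)
      as.numeric(replicator_rhs_derivative(q, cr))))
    pos_all <- pos_all & (e > 0)
  }
  stats::setNames(apply(pos_all, 1L, any), rownames(corners))
}

#' @export
print.stability_report <- function(x, digits = 4, ...) {
  cat("Corner-equilibrium stability (Lyapunov first method)\n")
  tab <- x$table
  tab[paste0("lambda", 1:4)] <- lapply(tab[paste0("lambda", 1:4)], round, digits)
  print(tab, row.names = FALSE)
  if (length(x$ess))
    cat("\nESS at this calibration:", paste(x$ess, collapse = ", "), "\n")
  else
    cat("\nNo ESS at this calibration\n")
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  tab <- object$table
  cat(sprintf("16 corner equilibria: %d ESS, %d unstable, %d indeterminate\n",
              sum(tab$label == "ESS"), sum(tab$label == "unstable"),
              sum(tab$label == "indeterminate")))
  cat("Always-unstable corners:",
      paste(tab$corner[tab$always_unstable], collapse = ", "), "\n")
  invisible(object)
}

#' @export
as.data.frame.stability_report <- function(x, ...) x$table
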