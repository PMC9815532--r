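# Sensitivity-scenario suites: each variant is a list of absolute parameter
# overrides (`set`), multiplicative scalings (`scale`) and initial-state
# overrides (`init`), applied to a base calibration at run time.

new_scenario <- function(id, description, variants) {
  structure(list(id = id, description = description, variants = variants),
            class = "scenario_spec")
}

variant <- function(label, set = NULL, scale = NULL, init = NULL) {
  bad <- c(setdiff(names(set), param_names()),
           setdiff(names(scale), param_names()),
           setdiff(names(init), c("x", "y", "z", "w")))
  if (length(bad))
    stop("scenario variant '", label, "' overrides unknown field(s): ",
         paste(bad, collapse = ", "))
  list(label = label, set = set, scale = scale, init = init)
}

#' Built-in policy-sensitivity scenario suites
#'
#' The five sensitivity suites of the model's simulation study, each a set
#' of variants around the baseline calibration:
#' \describe{
#'   \item{\code{penalty_provider}}{provider fine \code{Fs} and
#'     compensation \code{Io} fluctuated 50\% down/up
#'     (\code{Fs} in 10/20/30, \code{Io} in 5/10/15).}
#'   \item{\code{penalty_subsidy_platform}}{platform fine \code{Fe} in
#'     2.5/5/7.5 and subsidy \code{S} in 5/10/15.}
#'   \item{\code{online_evaluation}}{initial online-evaluation share
#'     \code{w} started at 0.25 vs 0.75 (the share still evolves).}
#'   \item{\code{reputation}}{the four reputational parameters
#'     \code{Is, Ds, Ie, De} jointly scaled by 0.5 and by 1.5.}
#'   \item{\code{complaint_rate}}{elderly complaint rate \code{beta} at
#'     0.01 vs 0.41.}
#' }
#'
#' @return Named list of \code{"scenario_spec"} objects.
#' @export
builtin_scenarios <- function() {
  list(
    penalty_provider = new_scenario("penalty_provider",
      "provider fine Fs and compensation Io fluctuated 50% down/up",
      c(lapply(c(10, 20, 30), function(v)
          variant(sprintf("Fs=%g", v), set = c(Fs = v))),
        lapply(c(5, 10, 15), function(v)
          variant(sprintf("Io=%g", v), set = c(Io = v))))),
    penalty_subsidy_platform = new_scenario("penalty_subsidy_platform",
      "platform fine Fe and subsidy S fluctuated 50% down/up",
      c(lapply(c(2.5, 5, 7.5), function(v)
          variant(sprintf("Fe=%g", v), set = c(Fe = v))),
        lapply(c(5, 10, 15), function(v)
          variant(sprintf("S=%g", v), set = c(S = v))))),
    online_evaluation = new_scenario("online_evaluation",
      "initial online-evaluation share w started low vs high",
      lapply(c(0.25, 0.75), function(v)
        variant(sprintf("w0=%g", v), init = c(w = v)))),
    reputation = new_scenario("reputation",
      "reputational gains/losses Is, Ds, Ie, De jointly moved 50% down/up",
      lapply(c(0.5, 1.5), function(k)
        variant(sprintf("reputation x%g", k),
                scale = c(Is = k, Ds = k, Ie = k, De = k)))),
    complaint_rate = new_scenario("complaint_rate",
      "elderly complaint rate beta low vs high",
      lapply(c(0.01, 0.41), function(v)
        variant(sprintf("beta=%g", v), set = c(beta = v))))
  )
}

# Apply a variant's parameter edits to a base calibration (always a copy).
apply_variant_params <- function(p, v) {
  q <- p
  for (nm in names(v$set)) q <- do.call(game_params,
    utils::modifyList(unclass(q), stats::setNames(list(v$set[[nm]]), nm)))
  for (nm in names(v$scale)) q <- scale_param(q, nm, v$scale[[nm]])
  q
}

apply_variant_init <- function(init, v) {
  s <- as_profile(init)
  for (nm in names(v$init)) s[[nm]] <- v$init[[nm]]
  s
}

#' Run a sensitivity-scenario suite
#'
#' Integrates every variant of a scenario from the same base calibration
#' and initial state, attaching per-variant convergence labels and
#' time-to-threshold values so that the variants' evolution speeds can be
#' compared. A variant whose integration fails is recorded with its error
#' message; the rest of the suite still runs.
#'
#' @param p base \code{\link{game_params}}.
#' @param spec a \code{"scenario_spec"} from
#'   \code{\link{builtin_scenarios}}.
#' @param init shared initial state (default \code{c(0.5,0.5,0.5,0.5)});
#'   variants may override components.
#' @param level probability level for the time-to-threshold table
#'   (default 0.99).
#' @param conv_tol,window convergence-detection settings, see
#'   \code{\link{detect_converged_strategy}}.
#' @param ... further arguments to \code{\link{simulate_game}}
#'   (\code{t_final}, \code{step}, \code{method}, ...).
#' @return An object of class \code{"scenario_result"}: list with the
#'   spec, the named list of trajectories (\code{NULL} where a variant
#'   failed), a \code{convergence} data.frame (variant x player labels),
#'   a \code{times} data.frame of threshold-crossing times per player,
#'   and \code{errors}.
#' @export
run_scenario_suite <- function(p, spec, init = c(0.5, 0.5, 0.5, 0.5),
                               level = 0.99, conv_tol = 0.01, window = 40L,
                               ...) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  labels <- vapply(spec$variants, `[[`, character(1), "label")
  trajs <- stats::setNames(vector("list", length(labels)), labels)
  errors <- stats::setNames(rep(NA_character_, length(labels)), labels)
  conv <- times <- NULL
  for (i in seq_along(spec$variants)) {
    v <- spec$variants[[i]]
    res <- tryCatch({
      q <- apply_variant_params(p, v)
      s0 <- apply_variant_init(init, v)
      simulate_game(q, init = s0, label = v$label, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
      conv <- rbind(conv, rep(NA_character_, 4L))
      times <- rbind(times, rep(NA_real_, 4L))
      next
    }
    trajs[[i]] <- res
    conv <- rbind(conv, detect_converged_strategy(res, conv_tol, window))
    times <- rbind(times, vapply(c("x", "y", "z", "w"),
      function(v2) time_to_threshold(res, v2, level), numeric(1)))
  }
  conv <- data.frame(variant = labels, conv, row.names = NULL)
  names(conv)[-1L] <- c("provider", "platform", "government", "elderly")
  times <- data.frame(variant = labels, times, row.names = NULL)
  names(times)[-1L] <- c("provider", "platform", "government", "elderly")
  structure(list(spec = spec, trajectories = trajs, convergence = conv,
                 times = times, errors = errors, level = level, init = init),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario suite:", x$spec$id, "-", x$spec$description, "\n")
  cat(sprintf("time to cross level %g (per player):\n", x$level))
  print(x$times, row.names = FALSE)
  cat("converged strategies:\n")
  print(x$convergence, row.names = FALSE)
  failed <- names(x$errors)[!is.na(x$errors)]
  if (length(failed)) cat("failed variants:", paste(failed, collapse = ", "), "\n")
  invisible(x)
}
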