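#' Game parameters for the elderly-care regulation game
#'
#' Constructs the full parameter set of the four-party evolutionary game
#' between elderly-care service providers, service information platforms,
#' the government, and elderly consumers. Called with no arguments it
#' returns the canonical baseline calibration; any subset of fields may be
#' overridden by name.
#'
#' Monetary quantities (revenues, costs, fines, subsidies, reputational
#' gains/losses) are in abstract currency units and must be non-negative.
#' The three rates \code{alpha} (platform commission share), \code{beta}
#' (elderly complaint rate) and \code{gamma} (relative size of the offline
#' social network) are fractions in [0, 1]. The provider fine \code{Fs} is
#' the administrative penalty levied by the government on providers caught
#' delivering low-quality service, distinct from the compensation \code{Io}
#' the provider pays to the affected elderly.
#'
#' @param ... named overrides of baseline fields (e.g. \code{Fs = 30}).
#'   Unknown names are an error.
#' @param .check validate the resulting set and error on violations
#'   (default \code{TRUE}).
#'
#' @return An object of class \code{"game_params"}: a named list of the 25
#'   scalar model constants.
#'
#' @section Fields:
#' \describe{
#'   \item{Rs, alpha}{total provider+platform revenue; platform commission share.}
#'   \item{Csh, Csl}{provider cost of high-/low-quality service (\code{Csh > Csl}).}
#'   \item{Io, Fs}{compensation to the elderly and government fine, both due on
#'     low-quality service.}
#'   \item{Is, Ds}{provider reputational gain (high quality) / loss (low quality).}
#'   \item{Cei, Ceo, S, Fe, Ie, De}{platform return-visit cost, operating cost,
#'     government subsidy, government fine, reputational gain/loss.}
#'   \item{Cg, Fg, Rg, Dg}{government regulation cost, superior-government
#'     penalty, social welfare from high quality, social loss from low quality.}
#'   \item{Cw, Cm, Ro, Do, Co}{elderly online/offline evaluation costs, gain
#'     utility, damage from low quality, complaint cost.}
#'   \item{beta, gamma}{complaint rate; offline social-network size.}
#' }
#'
#' @examples
#' p <- game_params()
#' p$Fs
#' q <- game_params(Fs = 30, S = 15)
#' @export
game_params <- function(..., .check = TRUE) {
  p <- baseline_values()
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    for (nm in names(ov)) {
      v <- ov[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("parameter '", nm, "' must be a single finite number")
      p[[nm]] <- as.numeric(v)
    }
  }
  obj <- structure(p, class = "game_params")
  if (.check) {
    rep <- validate_params(obj)
    if (!rep$ok)
      stop("invalid parameter set:\n  ", paste(rep$violations, collapse = "\n  "))
  }
  obj
}

# Baseline calibration; rates stored as fractions (alpha = 10% -> 0.10).
baseline_values <- function() {
  list(
    Rs = 100, Csh = 50, Csl = 25, Is = 20, Ds = 22,
    S = 10, Ceo = 15, Cei = 5, Ie = 10, De = 12,
    alpha = 0.10, beta = 0.01, gamma = 0.05,
    Fs = 20, Fe = 5, Fg = 200, Rg = 40, Cg = 10, Dg = 40,
    Cm = 10, Cw = 8, Io = 10, Ro = 20, Do = 30, Co = 5
  )
}

#' Names of the game-parameter fields
#' @return Character vector of the 25 field names.
#' @export
param_names <- function() names(baseline_values())

.rate_fields <- c("alpha", "beta", "gamma")

#' Validate a parameter set
#'
#' Checks the model's admissibility bounds: every monetary magnitude
#' non-negative, every rate in [0, 1], and the high-quality cost exceeding
#' the low-quality cost (\code{Csh > Csl}). Violations are reported, never
#' raised, so scenario sweeps can surface them to the caller.
#'
#' @param p a \code{game_params} object (or plain named list with the same
#'   fields).
#' @return A list of class \code{"validation_report"} with elements
#'   \code{ok} (logical) and \code{violations} (character vector; empty iff
#'   \code{ok}).
#' @examples
#' validate_params(game_params())$ok
#' @export
validate_params <- function(p) {
  v <- character(0)
  for (nm in param_names()) {
    val <- p[[nm]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      v <- c(v, sprintf("%s: missing or non-finite", nm))
      next
    }
    if (nm %in% .rate_fields) {
      if (val < 0 || val > 1)
        v <- c(v, sprintf("%s = %g outside [0, 1]", nm, val))
    } else if (val < 0) {
      v <- c(v, sprintf("%s = %g is negative", nm, val))
    }
  }
  if (is.numeric(p[["Csh"]]) && is.numeric(p[["Csl"]]) &&
      is.finite(p[["Csh"]]) && is.finite(p[["Csl"]]) &&
      p[["Csh"]] <= p[["Csl"]])
    v <- c(v, sprintf("Csh = %g must exceed Csl = %g (high-quality service costs more)",
                      p[["Csh"]], p[["Csl"]]))
  structure(list(ok = length(v) == 0L, violations = v),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("parameter set OK\n")
  else cat("parameter set INVALID:\n", paste0("  - ", x$violations, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Scale one parameter by a positive factor
#'
#' Returns a copy of \code{p} with a single field multiplied by
#' \code{factor}; all other fields are untouched. This is the elementary
#' move of the sensitivity scenarios (e.g. fluctuating the provider fine
#' \code{Fs} up and down by 50\%).
#'
#' @param p a \code{game_params} object.
#' @param name field name to scale.
#' @param factor positive scalar multiplier.
#' @return A new \code{game_params} object.
#' @examples
#' scale_param(game_params(), "Fs", 1.5)$Fs  # 30
#' @export
scale_param <- function(p, name, factor) {
  if (!name %in% param_names())
    stop("unknown parameter field: ", name)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("factor must be a single positive number")
  q <- unclass(p)
  q[[name]] <- q[[name]] * factor
  q <- structure(q, class = "game_params")
  rep <- validate_params(q)
  if (!rep$ok)
    stop("scaling ", name, " by ", factor, " breaks parameter bounds:\n  ",
         paste(rep$violations, collapse = "\n  "))
  q
}

#' @export
print.game_params <- function(x, ...) {
  cat("Elderly-care regulation game parameters\n")
  vals <- unlist(unclass(x))
  print(vals)
  invisible(x)
}

#' Strategy profile (x, y, z, w)
#'
#' The mixed state of the four populations: \code{x} probability a provider
#' offers high-quality service, \code{y} probability a platform makes
#' positive return visits, \code{z} probability the government regulates
#' positively, \code{w} probability an elderly person evaluates online.
#'
#' @param x,y,z,w probabilities in [0, 1]; may also be given as a single
#'   numeric vector of length 4 in \code{x}.
#' @return Named numeric vector \code{c(x, y, z, w)} of class
#'   \code{"strategy_profile"}.
#' @examples
#' strategy_profile(0.5, 0.5, 0.5, 0.5)
#' @export
strategy_profile <- function(x, y = NULL, z = NULL, w = NULL) {
  if (length(x) == 4L && is.null(y)) {
    s <- as.numeric(x)
  } else {
    s <- c(x, y, z, w)
  }
  if (length(s) != 4L || !is.numeric(s) || any(!is.finite(s)))
    stop("a strategy profile is four finite probabilities (x, y, z, w)")
  if (any(s < 0 | s > 1))
    stop("strategy probabilities must lie in [0, 1]")
  structure(stats::setNames(s, c("x", "y", "z", "w")),
            class = "strategy_profile")
}

# Internal: accept a strategy_profile or a bare length-4 vector.
as_profile <- function(s) {
  if (inherits(s, "strategy_profile")) return(unclass(s))
  s <- as.numeric(s)
  if (length(s) != 4L || any(!is.finite(s)))
    stop("expected a strategy profile (x, y, z, w)")
  stats::setNames(s, c("x", "y", "z", "w"))
}

#' Draw random admissible parameter sets
#'
#' Samples parameter sets within admissible bounds: every monetary
#' magnitude log-uniform on (0.1, 100) (so that draws span scales and
#' sums of parameters do not swamp individual ones), every rate uniform
#' on (0, 1), with \code{Csh > Csl} enforced by swapping. Used by
#' \code{\link{stability}} to decide which corner eigenvalues are positive
#' for every admissible calibration, and by the package's property tests.
#'
#' @param n number of draws.
#' @return A list of \code{n} \code{game_params} objects.
#' @export
random_game_params <- function(n = 1L) {
  nm <- param_names()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- baseline_values()
    for (f in nm) {
      p[[f]] <- if (f %in% .rate_fields) stats::runif(1) else 10^stats::runif(1, -1, 2)
    }
    if (p$Csh <= p$Csl) {
      tmp <- p$Csh; p$Csh <- p$Csl; p$Csl <- tmp
      if (p$Csh == p$Csl) p$Csh <- p$Csh + 0.1
    }
    out[[i]] <- structure(p, class = "game_params")
  }
  out
}

#' Read a parameter set from a YAML or JSON config file
#'
#' The file must be a flat mapping of field names to scalars. Missing
#' fields fall back to the baseline; unknown keys are an error so that
#' typos in scenario configs cannot silently revert to defaults.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{game_params} object.
#' @export
read_game_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '", ext, "' (use YAML or JSON)"))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) vals <- as.list(vals)
  bad <- setdiff(names(vals), param_names())
  if (length(bad))
    stop("unknown parameter key(s) in ", path, ": ", paste(bad, collapse = ", "))
  do.call(game_params, vals)
}

#' Write a parameter set to a YAML or JSON config file
#' @param p a \code{game_params} object.
#' @param path destination ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_game_params <- function(p, path) {
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(p)
  switch(ext,
    "yaml" = , "yml" = yaml::write_yaml(vals, path),
    "json" = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format '", ext, "' (use YAML or JSON)"))
  invisible(path)
}
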