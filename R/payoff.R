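#' Payoffs for one pure-strategy combination
#'
#' Evaluates one cell of the 16-cell payoff matrix of the four-party game.
#' Each player has two pure strategies: providers offer high- (\code{"HQ"})
#' or low-quality (\code{"LQ"}) service; platforms make positive
#' (\code{"PV"}) or negative (\code{"NV"}) return visits; the government
#' regulates positively (\code{"PR"}) or negatively (\code{"NR"}); the
#' elderly evaluate online (\code{"ON"}) or offline (\code{"OF"}).
#'
#' Reputational gains and losses are discounted by the offline
#' social-network size \code{gamma} when the elderly evaluate offline.
#' Under low-quality service with a negative return visit and negative
#' regulation, sanctions only arrive via elderly complaints, so the fines
#' \code{Fs}, \code{Fe}, the superior penalty \code{Fg}, the compensation
#' \code{Io} and the complaint cost \code{Co} are all discounted by the
#' complaint rate \code{beta}.
#'
#' @param p a \code{\link{game_params}} object.
#' @param provider \code{"HQ"} or \code{"LQ"}.
#' @param platform \code{"PV"} or \code{"NV"}.
#' @param government \code{"PR"} or \code{"NR"}.
#' @param elderly \code{"ON"} or \code{"OF"}.
#' @return Named numeric vector with elements \code{provider},
#'   \code{platform}, \code{government}, \code{elderly}.
#' @examples
#' payoff_cell(game_params(), "HQ", "PV", "PR", "ON")
#' @export
payoff_cell <- function(p, provider, platform, government, elderly) {
  provider   <- match.arg(provider,   c("HQ", "LQ"))
  platform   <- match.arg(platform,   c("PV", "NV"))
  government <- match.arg(government, c("PR", "NR"))
  elderly    <- match.arg(elderly,    c("ON", "OF"))

  hq <- provider == "HQ"; pv <- platform == "PV"
  pr <- government == "PR"; on <- elderly == "ON"

  # reputational terms carry the full weight online, gamma-discounted offline
  rep_s_gain <- if (on) p$Is else p$Is * p$gamma
  rep_s_loss <- if (on) p$Ds else p$Ds * p$gamma
  rep_e_gain <- if (on) p$Ie else p$Ie * p$gamma
  rep_e_loss <- if (on) p$De else p$De * p$gamma
  eval_cost  <- if (on) p$Cw else p$Cm

  if (hq) {
    sp <- (1 - p$alpha) * p$Rs - p$Csh + rep_s_gain
    ep <- if (pv) p$alpha * p$Rs - p$Cei - p$Ceo + p$S + rep_e_gain
          else    p$alpha * p$Rs - p$Ceo - rep_e_loss
    gp <- p$Rg - (if (pr) p$Cg else 0) - (if (pv) p$S else 0)
    op <- p$Ro - eval_cost
  } else if (pv) {
    if (pr) {
      sp <- (1 - p$alpha) * p$Rs - p$Csl - p$Io - p$Fs - rep_s_loss
      gp <- p$Fs - p$S - p$Cg - p$Dg
    } else {
      sp <- (1 - p$alpha) * p$Rs - p$Csl - rep_s_loss - p$Io
      gp <- -p$S - p$Dg
    }
    ep <- p$alpha * p$Rs - p$Cei - p$Ceo + p$S + rep_e_gain
    op <- p$Io - eval_cost - p$Do
  } else if (pr) {
    sp <- (1 - p$alpha) * p$Rs - p$Csl - p$Io - p$Fs - rep_s_loss
    ep <- p$alpha * p$Rs - p$Ceo - p$Fe - rep_e_loss
    gp <- p$Fs + p$Fe - p$Cg - p$Dg
    op <- p$Io - eval_cost - p$Do
  } else {
    # LQ, NV, NR: sanctions arrive only through complaints (rate beta)
    sp <- (1 - p$alpha) * p$Rs - p$Csl - p$beta * p$Fs - rep_s_loss - p$beta * p$Io
    ep <- p$alpha * p$Rs - p$Ceo - p$beta * p$Fe - rep_e_loss
    gp <- p$beta * (p$Fs + p$Fe - p$Fg) - p$Dg
    op <- p$beta * (p$Io - p$Co) - eval_cost - p$Do
  }
  c(provider = sp, platform = ep, government = gp, elderly = op)
}

#' Full 16-row payoff table
#'
#' All sixteen pure-strategy combinations with the four players' payoffs,
#' suitable for CSV export and regression snapshots. Rows are ordered
#' provider-major (HQ first), then platform (PV first), government (PR
#' first) and elderly (ON first).
#'
#' @param p a \code{\link{game_params}} object.
#' @return A \code{data.frame} with columns \code{provider},
#'   \code{platform}, \code{government}, \code{elderly} (strategy labels)
#'   and \code{provider_payoff}, \code{platform_payoff},
#'   \code{government_payoff}, \code{elderly_payoff}.
#' @export
payoff_table <- function(p) {
  combos <- expand.grid(elderly = c("ON", "OF"), government = c("PR", "NR"),
                        platform = c("PV", "NV"), provider = c("HQ", "LQ"),
                        stringsAsFactors = FALSE)[, 4:1]
  pay <- t(apply(combos, 1L, function(r)
    payoff_cell(p, r[["provider"]], r[["platform"]], r[["government"]], r[["elderly"]])))
  out <- cbind(combos,
               provider_payoff = pay[, "provider"],
               platform_payoff = pay[, "platform"],
               government_payoff = pay[, "government"],
               elderly_payoff = pay[, "elderly"])
  rownames(out) <- NULL
  out
}

.players <- c("provider", "platform", "government", "elderly")

#' Expected utilities of a player's two pure strategies
#'
#' For the chosen player, returns the expected payoff of its first strategy
#' (high quality / positive visits / positive regulation / online
#' evaluation), of its second strategy, and the population-average expected
#' payoff under its own mixing probability. These are the closed-form
#' expectation expressions of the model, taken over the opposing players'
#' mixed strategies.
#'
#' @param p a \code{\link{game_params}} object.
#' @param s a \code{\link{strategy_profile}} (or length-4 vector
#'   \code{c(x, y, z, w)}).
#' @param player one of \code{"provider"}, \code{"platform"},
#'   \code{"government"}, \code{"elderly"}.
#' @return Named numeric vector \code{c(U1, U2, U_avg)}.
#' @examples
#' expected_utilities(game_params(), c(0.5, 1, 1, 1), "provider")
#' @export
expected_utilities <- function(p, s, player = .players) {
  player <- match.arg(player)
  s <- as_profile(s)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]; w <- s[["w"]]
  switch(player,
    provider = {
      U1 <- (1 - p$alpha) * p$Rs - p$Csh + w * p$Is + (1 - w) * p$Is * p$gamma
      U2 <- (1 - p$alpha) * p$Rs - p$Csl - w * p$Ds - (1 - w) * p$Ds * p$gamma -
        z * p$Fs - y * p$Io - (1 - y) * z * p$Io -
        (1 - y) * (1 - z) * (p$beta * p$Fs + p$beta * p$Io)
      prob <- x
    },
    platform = {
      U1 <- p$alpha * p$Rs - p$Ceo - p$Cei + w * p$Ie + (1 - w) * p$Ie * p$gamma + p$S
      U2 <- p$alpha * p$Rs - p$Ceo - w * p$De - (1 - w) * p$De * p$gamma -
        (1 - x) * (z * p$Fe + (1 - z) * p$beta * p$Fe)
      prob <- y
    },
    government = {
      U1 <- x * p$Rg - y * p$S - p$Cg +
        (1 - x) * (p$Fs - p$Dg + (1 - y) * p$Fe)
      U2 <- x * p$Rg - y * p$S +
        (1 - x) * ((1 - y) * p$beta * (p$Fs + p$Fe - p$Fg) - p$Dg)
      prob <- z
    },
    elderly = {
      common <- x * p$Ro + (1 - x) * ((1 - y) * z * p$Io +
        p$beta * (1 - y) * (1 - z) * (p$Io - p$Co) + y * p$Io - p$Do)
      U1 <- common - p$Cw
      U2 <- common - p$Cm
      prob <- w
    })
  c(U1 = U1, U2 = U2, U_avg = prob * U1 + (1 - prob) * U2)
}

#' Incentive difference driving a player's replicator flow
#'
#' The expected payoff of a player's first strategy minus its second, as a
#' function of the other populations' mixing probabilities: \code{G(y,z,w)}
#' for providers, \code{H(x,z,w)} for platforms, \code{P(x,y)} for the
#' government, and the constant \code{Cm - Cw} for the elderly. The sign of
#' this difference is what pushes the replicator dynamics toward one pure
#' strategy or the other.
#'
#' @inheritParams expected_utilities
#' @return A single number.
#' @examples
#' incentive_difference(game_params(), c(0, 1, 1, 1), "provider")  # G(1,1,1)
#' @export
incentive_difference <- function(p, s, player = .players) {
  player <- match.arg(player)
  s <- as_profile(s)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]; w <- s[["w"]]
  switch(player,
    provider =
      w * (1 - p$gamma) * (p$Is + p$Ds) + z * p$Fs + p$Csl - p$Csh +
        p$Is * p$gamma + p$Ds * p$gamma + y * p$Io + (1 - y) * z * p$Io +
        (1 - y) * (1 - z) * (p$beta * p$Fs + p$beta * p$Io),
    platform =
      w * (1 - p$gamma) * (p$Ie + p$De) + p$Ie * p$gamma + p$De * p$gamma +
        p$S - p$Cei + (1 - x) * (z * p$Fe + (1 - z) * p$beta * p$Fe),
    government =
      (1 - x) * (p$Fs + (1 - y) * p$Fe -
                   (1 - y) * p$beta * (p$Fs + p$Fe - p$Fg)) - p$Cg,
    elderly = p$Cm - p$Cw)
}
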