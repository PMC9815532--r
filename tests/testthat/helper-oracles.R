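# Independent oracles used across the suite. These re-derive quantities
# from first principles (brute-force enumeration, quadrature, closed
# forms) and never call the code paths they check.

player_labels <- list(
  provider = c("HQ", "LQ"), platform = c("PV", "NV"),
  government = c("PR", "NR"), elderly = c("ON", "OF"))

# Expected payoff of each pure strategy of `player`, by brute-force
# enumeration of the 8 opposing pure-strategy combinations weighted by
# the opponents' mixing probabilities.
brute_expected <- function(p, s, player) {
  s <- stats::setNames(as.numeric(s), c("x", "y", "z", "w"))
  prob1 <- c(provider = s[["x"]], platform = s[["y"]],
             government = s[["z"]], elderly = s[["w"]])
  others <- setdiff(names(player_labels), player)
  U <- numeric(2)
  for (k in 1:2) {
    tot <- 0
    for (i in 0:1) for (j in 0:1) for (l in 0:1) {
      pick <- c(i, j, l)
      choice <- list()
      choice[[player]] <- player_labels[[player]][k]
      pr <- 1
      for (t in seq_along(others)) {
        o <- others[t]
        first <- pick[t] == 0L
        choice[[o]] <- player_labels[[o]][if (first) 1L else 2L]
        pr <- pr * if (first) prob1[[o]] else 1 - prob1[[o]]
      }
      pay <- payoff_cell(p, choice$provider, choice$platform,
                         choice$government, choice$elderly)
      tot <- tot + pr * pay[[player]]
    }
    U[k] <- tot
  }
  U
}

# The published corner-eigenvalue expressions (offline face with the
# gamma-discounted reputational terms, online face undiscounted), with
# the all-cooperate corner's first eigenvalue taken from the incentive
# algebra (no spurious -S term). Returns a 16 x 4 matrix in E1..E16 order.
table_eigenvalues <- function(p) {
  with(unclass(p), {
    off <- rbind(
      c(Is*gamma + Csl - Csh + Ds*gamma + beta*Fs + beta*Io,
        Ie*gamma - Cei + S + De*gamma + beta*Fe,
        Fs + Fe - beta*Fs - beta*Fe + beta*Fg - Cg, Cm - Cw),
      c(Csh - Csl - Is*gamma - Ds*gamma - beta*Fs - beta*Io,
        Ie*gamma + De*gamma + S - Cei, -Cg, Cm - Cw),
      c(Is*gamma + Csl - Csh + Ds*gamma + Io,
        Cei - Ie*gamma - De*gamma - S - beta*Fe, Fs - Cg, Cm - Cw),
      c(Is*gamma + Fs + Csl - Csh + Ds*gamma + Io,
        Ie*gamma - Cei + De*gamma + S + Fe,
        beta*Fe + beta*Fs + Cg - Fs - Fe - beta*Fg, Cm - Cw),
      c(Csh - Csl - Is*gamma - Ds*gamma - Io,
        Cei - Ie*gamma - De*gamma - S, -Cg, Cm - Cw),
      c(Is*gamma + Fs + Csl - Csh + Ds*gamma + Io,
        Cei - Ie*gamma - De*gamma - S - Fe, Cg - Fs, Cm - Cw),
      c(Csh - Csl - Is*gamma - Ds*gamma - Fs - Io,
        Ie*gamma - Cei + De*gamma + S, Cg, Cm - Cw),
      c(Csh - Csl - Is*gamma - Ds*gamma - Fs - Io,
        Cei - Ie*gamma - De*gamma - S, Cg, Cm - Cw))
    on <- rbind(
      c(Is + Csl - Csh + Ds + beta*Fs + beta*Io,
        Ie - Cei + De + S + beta*Fe,
        Fs + Fe - beta*Fs - beta*Fe + beta*Fg - Cg, Cw - Cm),
      c(Csh - Csl - Is - Ds - beta*Fs - beta*Io,
        Ie + De + S - Cei, -Cg, Cw - Cm),
      c(Is + Csl - Csh + Ds + Io,
        Cei - Ie - De - S - beta*Fe, Fs - Cg, Cw - Cm),
      c(Is + Fs + Csl - Csh + Ds + Io,
        Ie - Cei + De + S + Fe,
        beta*Fe + beta*Fs + Cg - Fs - Fe - beta*Fg, Cw - Cm),
      c(Csh - Csl - Is - Ds - Io, Cei - Ie - De - S, -Cg, Cw - Cm),
      c(Is + Fs + Csl - Csh + Ds + Io,
        Cei - Ie - De - S - Fe, Cg - Fs, Cw - Cm),
      c(Csh - Csl - Is - Ds - Fs - Io, Ie + De + S - Cei, Cg, Cw - Cm),
      c(Csh - Csl - Is - Ds - Fs - Io, Cei - S - Ie - De, Cg, Cw - Cm))
    m <- rbind(off, on)
    rownames(m) <- paste0("E", 1:16)
    m
  })
}

# Exact solution of the decoupled elderly equation dw/dt = w(1-w)(Cm-Cw).
logistic_w <- function(w0, rate, t) {
  w0 * exp(rate * t) / (1 - w0 + w0 * exp(rate * t))
}

baseline <- game_params()
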