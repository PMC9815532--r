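test_that("the five built-in suites carry the published variant grids", {
  sc <- builtin_scenarios()
  expect_named(sc, c("penalty_provider", "penalty_subsidy_platform",
                     "online_evaluation", "reputation", "complaint_rate"))

  labs1 <- vapply(sc$penalty_provider$variants, `[[`, character(1), "label")
  expect_setequal(labs1, c("Fs=10", "Fs=20", "Fs=30", "Io=5", "Io=10", "Io=15"))
  v30 <- Filter(function(v) v$label == "Fs=30", sc$penalty_provider$variants)[[1]]
  expect_equal(unname(v30$set["Fs"]), 30)
  expect_null(v30$scale)

  labs2 <- vapply(sc$penalty_subsidy_platform$variants, `[[`, character(1), "label")
  expect_setequal(labs2, c("Fe=2.5", "Fe=5", "Fe=7.5", "S=5", "S=10", "S=15"))

  expect_length(sc$online_evaluation$variants, 2L)
  expect_length(sc$complaint_rate$variants, 2L)
  expect_equal(vapply(sc$complaint_rate$variants, function(v)
    unname(v$set["beta"]), numeric(1)), c(0.01, 0.41))

  rep_up <- sc$reputation$variants[[2]]
  expect_equal(rep_up$scale, c(Is = 1.5, Ds = 1.5, Ie = 1.5, De = 1.5))

  # every variant resolves to an admissible parameter set
  for (suite in sc)
    for (v in suite$variants) {
      q <- eldergame:::apply_variant_params(game_params(), v)
      expect_true(validate_params(q)$ok)
    }
})

test_that("larger provider fines and compensations speed up the shift to high quality", {
  res <- run_scenario_suite(baseline, builtin_scenarios()$penalty_provider)
  tt <- res$times
  t_of <- function(lbl) tt$provider[tt$variant == lbl]
  expect_lt(t_of("Fs=30"), t_of("Fs=20"))
  expect_lt(t_of("Fs=20"), t_of("Fs=10"))
  expect_lt(t_of("Io=15"), t_of("Io=10"))
  expect_lt(t_of("Io=10"), t_of("Io=5"))
  expect_true(all(res$convergence$provider == "HQ"))
})

test_that("platform fines and subsidies do not slow, and subsidies speed up, positive visits", {
  res <- run_scenario_suite(baseline, builtin_scenarios()$penalty_subsidy_platform)
  tt <- res$times
  t_of <- function(lbl) tt$platform[tt$variant == lbl]
  # the subsidy bites directly; the fine only via low-quality providers
  expect_lt(t_of("S=15"), t_of("S=5"))
  expect_lte(t_of("S=15"), t_of("S=10"))
  expect_lte(t_of("Fe=7.5"), t_of("Fe=5"))
  expect_lte(t_of("Fe=5"), t_of("Fe=2.5"))
})

test_that("a larger initial online-evaluation share accelerates everyone", {
  res <- run_scenario_suite(baseline, builtin_scenarios()$online_evaluation)
  tt <- res$times
  hi <- tt[tt$variant == "w0=0.75", ]
  lo <- tt[tt$variant == "w0=0.25", ]
  expect_lte(hi$platform, lo$platform)
  expect_lte(hi$provider, lo$provider)
  expect_lte(hi$elderly, lo$elderly)
})

test_that("stronger reputation effects shorten convergence of providers and platforms", {
  res <- run_scenario_suite(baseline, builtin_scenarios()$reputation)
  tt <- res$times
  expect_lt(tt$provider[2], tt$provider[1])
  expect_lt(tt$platform[2], tt$platform[1])
})

test_that("a higher complaint rate speeds providers and slows the government's retreat", {
  res <- run_scenario_suite(baseline, builtin_scenarios()$complaint_rate)
  tt <- res$times
  expect_lt(tt$provider[tt$variant == "beta=0.41"],
            tt$provider[tt$variant == "beta=0.01"])
  # time for z to drift below 0.01 grows with beta
  tz <- vapply(res$trajectories, time_to_threshold, numeric(1),
               player = "government", level = 0.01)
  expect_gt(tz[["beta=0.41"]], tz[["beta=0.01"]])
})

test_that("every scenario variant with a unique ESS converges to it from the centroid", {
  set.seed(77)
  for (suite in builtin_scenarios()) {
    for (v in suite$variants) {
      q <- eldergame:::apply_variant_params(baseline, v)
      s0 <- eldergame:::apply_variant_init(c(0.5, 0.5, 0.5, 0.5), v)
      rep <- stability(q, n_draws = 50)  # draws only affect the always_unstable flags
      if (length(rep$ess) != 1L) next
      target <- as.numeric(corner_profiles()[as.character(rep$ess), ])
      tr <- simulate_game(q, init = s0)
      final <- as.numeric(tr[nrow(tr), c("x", "y", "z", "w")])
      expect_true(all(abs(final - target) < 0.01),
                  label = sprintf("suite %s variant %s reaches its ESS",
                                  suite$id, v$label))
    }
  }
})

test_that("a single baseline variant reproduces plain integration bit for bit", {
  spec <- eldergame:::new_scenario("ident", "baseline only",
    list(eldergame:::variant("base")))
  res <- run_scenario_suite(baseline, spec)
  direct <- simulate_game(baseline, label = "base")
  expect_identical(as.data.frame(res$trajectories$base),
                   as.data.frame(direct))
})

test_that("a failing variant is reported without aborting the suite", {
  spec <- eldergame:::new_scenario("mix", "one bad variant",
    list(eldergame:::variant("ok", set = c(Fs = 30)),
         eldergame:::variant("bad", set = c(gamma = 5))))
  res <- run_scenario_suite(baseline, spec)
  expect_false(is.null(res$trajectories$ok))
  expect_null(res$trajectories$bad)
  expect_match(res$errors[["bad"]], "gamma")
})
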