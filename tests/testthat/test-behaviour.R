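mk_events <- function() {
  # small hand-checkable log: one butterfly, one trial
  data.frame(
    id = "b1", origin = "homogeneous", trial = 1,
    tunnel = c("N", "N", "E", "E", "S", "S", "W", "N"),
    behaviour = c("sitting still", "net flight", "sun flight", "walking",
                  "sitting still", "free flight", "landing on host plant",
                  "sitting still"),
    duration_s = c(100, 20, 30, 10, 200, 15, 5, 50),
    temp_c = 24, rh_pct = 60, insolation = 0.5,
    target_tunnel = "E")
}

test_that("ethogram pooling tallies categories and conserves seconds", {
  one <- data.frame(id = "b", origin = "homogeneous", trial = 1, tunnel = "N",
                    behaviour = "sitting still", duration_s = 100)
  tt1 <- pool_behaviours(one)
  expect_equal(tt1$duration_s[tt1$category == "resting" & tt1$tunnel == "N"], 100)
  expect_equal(sum(tt1$duration_s), 100)

  tt <- pool_behaviours(mk_events())
  expect_equal(sum(tt$duration_s), sum(mk_events()$duration_s))
  # hand tally
  get <- function(tun, cat) tt$duration_s[tt$tunnel == tun & tt$category == cat]
  expect_equal(get("N", "resting"), 150)
  expect_equal(get("N", "departing"), 20)
  expect_equal(get("E", "departing"), 30)
  expect_equal(get("E", "navigation"), 10)
  expect_equal(get("S", "navigation"), 15)
  expect_equal(get("W", "navigation"), 5)
  expect_equal(get("W", "resting"), 0)   # explicit zero cell

  bad <- mk_events()
  bad$behaviour[1] <- "pirouette"
  expect_error(pool_behaviours(bad), "pirouette")
  neg <- mk_events()
  neg$duration_s[2] <- -1
  expect_error(pool_behaviours(neg), "negative")
})

test_that("plant-presence aggregation pools controls and sets the log(3) offset", {
  ev <- mk_events()
  tt <- pool_behaviours(ev)
  agg <- aggregate_by_plant_presence(tt)
  expect_equal(sum(agg$duration_s), sum(ev$duration_s))  # conservation
  expect_equal(agg$exposure_offset[agg$tunnel_type == "control"],
               rep(log(3), 3))
  expect_equal(agg$exposure_offset[agg$tunnel_type == "target"], rep(0, 3))
  # equal 60 s in each of 4 tunnels -> target 60, control 180
  eq <- data.frame(id = "b", origin = "homogeneous", trial = 1,
                   tunnel = c("N", "E", "S", "W"), behaviour = "sitting still",
                   duration_s = 60, target_tunnel = "N")
  agg2 <- aggregate_by_plant_presence(pool_behaviours(eq))
  expect_equal(agg2$duration_s[agg2$tunnel_type == "target" &
                                 agg2$category == "resting"], 60)
  expect_equal(agg2$duration_s[agg2$tunnel_type == "control" &
                                 agg2$category == "resting"], 180)

  expect_error(aggregate_by_plant_presence(tt, target_tunnel = "Z"),
               "exactly one target tunnel")
})

test_that("time-budget fits expose coefficients, dispersion and AIC", {
  tt <- simulate_timebudget_trials(seed = 91)
  f <- fit_timebudget(tt, "origin_interaction")
  expect_s3_class(f, "timebudget_fit")
  expect_true(f$converged)
  expect_true(all(c("(Intercept)", "originfragmented", "categorydeparting",
                    "originfragmented:categorydeparting") %in%
                    f$coefficients$term))
  expect_true(all(f$coefficients$se > 0))
  expect_true(is.finite(f$aic))
  expect_named(f$ranef_sd, c("trial", "id", "tunnel"))
  expect_equal(unname(coef(f)), f$coefficients$estimate)
  expect_equal(dim(vcov(f)), rep(nrow(f$coefficients), 2))

  frac <- tt
  frac$duration_s[1] <- 0.5
  expect_error(fit_timebudget(frac, "origin_interaction"), "whole seconds")
})

test_that("contrasts and marginal means agree with emmeans on the same fit", {
  skip_if_not_installed("emmeans")
  # use the first cleanly converged fit from a deterministic seed sequence
  f <- NULL
  for (s in 92:110) {
    tt <- simulate_timebudget_trials(seed = s)
    cand <- suppressWarnings(fit_timebudget(tt, "origin_interaction"))
    if (isTRUE(cand$converged)) {
      f <- cand
      break
    }
  }
  expect_true(isTRUE(f$converged))

  # identity contrast returns the coefficient itself
  ic <- linear_contrast(f, c(categorydeparting = 1))
  i <- which(f$coefficients$term == "categorydeparting")
  expect_equal(ic$mu, f$coefficients$estimate[i])
  expect_equal(ic$se, f$coefficients$se[i])
  expect_error(linear_contrast(f, numeric(nrow(f$coefficients))), "zero contrast")
  expect_error(linear_contrast(f, 1:3), "length")

  # departing - navigation in the homogeneous origin, vs emmeans
  em <- emmeans::emmeans(f$model, ~ category | origin)
  ec <- as.data.frame(emmeans::contrast(
    em, method = list(dvn = c(0, 1, -1))))  # resting, departing, navigation
  mine <- linear_contrast(f, c(categorydeparting = 1, categorynavigation = -1))
  expect_equal(mine$mu, ec$estimate[ec$origin == "homogeneous"],
               tolerance = 1e-6)
  expect_equal(mine$se, ec$SE[ec$origin == "homogeneous"], tolerance = 1e-6)

  # marginal means: hand-computed exp(eta +/- 1.96 se) and emmeans agreement
  mm <- marginal_means(f)
  beta <- coef(f)
  V <- vcov(f)
  eta_dep_frag <- beta["(Intercept)"] + beta["originfragmented"] +
    beta["categorydeparting"] + beta["originfragmented:categorydeparting"]
  w <- as.numeric(names(beta) %in% c("(Intercept)", "originfragmented",
                                     "categorydeparting",
                                     "originfragmented:categorydeparting"))
  se <- sqrt(drop(t(w) %*% V %*% w))
  row <- mm[mm$origin == "fragmented" & mm$category == "departing", ]
  expect_equal(row$mean, exp(unname(eta_dep_frag)))
  expect_equal(row$lwr, exp(unname(eta_dep_frag) - qnorm(0.975) * se))
  expect_equal(row$upr, exp(unname(eta_dep_frag) + qnorm(0.975) * se))
  emm <- as.data.frame(emmeans::emmeans(f$model, ~ origin * category,
                                        type = "response"))
  for (k in seq_len(nrow(mm))) {
    j <- which(emm$origin == as.character(mm$origin[k]) &
                 emm$category == as.character(mm$category[k]))
    expect_equal(mm$mean[k], emm$response[j], tolerance = 1e-6)
  }
  expect_error(marginal_means(f, data.frame(origin = "lunar",
                                            category = "resting")),
               "unknown level")
})

test_that("AIC selection ranks candidate models and rejects mismatched data", {
  tt <- simulate_timebudget_trials(seed = 93)
  f1 <- fit_timebudget(tt, "origin_interaction")
  sel_same <- select_by_aic(list(a = f1, b = f1))
  expect_equal(sel_same$table$delta_aic, c(0, 0))
  single <- select_by_aic(list(only = f1))
  expect_identical(single$best$aic, f1$aic)

  other <- simulate_timebudget_trials(trials_per_butterfly = 2, seed = 94)
  f2 <- fit_timebudget(other, "origin_interaction")
  expect_error(select_by_aic(list(f1, f2)), "row counts differ")

  # an informative category effect beats scrambled data on AIC
  f_cat <- fit_timebudget(tt, "category_only")
  shuf <- tt
  set.seed(95)
  shuf$duration_s <- sample(shuf$duration_s)
  f_shuf <- fit_timebudget(shuf, "category_only")
  expect_lt(f_cat$aic - 2, f_shuf$aic)
})

test_that("the full trial-log analysis runs end to end on synthetic data", {
  ev <- generate_trials(trial_sim_spec(seed = 96))
  ana <- reproduce_time_budget(ev)
  expect_equal(sum(ana$shares_pct), 100, tolerance = 1e-9)
  expect_gt(ana$shares_pct[["resting"]], 50)  # resting-dominant budget
  expect_equal(sum(ana$tunnel_minutes) * 60, sum(ev$duration_s))
  expect_s3_class(ana$fits$tunnel_interaction, "timebudget_fit")
  expect_s3_class(ana$contrast, "timebudget_contrast")
  expect_true(all(c("origin", "category") %in% names(ana$marginal_means)))
  expect_s3_class(ana$aic, "aic_selection")
})
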