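test_that("intercept-only death models recover closed-form MLEs", {
  long <- intercept_long(c(rep("PCA_DEATH", 250), rep("OTHER_DEATH", 150),
                           rep("STAY", 600)))
  fits <- fit_death_models(long, intercept_specs())
  expect_equal(unname(fits$death_pca$coef), qlogis(0.25),
               tolerance = 1e-6)
  # conditioning contract: model 2 sees total - #PCA_DEATH rows
  expect_identical(fits$death_other$n, 750L)
  expect_equal(unname(fits$death_other$coef), qlogis(150 / 750),
               tolerance = 1e-6)
  expect_error(fit_death_models(intercept_long(rep("STAY", 10)),
                                intercept_specs()),
               "no PCA_DEATH")
})

test_that("sequential death draws compose to the total death probability", {
  # p1 + (1 - p1) p2, and the full per-step distribution sums to one
  ms <- flat_models(p_pca = 0.1, p_other = 0.2,
                    p_dest = c(AA = 0.05, GNRH = 0.03))
  df <- data.frame(age = 70, cci = 0L, state = "WW", risk_category = 1L,
                   steps_in_state = 1L)
  p1 <- trajectsim:::predict_lp(ms$death_pca, df)
  p2 <- trajectsim:::predict_lp(ms$death_other, df)
  expect_equal(p1 + (1 - p1) * p2, 0.28, tolerance = 1e-12)
  pd <- trajectsim:::predict_destination(ms$destination$WW, df)
  total <- p1 + (1 - p1) * p2 + (1 - p1) * (1 - p2) * sum(pd)
  expect_equal(unname(total), 1, tolerance = 1e-12)
})

test_that("intercept-only destination model equals empirical proportions", {
  long <- intercept_long(c(rep("STAY", 900), rep("CHANGE", 100)),
                         state = "RT",
                         dest = c(rep(NA, 900), rep("AA", 60),
                                  rep("GNRH", 40)))
  fit <- fit_destination_model(long, "RT", default_graph,
                               intercept_specs())
  p <- trajectsim:::predict_destination(
    fit, data.frame(age = 70, cci = 0L, state = "RT", risk_category = 1L,
                    steps_in_state = 1L))
  expect_equal(unname(p[1, c("STAY", "AA", "GNRH")]), c(0.90, 0.06, 0.04),
               tolerance = 1e-6)
})

test_that("degenerate destination data drops destinations with a warning", {
  long <- intercept_long(rep("STAY", 200), state = "RT")
  expect_warning(fit <- fit_destination_model(long, "RT", default_graph,
                                              intercept_specs()),
                 "dropped")
  expect_length(fit$destinations, 0)
  p <- trajectsim:::predict_destination(
    fit, data.frame(age = 70, cci = 0L, state = "RT", risk_category = 1L,
                    steps_in_state = 1L))
  expect_equal(unname(p[1, "STAY"]), 1)
})

test_that("AS destination fitting excludes the rule-handled WW rows", {
  long <- intercept_long(c(rep("STAY", 300), rep("CHANGE", 60)),
                         state = "AS",
                         dest = c(rep(NA, 300), rep("WW", 30),
                                  rep("RP", 30)))
  expect_warning(
    fit <- fit_destination_model(long, "AS", default_graph,
                                 intercept_specs()),
    "no observed transitions to RT")
  expect_false("WW" %in% fit$destinations)
  # risk set excludes the rule rows: 330 rows, 30 RP events
  expect_identical(fit$n, 330L)
  p <- trajectsim:::predict_destination(
    fit, data.frame(age = 60, cci = 0L, state = "AS", risk_category = 1L,
                    steps_in_state = 1L))
  expect_equal(unname(p[1, "RP"]), 30 / 330, tolerance = 1e-6)
})

test_that("ordinal model probabilities and thresholds behave as stated", {
  om <- ordinal_model("AS", 3, c(0, log(3)), character(0), numeric(0))
  p <- trajectsim:::predict_ordinal(om, data.frame(age = 70, cci = 0L,
                                                   state = "AS",
                                                   risk_category = 1L,
                                                   steps_in_state = 1L))
  expect_equal(unname(p[1, ]), c(0.5, 0.25, 0.25), tolerance = 1e-12)
  expect_error(ordinal_model("AS", 3, c(1, 0), character(0), numeric(0)),
               "strictly increasing")

  entries <- data.frame(person_id = 1:100, step = 1L, dest = "AS",
                        category = rep(1:3, c(50, 25, 25)), age = 70,
                        cci = 0L, state = "AS", risk_category = 1L,
                        steps_in_state = 1L, inherited = FALSE)
  fit <- fit_risk_category_model(entries, "AS",
                                 list(risk_entry = character(0)),
                                 default_graph)
  expect_equal(fit$zeta, c(qlogis(0.5), qlogis(0.75)), tolerance = 1e-9)
  expect_true(all(diff(fit$zeta) > 0))
  one_cat <- entries; one_cat$category <- 1L
  expect_error(fit_risk_category_model(one_cat, "AS",
                                       list(risk_entry = character(0)),
                                       default_graph),
               "fewer than 2")
})

test_that("proportional-odds fitting recovers known coefficients", {
  set.seed(11)
  n <- 4000
  age <- runif(n, 55, 85)
  eta <- 0.6 * (age - 70) / 10
  zeta <- c(-1.2, -0.2, 0.8, 1.8, 2.8)
  cum <- plogis(outer(-eta, zeta, `+`))
  pr <- cbind(cum, 1) - cbind(0, cum)
  cat <- apply(pr, 1, function(w) sample.int(6, 1, prob = w))
  entries <- data.frame(person_id = 1:n, step = 1L, dest = "RP",
                        category = cat, age = age, cci = 0L, state = "AS",
                        risk_category = 1L, steps_in_state = 1L,
                        inherited = FALSE)
  fit <- fit_risk_category_model(entries, "RP",
                                 list(risk_entry = "age10"),
                                 default_graph)
  expect_lt(abs(fit$coef[["age10"]] - 0.6), 3 * fit$se[[1]] + 0.05)
})

test_that("zero-truncated Poisson fitting matches its mean identity", {
  set.seed(7)
  lam <- 0.5
  draws <- integer(0)
  while (length(draws) < 10000) {
    x <- rpois(20000, lam)
    draws <- c(draws, x[x > 0])
  }
  draws <- draws[1:10000]
  expect_equal(mean(draws), lam / (1 - exp(-lam)), tolerance = 0.02)
  fit <- trajectsim:::fit_ztp(matrix(1, length(draws), 1,
                                     dimnames = list(NULL, "(Intercept)")),
                              draws, rep(FALSE, length(draws)), "test")
  expect_lt(abs(exp(fit$coef[[1]]) - lam), 3 * exp(fit$coef[[1]]) *
              fit$se[[1]])
})

test_that("per-state CCI fits respect the cap and the floor", {
  cfg <- default_truth_config(n_persons = 1500, seed = 17)
  long <- expand_to_steps(generate_registry(cfg), default_graph)
  fits <- fit_cci_model(long, states = c("RP", "GNRH"))
  # state-specific: intercepts differ when generated so (-6.4 vs -5.9)
  expect_lt(fits$RP$logit$coef[["(Intercept)"]],
            fits$GNRH$logit$coef[["(Intercept)"]])
  # rows at the cap are not at risk
  expect_identical(fits$RP$logit$n,
                   sum(long$state == "RP" & long$cci < 3))
  no_inc <- long[long$state == "RP", , drop = FALSE]
  no_inc$cci_increased <- FALSE
  expect_warning(f0 <- fit_cci_model(no_inc, states = "RP"), "floored")
  expect_equal(unname(f0$RP$logit$coef[["(Intercept)"]]), qlogis(1e-6))
  expect_error(fit_cci_model(long[0, ], states = "RP"), "no person-period")
})

test_that("Rubin pooling follows the combination rules exactly", {
  mk <- function(b, se) {
    ms <- flat_models(p_pca = 0.01, p_other = 0.01,
                      p_dest = c(AA = 0.01))
    ms$death_pca <- lp_model("(Intercept)", b, se = se)
    ms
  }
  pooled <- pool_models(list(mk(0.1, 0.3), mk(0.3, 0.4)))
  expect_equal(unname(pooled$death_pca$coef), 0.2, tolerance = 1e-12)
  meta <- pooled$meta$pooling$death_pca
  expect_equal(unname(meta$between), 0.02, tolerance = 1e-12)
  expect_equal(unname(meta$within), (0.3^2 + 0.4^2) / 2, tolerance = 1e-12)
  expect_equal(unname(pooled$death_pca$se),
               sqrt((0.3^2 + 0.4^2) / 2 + 1.5 * 0.02), tolerance = 1e-12)
  # m identical sets: pooled equals the input with zero between-variance
  same <- pool_models(list(mk(0.25, 0.1), mk(0.25, 0.1), mk(0.25, 0.1)))
  expect_equal(unname(same$death_pca$coef), 0.25, tolerance = 1e-15)
  expect_equal(unname(same$meta$pooling$death_pca$between), 0,
               tolerance = 1e-15)
  # structural mismatch is a structured error
  other <- mk(0.1, 0.3)
  other$death_pca <- lp_model(c("(Intercept)", "age10"), c(0.1, 0),
                              se = c(0.3, 0.1))
  expect_error(pool_models(list(mk(0.1, 0.3), other)), "mismatch")
  expect_error(mice_impute(generate_registry(
    default_truth_config(n_persons = 20)), m = 1), "at least 2")
})

test_that("imputation is a seeded no-op without missingness and draws from
           the observed marginal without signal", {
  reg <- generate_registry(default_truth_config(n_persons = 300,
                                                seed = 19))
  imps <- mice_impute(reg, default_graph, m = 3, seed = 5)
  expect_length(imps, 3)
  for (i in 1:3) expect_identical(imps[[i]]$determinants,
                                  reg$determinants)

  # no predictive signal: zero ordinal coefficients and flat determinants
  cfg <- default_truth_config(n_persons = 2500, seed = 23)
  for (lab in names(cfg$truth_models$risk_entry)) {
    cfg$truth_models$risk_entry[[lab]]$coef[] <- 0
  }
  cfg$determinants$slope <- c(0, 0, 0)
  reg <- generate_registry(cfg)
  masked <- inject_missingness(reg, 0.5, seed = 31)
  i1 <- mice_impute(masked, default_graph, m = 4, iterations = 3,
                    seed = 11)
  i2 <- mice_impute(masked, default_graph, m = 4, iterations = 3,
                    seed = 11)
  expect_identical(i1[[1]]$determinants$category,
                   i2[[1]]$determinants$category)
  det <- masked$determinants
  lab <- names(which.max(table(det$label[det$deferred])))
  obs <- det$category[det$deferred & det$observed & det$label == lab]
  hole <- det$deferred & !det$observed & det$label == lab
  impv <- unlist(lapply(i1, function(r) r$determinants$category[hole]))
  K <- risk_category_counts(lab)
  p_obs <- tabulate(obs, K) / length(obs)
  p_imp <- tabulate(impv, K) / length(impv)
  # both marginals are estimates of the same truth: combine their errors
  se <- sqrt(p_obs * (1 - p_obs) *
               (1 / length(impv) + 1 / length(obs)))
  expect_true(all(abs(p_imp - p_obs) <= 3 * se + 0.01))
})
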