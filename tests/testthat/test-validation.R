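test_that("the discrete estimator handles empty, degenerate and censored
           data", {
  # no events: all curves zero
  c0 <- discrete_cuminc(rep(0L, 10), rep(20L, 10), rep(NA_character_, 10),
                        c("A", "B"), 30)
  expect_true(all(c0$inc == 0))
  # uncensored data conserve probability: sum CIF + S = 1
  set.seed(2)
  exit <- sample(1:30, 200, replace = TRUE)
  event <- sample(c("A", "B"), 200, replace = TRUE)
  cc <- discrete_cuminc(rep(0L, 200), exit, event, c("A", "B"), 30)
  expect_equal(rowSums(cc$inc) + cc$surv, rep(1, 30), tolerance = 1e-9)
  expect_true(all(diff(cc$inc[, "A"]) >= 0))
  expect_error(discrete_cuminc(0L, 5L, "C", c("A", "B"), 30),
               "unknown destination")
})

test_that("merged destinations equal one minus Kaplan-Meier", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 300
  exit <- sample(1:40, n, replace = TRUE)
  event <- sample(c("A", "B", NA), n, replace = TRUE,
                  prob = c(0.4, 0.3, 0.3))
  cc <- discrete_cuminc(rep(0L, n), exit, event, c("A", "B"), 40)
  km <- survival::survfit(
    survival::Surv(exit, !is.na(event)) ~ 1)
  S <- summary(km, times = 1:40, extend = TRUE)$surv
  expect_equal(rowSums(cc$inc), 1 - S, tolerance = 1e-9)
})

test_that("the estimator agrees with an established competing-risks
           implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(4)
  n <- 400
  exit <- sample(1:50, n, replace = TRUE)
  event <- sample(c("A", "B", NA), n, replace = TRUE,
                  prob = c(0.35, 0.25, 0.4))
  cc <- discrete_cuminc(rep(0L, n), exit, event, c("A", "B"), 50)
  code <- ifelse(is.na(event), 0, ifelse(event == "A", 1, 2))
  ci <- cmprsk::cuminc(exit, code, cencode = 0)
  tp <- cmprsk::timepoints(ci, times = 1:50)$est
  expect_equal(unname(cc$inc[, "A"]), unname(tp["1 1", ]),
               tolerance = 1e-9)
  expect_equal(unname(cc$inc[, "B"]), unname(tp["1 2", ]),
               tolerance = 1e-9)
})

test_that("constant-hazard first transitions match the analytic oracle", {
  cfg <- constant_hazard_config(p_dest = c(AA = 0.006, GNRH = 0.004),
                                n_persons = 4000, seed = 6)
  reg <- generate_registry(cfg)
  long <- expand_to_steps(reg, default_graph)
  obs <- cuminc_first_transition(long, default_graph)$WW
  oc <- oracle_cuminc(cfg, "WW")
  for (k in c("AA", "GNRH")) {
    se <- sqrt(pmax(oc$inc[, k] * (1 - oc$inc[, k]), 1e-12) / 4000)
    expect_true(all(abs(obs$inc[, k] - oc$inc[, k]) <= 3 * se + 1e-9))
  }
})

test_that("second transitions use delayed entry on the diagnosis clock", {
  # every man: RP at entry, RTADJ at step 5, GNRH at step 9
  n <- 40
  persons <- do.call(rbind, lapply(1:n, function(i) {
    p <- one_person(end = as.Date("2008-01-01") + 28 * 60)
    p$person_id <- i
    p
  }))
  ev <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(person_id = i, step = NA_integer_,
               date = as.Date("2008-01-01") + 28 * c(5, 9),
               type = "CHANGE", label = c("RTADJ", "GNRH"),
               category = c(2L, 3L), new_cci = NA_integer_)
  }))
  long <- expand_to_steps(manual_registry(persons, ev), default_graph,
                          horizon_steps = 60)
  sec <- cuminc_second_transition(long, "RTADJ", default_graph)
  crv <- sec$after_RTADJ
  expect_identical(attr(sec, "n_filtered"), as.integer(n))
  expect_equal(unname(crv$inc[8, "GNRH"]), 0)
  expect_equal(unname(crv$inc[9, "GNRH"]), 1)
  # nobody transitioning leaves an explicit zero-n marker
  empty <- cuminc_second_transition(
    expand_to_steps(manual_registry(one_person()), default_graph),
    "RTADJ", default_graph)
  expect_length(empty, 0)
  expect_identical(attr(empty, "n_filtered"), 0L)
})

test_that("simulated second-transition curves match an independent
           Monte-Carlo oracle under the same truth", {
  # two-stage constant hazards: WW -> AA, then AA -> GNRH
  p1 <- 0.01; p2 <- 0.02
  mk_cfg <- function(n, seed) {
    cfg <- constant_hazard_config(p_dest = c(AA = p1), n_persons = n,
                                  horizon_steps = 200L, seed = seed)
    cfg$truth_models$destination$AA$coef[1, "GNRH"] <-
      log(p2 / (1 - p2))
    cfg
  }
  big <- generate_registry(mk_cfg(6000, 15))
  obs <- cuminc_second_transition(
    expand_to_steps(big, default_graph, horizon_steps = 200L), "AA",
    default_graph)$after_AA
  cohort <- data.frame(person_id = 1:400, label = "WW",
                       risk_category = 1L, age_at_diagnosis = 70,
                       cci = 0L)
  ms <- mk_cfg(10, 1)$truth_models
  sim <- simulate_cohort(cohort, ms, default_graph, horizon_steps = 200L,
                         replicates = 25L, seed = 14,
                         occupancy = FALSE)
  sec <- cuminc_second_transition(sim, "AA", default_graph)$after_AA
  p <- obs$inc[, "GNRH"]
  # compare where both delayed-entry risk sets are informative; the first
  # few steps of a staggered-entry curve rest on a handful of entrants
  ok <- obs$n_at_risk >= 100 & sec$n_at_risk >= 100
  band <- 3 * sqrt(pmax(p * (1 - p), 1e-12)) *
    (1 / sqrt(pmax(obs$n_at_risk, 1)) + 1 / sqrt(pmax(sec$n_at_risk, 1)))
  expect_gt(sum(ok), 150)
  expect_true(all(abs(sec$inc[, "GNRH"] - p)[ok] <= band[ok] + 0.01))
})

test_that("curve comparison reports landmarks and sup-norms", {
  inc_o <- matrix(seq(0, 0.3, length.out = 326), ncol = 1,
                  dimnames = list(NULL, "RTADJ"))
  inc_s <- inc_o
  oc <- trajectsim:::new_cuminc("RP", inc_o, surv = 1 - inc_o[, 1],
                                n_at_risk = rep(100L, 326), n0 = 100L,
                                source = "OBSERVED")
  sc <- trajectsim:::new_cuminc("RP", inc_s, surv = 1 - inc_s[, 1],
                                n_at_risk = rep(100L, 326), n0 = 100L,
                                source = "SIMULATED")
  cmp0 <- compare_curves(oc, sc)
  expect_equal(unname(cmp0$sup_norm), 0)

  step10 <- ceiling(10 * 365.25 / 28)
  inc_o[step10, 1] <- 0.21; inc_s[step10, 1] <- 0.20
  oc$inc <- inc_o; sc$inc <- inc_s
  cmp <- compare_curves(oc, sc, landmark_years = 10)
  lm <- cmp$landmarks
  expect_equal(lm$difference[lm$years == 10], 0.01, tolerance = 1e-12)

  inc_o[196, 1] <- 0.07; inc_s[196, 1] <- 0.09
  oc$inc <- inc_o; sc$inc <- inc_s
  cmp15 <- compare_curves(oc, sc, landmark_years = 15)
  expect_equal(cmp15$landmarks$difference, -0.02, tolerance = 1e-12)

  bad <- sc
  colnames(bad$inc) <- "GNRH"
  expect_error(compare_curves(oc, bad), "mismatched")
})
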