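test_that("a cancer-death draw suppresses every later draw in the step", {
  sure_death <- flat_models(p_pca = 0.999999, p_other = 0.5,
                            p_dest = c(AA = 0.3), p_cci = 0.5)
  ctx <- list(label = "WW", risk_category = 1L, age_at_diagnosis = 70,
              cci = 0L, history = character(0))
  st <- step_person(ctx, 1L, sure_death, default_graph, seed = 1)
  expect_identical(st$outcome, "PCA_DEATH")
  expect_identical(st$slots_used, 1L)

  other_death <- flat_models(p_pca = 0, p_other = 0.999999,
                             p_dest = c(AA = 0.3), p_cci = 0.5)
  st2 <- step_person(ctx, 1L, other_death, default_graph, seed = 1)
  expect_identical(st2$outcome, "OTHER_DEATH")
  expect_identical(st2$slots_used, c(1L, 2L))

  survive <- flat_models(p_pca = 0, p_other = 0, p_dest = c(AA = 0),
                         p_cci = 0)
  st3 <- step_person(ctx, 1L, survive, default_graph, seed = 1)
  expect_identical(st3$outcome, "STAY")
  expect_identical(st3$slots_used, c(1L, 2L, 3L, 5L))
  expect_error(step_person(list(label = "PCA_DEATH"), 1L, survive,
                           default_graph, seed = 1), "absorbing")
})

test_that("per-step death frequency composes the two sequential draws", {
  ms <- flat_models(p_pca = 0.1, p_other = 0.2)
  cohort <- data.frame(person_id = 1:1000, label = "WW",
                       risk_category = 1L, age_at_diagnosis = 70,
                       cci = 0L)
  sim <- simulate_cohort(cohort, ms, default_graph, horizon_steps = 1L,
                         replicates = 100L, seed = 99, occupancy = FALSE)
  died <- mean(sim$terminal$status != "HORIZON")
  expect_lt(abs(died - 0.28), 3 * sqrt(0.28 * 0.72 / 1e5))
  # conditional split between the two causes: P(pca | death) = 0.1/0.28
  p_pca <- mean(sim$terminal$status == "PCA_DEATH") / died
  expect_lt(abs(p_pca - 0.1 / 0.28), 3 * sqrt(0.357 * 0.643 / (0.28 * 1e5)))
})

test_that("degenerate models run every trajectory to the horizon", {
  ms <- flat_models()
  sim <- simulate_person(list(label = "WW", risk_category = 1L,
                              age_at_diagnosis = 70, cci = 0L),
                         ms, default_graph, replicates = 20L, seed = 3)
  expect_true(all(sim$terminal$status == "HORIZON"))
  expect_true(all(sim$terminal$end_step == 326L))
  expect_identical(nrow(sim$events), 0L)
})

test_that("survival under a constant hazard is geometric", {
  ms <- flat_models(p_pca = 0.01)
  sim <- simulate_person(list(label = "GNRH", risk_category = 1L,
                              age_at_diagnosis = 70, cci = 0L),
                         ms, default_graph, replicates = 10000L, seed = 4)
  frac <- mean(sim$terminal$status == "HORIZON")
  expect_lt(abs(frac - 0.99^326),
            3 * sqrt(0.99^326 * (1 - 0.99^326) / 1e4))
})

test_that("the engine is deterministic and order-invariant", {
  ms <- default_truth_models()
  cohort <- data.frame(person_id = 1:50, label = rep(c("RP", "GNRH"), 25),
                       risk_category = 2L,
                       age_at_diagnosis = seq(55, 85, length.out = 50),
                       cci = rep(0:3, length.out = 50))
  s1 <- simulate_cohort(cohort, ms, default_graph, replicates = 3L,
                        seed = 7, occupancy = FALSE)
  s2 <- simulate_cohort(cohort[rev(seq_len(50)), ], ms, default_graph,
                        replicates = 3L, seed = 7, occupancy = FALSE)
  key <- function(x) {
    e <- x$events[order(x$events$person_id, x$events$replicate,
                        x$events$step, x$events$type), ]
    rownames(e) <- NULL
    e
  }
  expect_identical(key(s1), key(s2))
  t1 <- s1$terminal[order(s1$terminal$person_id, s1$terminal$replicate), ]
  t2 <- s2$terminal[order(s2$terminal$person_id, s2$terminal$replicate), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_identical(t1, t2)
})

test_that("R reference stepper and compiled engine agree trajectory-wise", {
  ms <- default_truth_models()
  g <- default_graph
  for (case in list(list(pid = 5L, lab = "AS", cat = 2L, age = 72,
                         cci = 1L),
                    list(pid = 11L, lab = "RP", cat = 4L, age = 58,
                         cci = 0L),
                    list(pid = 23L, lab = "GNRH", cat = 7L, age = 80,
                         cci = 2L))) {
    seed <- 1234
    ctx <- list(label = case$lab, risk_category = case$cat,
                age_at_diagnosis = case$age, cci = case$cci,
                history = character(0), steps_in_state = 1L)
    ref_events <- list(); ref_term <- c(326L, "HORIZON")
    for (t in 1:326) {
      st <- step_person(ctx, t, ms, g, seed, person = case$pid,
                        replicate = 1L)
      if (st$outcome %in% absorbing_labels()) {
        ref_term <- c(t, st$outcome); break
      }
      if (st$outcome == "CHANGE") {
        ref_events[[length(ref_events) + 1]] <-
          c(t, st$dest_label, st$dest_category)
      }
      if (st$cci_increased) {
        ref_events[[length(ref_events) + 1]] <- c(t, "CCI", st$new_cci)
      }
      ctx <- st$ctx
    }
    sim <- simulate_cohort(
      data.frame(person_id = case$pid, label = case$lab,
                 risk_category = case$cat, age_at_diagnosis = case$age,
                 cci = case$cci),
      ms, g, replicates = 1L, seed = seed, occupancy = FALSE)
    expect_identical(sim$terminal$end_step, as.integer(ref_term[1]))
    expect_identical(sim$terminal$status, ref_term[2])
    eng <- sim$events
    expect_identical(nrow(eng), length(ref_events))
    for (i in seq_along(ref_events)) {
      expect_identical(eng$step[i], as.integer(ref_events[[i]][1]))
      if (ref_events[[i]][2] == "CCI") {
        expect_identical(eng$type[i], "CCI_INC")
        expect_identical(eng$new_cci[i], as.integer(ref_events[[i]][3]))
      } else {
        expect_identical(eng$label[i], unname(ref_events[[i]][2]))
        expect_identical(eng$category[i],
                         as.integer(unname(ref_events[[i]][3])))
      }
    }
  }
})

test_that("the AS rule forces the switch to WW deterministically", {
  ms <- default_truth_models()
  ms$death_pca$coef[] <- c(-50, rep(0, length(ms$death_pca$coef) - 1))
  ms$death_other$coef[] <- c(-50, rep(0, length(ms$death_other$coef) - 1))
  ctx <- list(label = "AS", risk_category = 1L, age_at_diagnosis = 80,
              cci = 0L, history = character(0))
  st <- step_person(ctx, 1L, ms, default_graph, seed = 8)
  expect_identical(st$outcome, "CHANGE")
  expect_identical(st$dest_label, "WW")
  # below threshold the destination is stochastic, not the rule
  ctx$age_at_diagnosis <- 50
  draws <- replicate(20, {
    s <- step_person(ctx, 1L, ms, default_graph,
                     seed = sample.int(1e6, 1))
    s$dest_label
  })
  expect_false(any(draws == "WW", na.rm = TRUE))
})

test_that("cohort simulation conserves occupancy and grows monotone
           absorbing states", {
  ms <- default_truth_models()
  cohort <- entry_table(generate_registry(
    default_truth_config(n_persons = 80, seed = 12)))
  sim <- simulate_cohort(cohort, ms, default_graph, replicates = 25L,
                         seed = 5)
  expect_identical(nrow(sim$terminal), 80L * 25L)
  occ <- sim$occupancy
  sums <- tapply(occ$proportion, occ$step, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  for (ab in absorbing_labels()) {
    p <- occ$proportion[occ$state == ab][order(occ$step[occ$state == ab])]
    expect_true(all(diff(p) >= -1e-12))
  }
  expect_error(simulate_cohort(cohort[0, ], ms, default_graph),
               "empty")
})

test_that("simulated trajectories satisfy the structural invariants", {
  ms <- default_truth_models()
  cohort <- entry_table(generate_registry(
    default_truth_config(n_persons = 60, seed = 13)))
  sim <- simulate_cohort(cohort, ms, default_graph, replicates = 2L,
                         seed = 21, occupancy = FALSE)
  states <- trajectory_states(sim)
  for (k in split(states, paste(states$person_id, states$replicate))) {
    expect_true(validate_trajectory(unique(k$state),
                                    default_graph)$valid)
    expect_true(all(diff(k$cci) >= 0))
    expect_true(max(k$cci) <= 3)
    expect_true(nrow(k) <= 326)
  }
})
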