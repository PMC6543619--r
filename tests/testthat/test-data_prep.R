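test_that("expansion assigns steps by half-open four-week intervals", {
  # censored at day 100 with no events: ceil(100/28) = 4 rows, all STAY
  reg <- manual_registry(one_person(end = as.Date("2008-01-01") + 100))
  long <- expand_to_steps(reg, default_graph)
  expect_identical(nrow(long), 4L)
  expect_true(all(long$outcome == "STAY"))
  expect_identical(long$t, 1:4)

  # a change dated day 30 lands in step 2 (30 in (28, 56])
  p <- one_person(end = as.Date("2008-01-01") + 200)
  ev <- data.frame(person_id = 1L, step = NA_integer_,
                   date = as.Date("2008-01-01") + 30, type = "CHANGE",
                   label = "RTADJ", category = 2L, new_cci = NA_integer_)
  long <- expand_to_steps(manual_registry(p, ev), default_graph)
  expect_identical(long$outcome[long$t == 2], "CHANGE")
  expect_identical(long$dest_label[long$t == 2], "RTADJ")
  expect_true(all(long$state[long$t <= 2] == "RP"))
  expect_true(all(long$state[long$t > 2] == "RTADJ"))
  expect_true(all(long$hist_RP[long$t > 2]))
  expect_identical(long$steps_in_state[long$t == 3], 1L)
})

test_that("attained age is updated at each step end", {
  reg <- manual_registry(one_person(age = 65,
                                    end = as.Date("2008-01-01") + 500))
  long <- expand_to_steps(reg, default_graph)
  expect_equal(long$age[long$t == 13], 65 + 13 * 28 / 365.25,
               tolerance = 1e-9)
  expect_equal(long$age[long$t == 13], 65.9966, tolerance = 1e-4)
  expect_equal(diff(long$age), rep(28 / 365.25, nrow(long) - 1),
               tolerance = 1e-12)
})

test_that("death outcomes end the person's rows, and CCI updates lag", {
  p <- one_person(end = as.Date("2008-01-01") + 28 * 7,
                  status = "PCA_DEATH")
  ev <- data.frame(person_id = 1L, step = NA_integer_,
                   date = as.Date("2008-01-01") + 28 * 3, type = "CCI_INC",
                   label = NA_character_, category = NA_integer_,
                   new_cci = 2L)
  long <- expand_to_steps(manual_registry(p, ev), default_graph)
  expect_identical(nrow(long), 7L)
  expect_identical(long$outcome[long$t == 7], "PCA_DEATH")
  expect_true(long$cci_increased[long$t == 3])
  expect_identical(long$new_cci[long$t == 3], 2L)
  expect_identical(long$cci[long$t == 3], 0L)  # increase effective next step
  expect_true(all(long$cci[long$t > 3] == 2L))
})

test_that("events dated outside follow-up are structured errors", {
  p <- one_person(end = "2008-03-01")
  ev <- data.frame(person_id = 1L, step = NA_integer_,
                   date = as.Date("2009-01-01"), type = "CHANGE",
                   label = "RTADJ", category = 1L, new_cci = NA_integer_)
  expect_error(expand_to_steps(manual_registry(p, ev), default_graph),
               "person_id 1")
})

test_that("expansion is consistent across horizons", {
  cfg <- default_truth_config(n_persons = 150, seed = 21)
  reg <- generate_registry(cfg)
  full <- expand_to_steps(reg, default_graph, horizon_steps = 326)
  short <- expand_to_steps(reg, default_graph, horizon_steps = 100)
  fcut <- full[full$t <= 100, ]
  rownames(fcut) <- rownames(short) <- NULL
  expect_equal(as.data.frame(fcut), as.data.frame(short),
               ignore_attr = TRUE)
})

test_that("expansion reproduces the generator's step-level outcomes", {
  cfg <- default_truth_config(n_persons = 300, seed = 8)
  reg <- generate_registry(cfg)
  long <- expand_to_steps(reg, default_graph)
  ch <- long[long$outcome == "CHANGE", c("person_id", "t", "dest_label",
                                         "dest_category")]
  ev <- reg$events[reg$events$type == "CHANGE",
                   c("person_id", "step", "label", "category")]
  expect_identical(nrow(ch), nrow(ev))
  o1 <- order(ch$person_id, ch$t); o2 <- order(ev$person_id, ev$step)
  expect_identical(ch$t[o1], ev$step[o2])
  expect_identical(ch$dest_label[o1], ev$label[o2])
  expect_identical(ch$dest_category[o1], ev$category[o2])
  # row count for an uncensored person equals his death step
  dead <- reg$persons[reg$persons$end_status != "CENSORED", ]
  rows <- table(long$person_id)
  steps <- as.numeric(dead$end_date - dead$diagnosis_date) / 28
  expect_equal(as.integer(rows[as.character(dead$person_id)]),
               as.integer(steps))
})

test_that("left truncation drops, delays and reconstructs correctly", {
  # censored well before the truncation date: dropped
  p1 <- one_person(diagnosis = "2004-06-01", end = "2005-06-30")
  # diagnosed after the date: untouched
  p2 <- one_person(diagnosis = "2010-03-01", end = "2012-01-01")
  p2$person_id <- 2L
  # diagnosed 2004 on RP with a 2005 change to RTADJ: delayed entry in
  # RTADJ with RP history
  p3 <- one_person(diagnosis = "2004-01-10", end = "2008-01-01")
  p3$person_id <- 3L
  ev <- data.frame(person_id = 3L, step = NA_integer_,
                   date = as.Date("2005-05-01"), type = "CHANGE",
                   label = "RTADJ", category = 2L, new_cci = NA_integer_)
  reg <- manual_registry(rbind(p1, p2, p3), ev)
  reg$determinants <- reg$determinants[reg$determinants$person_id != 1L, ]
  trunc <- apply_left_truncation(reg, "2006-01-01")
  expect_setequal(trunc$persons$person_id, c(2L, 3L))
  expect_identical(trunc$persons$entry_step[trunc$persons$person_id == 2L],
                   1L)
  long <- expand_to_steps(trunc, default_graph)
  l3 <- long[long$person_id == 3L, ]
  # first row starts at the first full step after the date
  d <- as.numeric(as.Date("2006-01-01") - as.Date("2004-01-10"))
  expect_identical(min(l3$t), as.integer(ceiling(d / 28)) + 1L)
  expect_true(all(l3$state == "RTADJ"))
  expect_true(all(l3$hist_RP))
  expect_false(any(l3$outcome == "CHANGE"))
})

test_that("train/validation split is an exhaustive person-level partition", {
  cfg <- default_truth_config(n_persons = 101, seed = 4)
  reg <- generate_registry(cfg)
  sp <- split_train_validation(reg, seed = 7)
  n1 <- nrow(sp$train$persons); n2 <- nrow(sp$validation$persons)
  expect_setequal(c(n1, n2), c(50L, 51L))
  expect_length(intersect(sp$train$persons$person_id,
                          sp$validation$persons$person_id), 0)
  expect_setequal(c(sp$train$persons$person_id,
                    sp$validation$persons$person_id),
                  reg$persons$person_id)
  sp2 <- split_train_validation(reg, seed = 7)
  expect_identical(sp$train$persons$person_id,
                   sp2$train$persons$person_id)
  expect_error(split_train_validation(reg, fraction = 1.5), "between")
})
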