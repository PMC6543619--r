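# Individual-level microsimulation: a readable single-step reference
# implementation in R, and cohort-scale simulation through the C++ engine.
# Both consume the same counter-based uniform stream, which is what the
# cross-implementation equivalence tests rely on.

#' Counter-based uniform random numbers
#'
#' Deterministic uniforms keyed on (seed, person, replicate, step, slot):
#' every draw the simulator may need has a fixed address in the stream, so
#' simulated trajectories do not depend on cohort ordering, on batching, or
#' on draws skipped earlier in the same step (e.g. a death draw that ends the
#' step consumes nothing from later slots).
#'
#' @param seed Integer stream seed.
#' @param person,replicate,step,slot Integer vectors (recycled to a common
#'   length).
#' @return Numeric vector of uniforms in `[0, 1)`.
#' @export
counter_uniform <- function(seed, person, replicate, step, slot) {
  n <- max(length(person), length(replicate), length(step), length(slot))
  .cpp_counter_uniform(as.double(seed),
                       as.integer(rep_len(person, n)),
                       as.integer(rep_len(replicate, n)),
                       as.integer(rep_len(step, n)),
                       as.integer(rep_len(slot, n)))
}

# draw slots (addresses within a step)
SLOT_DEATH_PCA   <- 1L
SLOT_DEATH_OTHER <- 2L
SLOT_DESTINATION <- 3L
SLOT_CATEGORY    <- 4L
SLOT_CCI_INC     <- 5L
SLOT_CCI_SIZE    <- 6L

history_mask <- function(labels) {
  if (length(labels) == 0) return(0L)
  as.integer(sum(bitwShiftL(1L, label_code(unique(labels)))))
}

mask_labels <- function(mask) {
  labs <- transient_labels()
  labs[bitwAnd(bitwShiftR(mask, label_code(labs)), 1L) == 1L]
}

# single-row context data.frame for predict_* helpers
ctx_frame <- function(label, cat, age, cci, hist_labels, tis = 0L) {
  df <- data.frame(age = age, cci = cci, state = label,
                   risk_category = cat, steps_in_state = tis)
  for (lab in transient_labels()) {
    df[[paste0("hist_", lab)]] <- lab %in% hist_labels
  }
  df
}

#' Advance one person by a single time step (reference implementation)
#'
#' Executes one 4-week step in the fixed draw order: (1) vital status --
#' prostate-cancer death first, then, conditional on surviving it, death from
#' other causes; (2) for survivors, treatment change -- the deterministic
#' AS-to-WW rule is checked before the stochastic destination draw, the new
#' risk category is inherited for RP to RTADJ and otherwise drawn from the
#' destination's ordinal entry model; (3) for survivors, a comorbidity
#' update (logistic any-increase, zero-truncated Poisson increment, capped
#' at CCI 3), evaluated on the state occupied during the step and effective
#' from the next step. A death therefore suppresses all later draws of the
#' step. This R implementation consumes the identical uniform stream as the
#' compiled cohort engine and exists as its readable, testable counterpart.
#'
#' @param ctx List with `label`, `risk_category`, `age_at_diagnosis`, `cci`,
#'   `history` (character vector of previously occupied labels),
#'   `steps_in_state` (optional, default `t`).
#' @param t Step index (age at the end of the step is
#'   `age_at_diagnosis + 28 t / 365.25`).
#' @param models A `trs_model_set`.
#' @param graph A `trs_graph`.
#' @param seed,person,replicate Stream address of this person-replicate.
#' @return List with `outcome` (`"STAY"`, `"CHANGE"`, `"PCA_DEATH"`,
#'   `"OTHER_DEATH"`), `dest_label`, `dest_category`, `cci_increased`,
#'   `new_cci`, the updated `ctx`, and `slots_used` (which stream slots were
#'   consumed).
#' @export
step_person <- function(ctx, t, models, graph, seed, person = 1L,
                        replicate = 1L) {
  if (ctx$label %in% absorbing_labels()) {
    stop("cannot step a person in absorbing state '", ctx$label, "'",
         call. = FALSE)
  }
  age <- ctx$age_at_diagnosis + t * 28 / 365.25
  tis <- if (is.null(ctx$steps_in_state)) t else ctx$steps_in_state
  df <- ctx_frame(ctx$label, ctx$risk_category, age, ctx$cci, ctx$history,
                  tis)
  u <- function(slot) counter_uniform(seed, person, replicate, t, slot)
  slots <- integer(0)
  out <- list(outcome = "STAY", dest_label = NA_character_,
              dest_category = NA_integer_, cci_increased = FALSE,
              new_cci = NA_integer_)

  slots <- c(slots, SLOT_DEATH_PCA)
  if (u(SLOT_DEATH_PCA) < predict_lp(models$death_pca, df)) {
    out$outcome <- "PCA_DEATH"
    out$ctx <- ctx; out$slots_used <- slots
    return(out)
  }
  slots <- c(slots, SLOT_DEATH_OTHER)
  if (u(SLOT_DEATH_OTHER) < predict_lp(models$death_other, df)) {
    out$outcome <- "OTHER_DEATH"
    out$ctx <- ctx; out$slots_used <- slots
    return(out)
  }

  new_label <- ctx$label; new_cat <- ctx$risk_category
  rule <- models$as_ww_thresholds
  if (ctx$label == "AS" && !is.null(rule) &&
      as_ww_switch(age, ctx$cci, rule)) {
    new_label <- "WW"
  } else if (!is.null(models$destination[[ctx$label]]) &&
             length(models$destination[[ctx$label]]$destinations)) {
    slots <- c(slots, SLOT_DESTINATION)
    p <- predict_destination(models$destination[[ctx$label]], df)
    dests <- models$destination[[ctx$label]]$destinations
    acc <- cumsum(p[1, dests])
    hit <- which(u(SLOT_DESTINATION) < acc)
    if (length(hit)) new_label <- dests[hit[1]]
  }
  if (new_label != ctx$label) {
    if (new_label == "RTADJ") {
      new_cat <- ctx$risk_category
    } else {
      om <- models$risk_entry[[new_label]]
      if (is.null(om)) {
        stop("no ordinal entry model for destination '", new_label, "'",
             call. = FALSE)
      }
      slots <- c(slots, SLOT_CATEGORY)
      edf <- ctx_frame(ctx$label, ctx$risk_category, age, ctx$cci,
                       c(ctx$history, ctx$label), tis)
      pk <- predict_ordinal(om, edf)
      new_cat <- which(u(SLOT_CATEGORY) < cumsum(pk[1, ]))[1]
    }
    out$outcome <- "CHANGE"
    out$dest_label <- new_label
    out$dest_category <- new_cat
  }

  new_cci <- ctx$cci
  if (ctx$cci < 3) {
    slots <- c(slots, SLOT_CCI_INC)
    if (u(SLOT_CCI_INC) < predict_lp(models$cci[[ctx$label]]$logit, df)) {
      slots <- c(slots, SLOT_CCI_SIZE)
      lam <- predict_lp(models$cci[[ctx$label]]$rate, df)
      inc <- ztp_quantile(models$cci[[ctx$label]], lam,
                          u(SLOT_CCI_SIZE))
      new_cci <- min(3L, ctx$cci + inc)
      out$cci_increased <- TRUE
      out$new_cci <- new_cci
    }
  }

  nctx <- ctx
  if (out$outcome == "CHANGE") {
    nctx$history <- unique(c(ctx$history, ctx$label))
    nctx$label <- new_label
    nctx$risk_category <- new_cat
    nctx$steps_in_state <- 0L
  } else {
    nctx$steps_in_state <- tis + 1L
  }
  nctx$cci <- new_cci
  out$ctx <- nctx
  out$slots_used <- slots
  out
}

# inverse CDF of the zero-truncated Poisson, mirroring the engine
ztp_quantile <- function(model, lambda, u) {
  if (lambda < 1e-12) return(1L)
  denom <- expm1(lambda)
  term <- lambda; cum <- 0
  for (k in 1:100) {
    cum <- cum + term / denom
    if (u < cum) return(as.integer(k))
    term <- term * lambda / (k + 1)
  }
  100L
}

#' Simulate replicate trajectories for one person
#'
#' Runs the compiled step engine for a single person's entry conditions.
#' Replicate `r` draws from the substream addressed by (person, r), so
#' results are reproducible and independent of how replicates are batched.
#'
#' @param entry List with `label`, `risk_category`, `age_at_diagnosis`,
#'   `cci`, optional `history` (character) and `person_id`.
#' @param models A `trs_model_set`.
#' @param graph A `trs_graph`.
#' @param horizon_steps Number of 4-week steps to simulate (default 326,
#'   i.e. 25 years).
#' @param replicates Number of replicate trajectories.
#' @param seed Stream seed.
#' @return A `trs_trajectories` object (see [simulate_cohort()]).
#' @export
simulate_person <- function(entry, models, graph, horizon_steps = 326L,
                            replicates = 100L, seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  cohort <- data.frame(
    person_id = if (is.null(entry$person_id)) 1L else entry$person_id,
    label = entry$label, risk_category = entry$risk_category,
    age_at_diagnosis = entry$age_at_diagnosis, cci = entry$cci,
    stringsAsFactors = FALSE)
  cohort$history <- list(if (is.null(entry$history)) character(0)
                         else entry$history)
  simulate_cohort(cohort, models, graph, horizon_steps = horizon_steps,
                  replicates = replicates, seed = seed, occupancy = FALSE)
}

#' Simulate a cohort of individuals
#'
#' @param cohort Data frame of entry conditions: `person_id`, `label`,
#'   `risk_category`, `age_at_diagnosis`, `cci`, and optionally `history`
#'   (list column of label vectors) and `start_t` (first step to simulate,
#'   default 1, used for delayed entry).
#' @param models A `trs_model_set`.
#' @param graph A `trs_graph`.
#' @param horizon_steps,replicates,seed As in [simulate_person()].
#' @param occupancy Also tabulate per-step state occupancy over all
#'   person-replicates?
#' @return A `trs_trajectories` object: list with `events` (data frame
#'   `person_id`, `replicate`, `step`, `type`, `label`, `category`,
#'   `new_cci`), `terminal` (data frame `person_id`, `replicate`,
#'   `end_step`, `status` with status `HORIZON`/`PCA_DEATH`/`OTHER_DEATH`),
#'   `entry` (the cohort table), `occupancy` (data frame `step`, `state`,
#'   `proportion`, or `NULL`), `horizon` and `replicates`.
#' @export
simulate_cohort <- function(cohort, models, graph, horizon_steps = 326L,
                            replicates = 100L, seed = 1L, occupancy = TRUE) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (horizon_steps <= 0) stop("horizon must be positive", call. = FALSE)
  bad <- !cohort$label %in% transient_labels()
  if (any(bad)) {
    stop("entry states must be transient; offending person_id: ",
         paste(utils::head(cohort$person_id[bad]), collapse = ", "),
         call. = FALSE)
  }
  hist0 <- if (!is.null(cohort$history)) {
    vapply(cohort$history, history_mask, integer(1))
  } else rep(0L, nrow(cohort))
  start_t <- if (!is.null(cohort$start_t)) as.integer(cohort$start_t)
             else rep(1L, nrow(cohort))
  cm <- compile_models(models, graph)
  res <- .cpp_sim_engine(
    as.integer(cohort$person_id), label_code(cohort$label),
    as.integer(cohort$risk_category), as.double(cohort$age_at_diagnosis),
    as.integer(cohort$cci), hist0, start_t, cm,
    as.integer(horizon_steps), as.integer(replicates), 1L,
    as.double(seed), occupancy)
  structure(
    list(events = engine_events_frame(res$events),
         terminal = engine_terminal_frame(res$terminal),
         entry = cohort,
         occupancy = if (occupancy) {
           occupancy_frame(res$occupancy, horizon_steps,
                           nrow(cohort) * replicates)
         },
         horizon = as.integer(horizon_steps),
         replicates = as.integer(replicates), seed = seed),
    class = "trs_trajectories")
}

engine_events_frame <- function(ev) {
  data.frame(person_id = ev$person_id, replicate = ev$replicate,
             step = ev$step,
             type = c("CHANGE", "CCI_INC")[ev$type],
             label = ifelse(ev$type == 1L, code_label(pmax(ev$a, 1L)),
                            NA_character_),
             category = ifelse(ev$type == 1L, ev$b, NA_integer_),
             new_cci = ifelse(ev$type == 2L, ev$a, NA_integer_),
             stringsAsFactors = FALSE)
}

engine_terminal_frame <- function(tm) {
  data.frame(person_id = tm$person_id, replicate = tm$replicate,
             end_step = tm$end_step,
             status = ifelse(tm$status == 0L, "HORIZON",
                             code_label(pmax(tm$status, 1L))),
             stringsAsFactors = FALSE)
}

occupancy_frame <- function(occ, horizon, n_total) {
  data.frame(step = rep(seq_len(horizon), times = length(all_labels())),
             state = rep(all_labels(), each = horizon),
             proportion = as.vector(occ) / n_total,
             stringsAsFactors = FALSE)
}

#' @export
print.trs_trajectories <- function(x, ...) {
  cat("<simulated trajectories: ", nrow(x$entry), " persons x ",
      x$replicates, " replicates, horizon ", x$horizon, " steps, ",
      nrow(x$events), " events>\n", sep = "")
  invisible(x)
}

#' Expand simulated trajectories to per-step state sequences
#'
#' Reconstructs the full (step, state, risk category, CCI) sequence of each
#' person-replicate from the compact event representation. Intended for
#' small cohorts; cohort-scale summaries should use the event form or the
#' occupancy table directly.
#'
#' @param sim A `trs_trajectories` object.
#' @return Data frame with columns `person_id`, `replicate`, `step`,
#'   `state`, `risk_category`, `cci`.
#' @export
trajectory_states <- function(sim) {
  ent <- sim$entry
  out <- vector("list", nrow(sim$terminal))
  for (i in seq_len(nrow(sim$terminal))) {
    tr <- sim$terminal[i, ]
    e <- ent[ent$person_id == tr$person_id, ][1, ]
    ev <- sim$events[sim$events$person_id == tr$person_id &
                     sim$events$replicate == tr$replicate, ]
    n <- if (tr$status == "HORIZON") tr$end_step else tr$end_step
    steps <- seq_len(n)
    state <- rep(e$label, n); cat <- rep(e$risk_category, n)
    cci <- rep(e$cci, n)
    ch <- ev[ev$type == "CHANGE", ]
    for (j in seq_len(nrow(ch))) {
      from <- ch$step[j] + 1L
      if (from <= n) {
        state[from:n] <- ch$label[j]
        cat[from:n] <- ch$category[j]
      }
    }
    ci <- ev[ev$type == "CCI_INC", ]
    for (j in seq_len(nrow(ci))) {
      from <- ci$step[j] + 1L
      if (from <= n) cci[from:n] <- ci$new_cci[j]
    }
    if (tr$status != "HORIZON") {
      state[n] <- state[n] # death resolves at end_step; state row keeps the
                           # transient state occupied during the final step
    }
    out[[i]] <- data.frame(person_id = tr$person_id,
                           replicate = tr$replicate, step = steps,
                           state = state, risk_category = cat, cci = cci,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
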