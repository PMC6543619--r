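# Person-period preparation: expansion of dated registry records into the
# 4-week long format with time-updated age, comorbidity and history, left
# truncation with delayed entry, and the person-level train/validation
# split.

#' @import data.table
NULL

.datatable.aware <- TRUE

#' Expand a registry to 4-week person-period rows
#'
#' Step `t` covers days `(28(t-1), 28t]` after diagnosis (half-open,
#' right-inclusive); an event dated inside the interval becomes the row's
#' outcome. Each man contributes one row per step alive under follow-up,
#' ending at his death row or at censoring; a death and a treatment change
#' falling in the same step resolve to the death, matching the simulation's
#' draw order. Attained age on row `t` is
#' `age_at_diagnosis + 28 t / 365.25` (age at the end of the step), and CCI
#' increases take effect from the row after the increase. For persons with
#' delayed entry (see [apply_left_truncation()]) rows start at the entry
#' step, in the state and comorbidity level occupied there; earlier events
#' shape state, category, CCI and history but contribute no rows.
#'
#' @param registry A `trs_registry`.
#' @param graph A `trs_graph`.
#' @param step_days Step length in days (28).
#' @param horizon_steps Follow-up truncated at this step count
#'   (default 326 = 25 years of 4-week steps).
#' @return A `data.frame` (class `trs_long`) with columns `person_id`, `t`,
#'   `state`, `risk_category`, `steps_in_state`, `age`, `cci`,
#'   `hist_<LABEL>` indicators, `outcome` (`STAY`, `CHANGE`, `PCA_DEATH`,
#'   `OTHER_DEATH`), `dest_label`, `dest_category`, `cci_increased`,
#'   `new_cci`, `entry_label`.
#' @export
expand_to_steps <- function(registry, graph = build_default_graph(),
                            step_days = 28L, horizon_steps = 326L) {
  stopifnot(step_days > 0)
  p <- data.table::as.data.table(registry$persons)
  ev <- data.table::as.data.table(registry$events)
  if (nrow(ev)) {
    days <- as.numeric(ev$date -
                         p$diagnosis_date[match(ev$person_id, p$person_id)])
    endd <- as.numeric(p$end_date[match(ev$person_id, p$person_id)] -
                         p$diagnosis_date[match(ev$person_id, p$person_id)])
    bad <- days <= 0 | days > endd
    if (any(bad)) {
      stop("event dated outside follow-up for person_id ",
           paste(unique(ev$person_id[bad]), collapse = ", "), call. = FALSE)
    }
    ev[, step := as.integer(ceiling(days / step_days))]
  } else {
    ev[, step := integer(0)]
  }

  fu_days <- as.numeric(p$end_date - p$diagnosis_date)
  p[, raw_steps := as.integer(ceiling(fu_days / step_days))]
  p[, n_steps := pmin(raw_steps, as.integer(horizon_steps))]
  if (is.null(p$entry_step)) p[, entry_step := 1L]
  p <- p[n_steps >= entry_step]
  if (nrow(p) == 0) stop("no person contributes follow-up time",
                         call. = FALSE)

  lens <- p$n_steps - p$entry_step + 1L
  long <- data.table::data.table(
    person_id = rep(p$person_id, lens),
    t = unlist(Map(seq.int, p$entry_step, p$n_steps), use.names = FALSE))
  idx <- rep(seq_len(nrow(p)), lens)
  long[, `:=`(entry_label = p$entry_label[idx],
              age = p$age_at_diagnosis[idx] + step_days * t / 365.25)]

  # piecewise state / category / history from treatment-change events
  ch <- ev[type == "CHANGE"][order(person_id, step)]
  tl <- transient_labels()
  if (nrow(ch)) {
    ch[, origin := data.table::shift(label, fill = NA_character_),
       by = person_id]
    first <- is.na(ch$origin)
    ch$origin[first] <-
      p$entry_label[match(ch$person_id[first], p$person_id)]
    if (anyNA(ch$label) ||
        !all(paste(ch$origin, ch$label) %in%
               paste(graph$treatment_edges[, 1], graph$treatment_edges[, 2]))) {
      stop("treatment-change event violates the transition graph",
           call. = FALSE)
    }
    bit <- function(lab) bitwShiftL(1L, label_code(lab))
    ch[, hmask := Reduce(bitwOr, bit(origin), accumulate = TRUE),
       by = person_id]
    # state on row t is the state occupied during (t-1, t]: the last change
    # with step < t has already happened
    lk <- ch[, .(person_id, s = step, state = label, risk_category = category,
                 hmask, centry = step)]
    data.table::setkey(lk, person_id, s)
    long[, s := t - 1L]
    hit <- lk[long, on = c("person_id", "s"), roll = Inf]
    long[, s := NULL]
    long[, state := data.table::fifelse(is.na(hit$state), entry_label,
                                        hit$state)]
    ecat <- p$entry_category[idx]
    long[, risk_category := data.table::fifelse(is.na(hit$risk_category),
                                                ecat, hit$risk_category)]
    long[, hmask := data.table::fifelse(is.na(hit$hmask), 0L, hit$hmask)]
    long[, steps_in_state := data.table::fifelse(is.na(hit$centry), t,
                                                 t - hit$centry)]
  } else {
    long[, state := entry_label]
    long[, risk_category := p$entry_category[idx]]
    long[, hmask := 0L]
    long[, steps_in_state := t]
  }
  for (lab in tl) {
    long[, paste0("hist_", lab) :=
           bitwAnd(hmask, bitwShiftL(1L, label_code(lab))) > 0L]
  }
  long[, hmask := NULL]

  # time-updated CCI, effective the row after the increase
  ci <- ev[type == "CCI_INC"][order(person_id, step)]
  ecci <- p$cci_at_diagnosis[idx]
  if (nrow(ci)) {
    lkc <- ci[, .(person_id, s = step, cci_upd = new_cci)]
    data.table::setkey(lkc, person_id, s)
    long[, s := t - 1L]
    hc <- lkc[long, on = c("person_id", "s"), roll = Inf]
    long[, s := NULL]
    long[, cci := data.table::fifelse(is.na(hc$cci_upd), ecci, hc$cci_upd)]
  } else {
    long[, cci := ecci]
  }

  # outcomes
  long[, `:=`(outcome = "STAY", dest_label = NA_character_,
              dest_category = NA_integer_, cci_increased = FALSE,
              new_cci = NA_integer_)]
  if (nrow(ci)) {
    long[ci, on = c("person_id", t = "step"),
         `:=`(cci_increased = TRUE, new_cci = i.new_cci)]
  }
  if (nrow(ch)) {
    long[ch, on = c("person_id", t = "step"),
         `:=`(outcome = "CHANGE", dest_label = i.label,
              dest_category = i.category)]
  }
  # a death beyond the horizon is censored by the horizon, not relabelled
  dead <- p[end_status %in% absorbing_labels() & raw_steps <= n_steps,
            .(person_id, t = n_steps, end_status)]
  if (nrow(dead)) {
    long[dead, on = c("person_id", "t"),
         `:=`(outcome = i.end_status, dest_label = NA_character_,
              dest_category = NA_integer_)]
  }

  out <- as.data.frame(long)
  class(out) <- c("trs_long", class(out))
  attr(out, "horizon_steps") <- as.integer(horizon_steps)
  attr(out, "step_days") <- as.integer(step_days)
  out
}

#' Apply left truncation (delayed entry) at a calendar date
#'
#' Persons whose follow-up ended before the date are removed; the remainder
#' contribute person-period rows only from the first step that starts on or
#' after the date, entering in the state, risk category, comorbidity level
#' and treatment history they occupy at that date. Events before the date
#' still shape the entry context but produce no outcome rows. Left
#' truncation only reshapes the risk sets; calendar time is not a model
#' covariate.
#'
#' @param registry A `trs_registry`.
#' @param date Truncation date.
#' @return The registry with persons filtered and an `entry_step` column
#'   added, ready for [expand_to_steps()].
#' @export
apply_left_truncation <- function(registry, date) {
  date <- as.Date(date)
  p <- registry$persons
  d <- as.numeric(date - p$diagnosis_date)
  entry_step <- ifelse(d <= 0, 1L, as.integer(ceiling(d / 28)) + 1L)
  n_steps <- as.integer(ceiling(as.numeric(p$end_date - p$diagnosis_date) /
                                  28))
  keep <- p$end_date >= date & entry_step <= n_steps
  p$entry_step <- entry_step
  registry$persons <- p[keep, , drop = FALSE]
  registry$events <-
    registry$events[registry$events$person_id %in% p$person_id[keep], ,
                    drop = FALSE]
  registry$determinants <-
    registry$determinants[registry$determinants$person_id %in%
                            p$person_id[keep], , drop = FALSE]
  registry
}

#' Split a registry into training and validation halves
#'
#' Person-level (never row-level) random split, deterministic given the
#' seed; at the default fraction the two halves differ in size by at most
#' one person and partition the cohort exactly.
#'
#' @param registry A `trs_registry`.
#' @param seed Integer seed.
#' @param fraction Training fraction in (0, 1).
#' @return List with elements `train` and `validation`, both
#'   `trs_registry`.
#' @export
split_train_validation <- function(registry, seed = 1L, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  ids <- registry$persons$person_id
  if (length(ids) == 0) stop("registry is empty", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  shuffled <- sample(ids)
  n_train <- floor(length(ids) * fraction)
  train_ids <- shuffled[seq_len(n_train)]
  list(train = subset_registry(registry, train_ids),
       validation = subset_registry(registry, setdiff(ids, train_ids)))
}

subset_registry <- function(registry, ids) {
  registry$persons <-
    registry$persons[registry$persons$person_id %in% ids, , drop = FALSE]
  registry$events <-
    registry$events[registry$events$person_id %in% ids, , drop = FALSE]
  registry$determinants <-
    registry$determinants[registry$determinants$person_id %in% ids, ,
                          drop = FALSE]
  registry
}

#' Deferred state-entry records of a person-period table
#'
#' One record per treatment change, carrying the covariates at entry (age
#' and CCI at the change step, origin state and category, history including
#' the origin) and the realised destination category (possibly missing when
#' masked). Records entering `RTADJ` inherit the RP category directly and
#' are flagged `inherited`; they are excluded from ordinal
#' category-entry fitting.
#'
#' @param long A `trs_long` table.
#' @return Data frame of entry records.
#' @export
deferred_entries <- function(long) {
  rows <- long[long$outcome == "CHANGE", , drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(person_id = integer(0), step = integer(0),
                      dest = character(0), category = integer(0),
                      age = numeric(0), cci = integer(0),
                      state = character(0), risk_category = integer(0),
                      inherited = logical(0)))
  }
  out <- data.frame(person_id = rows$person_id, step = rows$t,
                    dest = rows$dest_label, category = rows$dest_category,
                    age = rows$age, cci = rows$cci,
                    state = rows$state, risk_category = rows$risk_category,
                    steps_in_state = rows$steps_in_state,
                    inherited = rows$dest_label == "RTADJ",
                    stringsAsFactors = FALSE)
  for (lab in transient_labels()) {
    col <- paste0("hist_", lab)
    out[[col]] <- rows[[col]] | rows$state == lab
  }
  out
}
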