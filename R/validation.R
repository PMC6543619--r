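# Internal validation: discrete-time competing-risks cumulative incidence
# of first and second transitions and of cause-specific death, computed the
# same way for observed person-period data and for simulated trajectories,
# plus landmark comparisons between the two.

new_cuminc <- function(label, inc, surv, n_at_risk, n0,
                       source = c("OBSERVED", "SIMULATED", "ORACLE")) {
  source <- match.arg(source)
  structure(list(label = label, steps = seq_len(nrow(inc)), inc = inc,
                 surv = surv, n_at_risk = n_at_risk, n0 = n0,
                 source = source),
            class = "trs_cuminc")
}

#' @export
print.trs_cuminc <- function(x, ...) {
  endpoint <- round(x$inc[nrow(x$inc), ], 4)
  cat("<", tolower(x$source), " cumulative incidence: ", x$label,
      ", n0 = ", x$n0, ", ", nrow(x$inc), " steps>\n", sep = "")
  print(endpoint)
  invisible(x)
}

#' Discrete-time competing-risks cumulative incidence
#'
#' The discrete-time Aalen-Johansen estimator
#' `CIF_k(t) = sum_{s <= t} h_k(s) S(s - 1)`, with `h_k(s)` the empirical
#' per-step probability of destination `k` among those at risk in step `s`
#' and `S` the all-cause event-free survival `prod(1 - sum_k h_k)`.
#' Censoring removes individuals from later risk sets; delayed entry adds
#' them only from their entry step. With complete follow-up and merged
#' destinations the estimator reduces to one minus the Kaplan-Meier curve
#' of the composite event.
#'
#' @param entry Integer vector: individuals are at risk from step
#'   `entry + 1` (0 = at risk from the first step).
#' @param exit Integer vector of last step at risk (event or censoring
#'   step).
#' @param event Character vector: destination label, or `NA` for censoring.
#' @param destinations Destination labels (columns of the result).
#' @param horizon Number of steps.
#' @param label Curve label.
#' @param source Data source tag.
#' @return A `trs_cuminc` with elements `inc` (steps x destinations),
#'   `surv`, `n_at_risk`, `n0`.
#' @export
discrete_cuminc <- function(entry, exit, event, destinations, horizon,
                            label = "", source = "OBSERVED") {
  stopifnot(length(entry) == length(exit), length(exit) == length(event))
  bad <- !is.na(event) & !event %in% destinations
  if (any(bad)) {
    stop("unknown destination event(s): ",
         paste(unique(event[bad]), collapse = ", "), call. = FALSE)
  }
  over <- exit > horizon
  event[over] <- NA
  exit <- pmin(exit, horizon)
  # n(t) = #{entry < t <= exit}
  ent_c <- cumsum(tabulate(pmin(entry, horizon) + 1L, horizon + 1L))
  ext_c <- cumsum(tabulate(exit, horizon))
  n_at_risk <- ent_c[seq_len(horizon)] - c(0, ext_c[seq_len(horizon - 1)])
  d <- vapply(destinations, function(k) {
    tabulate(exit[!is.na(event) & event == k], horizon)
  }, numeric(horizon))
  h <- d / ifelse(n_at_risk > 0, n_at_risk, 1)
  h[n_at_risk == 0, ] <- 0
  htot <- rowSums(h)
  surv <- cumprod(1 - htot)
  slag <- c(1, surv[-horizon])
  inc <- apply(h * slag, 2, cumsum)
  dimnames(inc) <- list(NULL, destinations)
  new_cuminc(label, inc, surv, n_at_risk, n0 = length(exit),
             source = source)
}

# first-exit summaries: one row per individual with entry offset, exit step
# and event label (NA = censored)

first_exit_long <- function(long) {
  dt <- data.table::as.data.table(long)
  hist_cols <- paste0("hist_", transient_labels())
  dt[, no_hist := rowSums(as.matrix(.SD)) == 0, .SDcols = hist_cols]
  seg <- dt[state == entry_label & no_hist]
  seg[, .(entry = min(t) - 1L, exit = max(t),
          event = {
            oc <- outcome[which.max(t)]
            dl <- dest_label[which.max(t)]
            data.table::fifelse(oc == "STAY", NA_character_,
                                data.table::fifelse(oc == "CHANGE", dl, oc))
          },
          entry_label = entry_label[1]),
      by = person_id]
}

first_exit_sim <- function(sim) {
  ch <- data.table::as.data.table(
    sim$events[sim$events$type == "CHANGE", , drop = FALSE])
  tm <- data.table::as.data.table(sim$terminal)
  if (nrow(ch)) {
    f <- ch[, .(c_step = min(step),
                c_label = label[which.min(step)],
                c_cat = category[which.min(step)]), by = .(person_id,
                                                           replicate)]
    tm <- merge(tm, f, by = c("person_id", "replicate"), all.x = TRUE)
  } else {
    tm[, `:=`(c_step = NA_integer_, c_label = NA_character_,
              c_cat = NA_integer_)]
  }
  ent <- sim$entry
  tm[, entry_label := ent$label[match(person_id, ent$person_id)]]
  tm[, exit := data.table::fifelse(!is.na(c_step), c_step, end_step)]
  tm[, event := data.table::fifelse(
    !is.na(c_step), c_label,
    data.table::fifelse(status == "HORIZON", NA_character_, status))]
  tm[, entry := 0L]
  tm
}

#' Cumulative incidence of the first transition, by entry state
#'
#' For each entry state, the competing-risks cumulative incidence of the
#' first transition out of it -- to each allowed treatment destination and
#' to either death -- on the time-since-diagnosis clock. Accepts an
#' observed person-period table (censoring handled by risk-set decrement;
#' persons whose follow-up starts after their first transition are
#' excluded) or simulated trajectories (no censoring before the horizon).
#'
#' @param data A `trs_long` table or `trs_trajectories` object.
#' @param graph A `trs_graph`.
#' @param horizon Steps to evaluate (defaults to the data's horizon).
#' @return Named list of `trs_cuminc`, one per entry state present.
#' @export
cuminc_first_transition <- function(data, graph = build_default_graph(),
                                    horizon = NULL) {
  if (inherits(data, "trs_trajectories")) {
    fe <- first_exit_sim(data)
    if (is.null(horizon)) horizon <- data$horizon
    src <- "SIMULATED"
  } else {
    fe <- first_exit_long(data)
    if (is.null(horizon)) horizon <- attr(data, "horizon_steps")
    if (is.null(horizon)) horizon <- max(fe$exit)
    src <- "OBSERVED"
  }
  out <- list()
  for (lab in intersect(graph$entry_labels, unique(fe$entry_label))) {
    sub <- fe[fe$entry_label == lab, ]
    out[[lab]] <- discrete_cuminc(sub$entry, sub$exit, sub$event,
                                  allowed_destinations(lab, graph),
                                  horizon, label = lab, source = src)
  }
  out
}

# second-exit summaries: individuals whose first transition entered one of
# the filter states; time axis stays on the diagnosis clock with delayed
# entry at the first-transition step

second_exit_long <- function(long, filter_labels) {
  dt <- data.table::as.data.table(long)
  hist_cols <- paste0("hist_", transient_labels())
  dt[, no_hist := rowSums(as.matrix(.SD)) == 0, .SDcols = hist_cols]
  if (!any(dt$no_hist & dt$outcome == "CHANGE")) {
    return(data.table::data.table(person_id = integer(0),
                                  entry = integer(0), exit = integer(0),
                                  event = character(0),
                                  post_label = character(0)))
  }
  firsts <- dt[no_hist & outcome == "CHANGE",
               .(f_step = min(t), f_label = dest_label[which.min(t)]),
               by = person_id]
  firsts <- firsts[f_label %in% filter_labels]
  if (nrow(firsts) == 0) return(firsts)
  seg <- dt[firsts, on = "person_id"][state == f_label & t > f_step]
  seg[, .(entry = f_step[1], exit = max(t),
          event = {
            oc <- outcome[which.max(t)]
            dl <- dest_label[which.max(t)]
            data.table::fifelse(oc == "STAY", NA_character_,
                                data.table::fifelse(oc == "CHANGE", dl, oc))
          },
          post_label = f_label[1]),
      by = person_id]
}

second_exit_sim <- function(sim, filter_labels) {
  ev <- data.table::as.data.table(
    sim$events[sim$events$type == "CHANGE", , drop = FALSE])
  if (nrow(ev) == 0) return(ev)
  data.table::setorder(ev, person_id, replicate, step)
  ev[, ord := seq_len(.N), by = .(person_id, replicate)]
  firsts <- ev[ord == 1L & label %in% filter_labels,
               .(person_id, replicate, f_step = step, f_label = label)]
  if (nrow(firsts) == 0) return(firsts)
  seconds <- ev[ord == 2L, .(person_id, replicate, s_step = step,
                             s_label = label)]
  tm <- data.table::as.data.table(sim$terminal)
  x <- merge(firsts, seconds, by = c("person_id", "replicate"),
             all.x = TRUE)
  x <- merge(x, tm, by = c("person_id", "replicate"))
  x[, entry := f_step]
  x[, exit := data.table::fifelse(!is.na(s_step), s_step, end_step)]
  x[, event := data.table::fifelse(
    !is.na(s_step), s_label,
    data.table::fifelse(status == "HORIZON", NA_character_, status))]
  x[, post_label := f_label]
  x
}

#' Cumulative incidence of the second transition
#'
#' Restricted to individuals whose first transition entered one of
#' `first_destinations` (e.g. the states reachable from primary RP or RT),
#' the competing-risks cumulative incidence of the next transition out of
#' that state. The time axis remains steps since diagnosis, with delayed
#' entry at the first-transition step, so landmark ages read on the same
#' clock as the first-transition curves.
#'
#' @param data A `trs_long` table or `trs_trajectories` object.
#' @param first_destinations Labels the first transition must have entered.
#' @param graph A `trs_graph`.
#' @param horizon Steps to evaluate.
#' @return Named list of `trs_cuminc`, one per post-transition state
#'   (named `after_<LABEL>`); an empty list with attribute `n_filtered = 0`
#'   when nobody's first transition entered the filter set.
#' @export
cuminc_second_transition <- function(data, first_destinations,
                                     graph = build_default_graph(),
                                     horizon = NULL) {
  if (inherits(data, "trs_trajectories")) {
    se <- second_exit_sim(data, first_destinations)
    if (is.null(horizon)) horizon <- data$horizon
    src <- "SIMULATED"
  } else {
    if (nrow(data) == 0) stop("empty person-period table", call. = FALSE)
    se <- second_exit_long(data, first_destinations)
    if (is.null(horizon)) horizon <- attr(data, "horizon_steps")
    src <- "OBSERVED"
  }
  if (nrow(se) == 0) {
    out <- list()
    attr(out, "n_filtered") <- 0L
    return(out)
  }
  out <- list()
  for (lab in sort(unique(se$post_label))) {
    sub <- se[se$post_label == lab, ]
    out[[paste0("after_", lab)]] <-
      discrete_cuminc(sub$entry, sub$exit, sub$event,
                      allowed_destinations(lab, graph), horizon,
                      label = paste0("after first transition to ", lab),
                      source = src)
  }
  attr(out, "n_filtered") <- nrow(se)
  out
}

#' Compare an observed and a simulated cumulative-incidence curve
#'
#' Per destination: pointwise differences (observed minus simulated), the
#' sup-norm difference over the grid, and a landmark table at the requested
#' years (step index `ceiling(y * 365.25 / 28)`).
#'
#' @param observed,simulated `trs_cuminc` objects on the same grid with the
#'   same destination set.
#' @param landmark_years Numeric years for the landmark table.
#' @return An object of class `trs_curve_comparison`: list with `label`,
#'   `sup_norm` (named per destination), `landmarks` (data frame) and
#'   `diff` (steps x destinations matrix).
#' @export
compare_curves <- function(observed, simulated,
                           landmark_years = c(10, 15, 20)) {
  if (!identical(colnames(observed$inc), colnames(simulated$inc)) ||
      nrow(observed$inc) != nrow(simulated$inc)) {
    stop("curves have mismatched grids or destination sets", call. = FALSE)
  }
  d <- observed$inc - simulated$inc
  sup <- apply(abs(d), 2, max)
  steps <- ceiling(landmark_years * 365.25 / 28)
  steps <- steps[steps <= nrow(observed$inc)]
  yrs <- landmark_years[seq_along(steps)]
  lm <- do.call(rbind, lapply(seq_along(steps), function(i) {
    data.frame(years = yrs[i], step = steps[i],
               destination = colnames(observed$inc),
               observed = observed$inc[steps[i], ],
               simulated = simulated$inc[steps[i], ],
               difference = d[steps[i], ], row.names = NULL)
  }))
  structure(list(label = observed$label, sup_norm = sup, landmarks = lm,
                 diff = d),
            class = "trs_curve_comparison")
}

#' @export
print.trs_curve_comparison <- function(x, ...) {
  cat("<observed vs simulated: ", x$label, ">\n", sep = "")
  cat("sup-norm differences:\n")
  print(round(x$sup_norm, 4))
  cat("landmarks:\n")
  print(transform(x$landmarks, observed = round(observed, 3),
                  simulated = round(simulated, 3),
                  difference = round(difference, 3)))
  invisible(x)
}

#' Plot a cumulative-incidence curve (optionally against a comparator)
#'
#' @param x A `trs_cuminc`.
#' @param comparator Optional second `trs_cuminc` drawn dashed.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.trs_cuminc <- function(x, comparator = NULL, ...) {
  yrs <- x$steps * 28 / 365.25
  graphics::matplot(yrs, x$inc, type = "l", lty = 1,
                    xlab = "years since diagnosis",
                    ylab = "cumulative incidence",
                    main = x$label, ...)
  if (!is.null(comparator)) {
    graphics::matlines(comparator$steps * 28 / 365.25, comparator$inc,
                       lty = 2)
  }
  graphics::legend("topleft", legend = colnames(x$inc),
                   col = seq_len(ncol(x$inc)), lty = 1, bty = "n",
                   cex = 0.8)
  invisible(x)
}
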