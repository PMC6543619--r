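# shared fixtures: all built in code at test time

default_graph <- build_default_graph()

# hand-built registry: diagnosis dates and dated events chosen per test
manual_registry <- function(persons, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(person_id = integer(0), step = integer(0),
                         date = as.Date(character(0)),
                         type = character(0), label = character(0),
                         category = integer(0), new_cci = integer(0),
                         stringsAsFactors = FALSE)
  }
  det <- data.frame(person_id = persons$person_id, step = 0L,
                    label = persons$entry_label,
                    category = persons$entry_category,
                    det1 = 0, det2 = 0, det3 = 0, deferred = FALSE,
                    observed = TRUE, stringsAsFactors = FALSE)
  structure(list(persons = persons, events = events, determinants = det),
            class = "trs_registry")
}

one_person <- function(entry_label = "RP", entry_category = 2L,
                       diagnosis = "2008-01-01", age = 65, cci = 0L,
                       end = "2010-01-01", status = "CENSORED") {
  data.frame(person_id = 1L, diagnosis_date = as.Date(diagnosis),
             age_at_diagnosis = age, cci_at_diagnosis = cci,
             entry_label = entry_label, entry_category = entry_category,
             end_status = status, end_date = as.Date(end),
             stringsAsFactors = FALSE)
}

# intercept-only model set with the given constant per-step probabilities
flat_models <- function(p_pca = 0, p_other = 0, p_dest = NULL,
                        entry_label = "WW", p_cci = 0) {
  constant_hazard_config(entry_label = entry_label,
                         p_dest = if (is.null(p_dest)) {
                           stats::setNames(numeric(0), character(0))
                         } else p_dest,
                         p_pca = p_pca, p_other = p_other, p_cci = p_cci,
                         n_persons = 10L)$truth_models
}

# minimal person-period table for intercept-only fitting exercises
intercept_long <- function(outcomes, state = "RT", dest = NULL) {
  n <- length(outcomes)
  df <- data.frame(person_id = seq_len(n), t = 1L, state = state,
                   risk_category = 1L, steps_in_state = 1L, age = 70,
                   cci = 0L, outcome = outcomes,
                   dest_label = if (is.null(dest)) NA_character_ else dest,
                   dest_category = NA_integer_, cci_increased = FALSE,
                   new_cci = NA_integer_, entry_label = state,
                   stringsAsFactors = FALSE)
  for (lab in transient_labels()) df[[paste0("hist_", lab)]] <- FALSE
  class(df) <- c("trs_long", class(df))
  attr(df, "horizon_steps") <- 326L
  df
}

intercept_specs <- function() {
  list(death_pca = "(Intercept)", death_other = "(Intercept)",
       destination = "(Intercept)", risk_entry = character(0),
       cci_logit = "(Intercept)", cci_rate = "(Intercept)")
}
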