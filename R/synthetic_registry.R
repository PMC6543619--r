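# Synthetic registry generation. The generator inverts the estimation
# pipeline: it draws entry conditions from a documented cohort composition,
# runs the same step engine as the simulator under a fully known truth model
# set, and emits the result in registry form (dated events, censoring,
# determinants subject to missingness). Because event dates are placed on
# 4-week step boundaries, person-period expansion recovers the generated
# step-level outcomes exactly, which the round-trip tests exploit.

#' Construct a synthetic-registry configuration
#'
#' @param n_persons Cohort size.
#' @param composition Named fractions over entry labels (must sum to 1).
#' @param age Named list per entry label: `mean`, `sd`, `min`, `max` of the
#'   truncated-normal age-at-diagnosis distribution.
#' @param cci Named list per entry label: probabilities over CCI 0..3.
#' @param entry_risk Named list per entry label: probabilities over the
#'   label's risk categories.
#' @param truth_models A `trs_model_set` of known parameters.
#' @param graph A `trs_graph`.
#' @param determinants List with `base`, `slope`, `sd` (length-3 numeric)
#'   and `corr`: determinant j at a state entry with category c is
#'   `base_j + slope_j (c - 1)` plus correlated Gaussian noise. These
#'   emulate staging variables without clinical semantics; their only role
#'   is to give the imputation model something to chain on.
#' @param missingness_rate Fraction of deferred-entry determinant vectors
#'   masked by [generate_registry()] (0 disables; masking can also be
#'   applied explicitly with [inject_missingness()]).
#' @param diagnosis_window Character or Date vector of length 2.
#' @param end_of_followup Optional administrative censoring date.
#' @param truncation_date Optional left-truncation date (applied by
#'   [apply_left_truncation()], stored here for provenance).
#' @param horizon_steps Follow-up horizon in 4-week steps (326 = 25 years).
#' @param seed Integer seed driving both the R-side entry draws and the
#'   engine's counter-based streams.
#' @return An object of class `trs_synth_config`.
#' @export
synth_config <- function(n_persons, composition, age, cci, entry_risk,
                         truth_models, graph = build_default_graph(),
                         determinants = list(base = c(0, 0, 0),
                                             slope = c(0.8, 0.6, 0.5),
                                             sd = c(1, 1, 1), corr = 0.5),
                         missingness_rate = 0,
                         diagnosis_window = c("1992-01-01", "2014-12-31"),
                         end_of_followup = NULL, truncation_date = NULL,
                         horizon_steps = 326L, seed = 1L) {
  cfg <- structure(
    list(n_persons = as.integer(n_persons), composition = composition,
         age = age, cci = cci, entry_risk = entry_risk,
         truth_models = truth_models, graph = graph,
         determinants = determinants,
         missingness_rate = missingness_rate,
         diagnosis_window = as.Date(diagnosis_window),
         end_of_followup = if (!is.null(end_of_followup))
           as.Date(end_of_followup),
         truncation_date = if (!is.null(truncation_date))
           as.Date(truncation_date),
         horizon_steps = as.integer(horizon_steps), seed = as.integer(seed)),
    class = "trs_synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_persons < 1) stop("n_persons must be positive", call. = FALSE)
  if (abs(sum(cfg$composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  labs <- names(cfg$composition)
  if (!all(labs %in% cfg$graph$entry_labels)) {
    stop("composition labels must be entry labels of the graph",
         call. = FALSE)
  }
  for (lab in labs) {
    if (is.null(cfg$age[[lab]]) || is.null(cfg$cci[[lab]]) ||
        is.null(cfg$entry_risk[[lab]])) {
      stop("age, cci and entry_risk must be specified for entry label '",
           lab, "'", call. = FALSE)
    }
    if (abs(sum(cfg$cci[[lab]]) - 1) > 1e-6 ||
        abs(sum(cfg$entry_risk[[lab]]) - 1) > 1e-6) {
      stop("cci and entry_risk probabilities must sum to 1 for '", lab, "'",
           call. = FALSE)
    }
    if (length(cfg$entry_risk[[lab]]) !=
        cfg$graph$risk_category_counts[[lab]]) {
      stop("entry_risk for '", lab, "' must cover all its categories",
           call. = FALSE)
    }
  }
  if (cfg$missingness_rate < 0 || cfg$missingness_rate > 1) {
    stop("missingness_rate must lie in [0, 1]", call. = FALSE)
  }
  check_model_set(cfg$truth_models, cfg$graph)
  invisible(cfg)
}

#' @export
print.trs_synth_config <- function(x, ...) {
  cat("<synthetic registry config: n = ", x$n_persons, ", entry {",
      paste(sprintf("%s %.1f%%", names(x$composition),
                    100 * x$composition), collapse = ", "),
      "}, horizon ", x$horizon_steps, " steps, seed ", x$seed, ">\n",
      sep = "")
  invisible(x)
}

#' Default ground-truth model set
#'
#' The truth parameters behind [default_truth_config()]. Baseline per-step
#' probabilities were chosen once, by back-calculating constant-hazard
#' approximations from long-run cumulative incidences typical of a nationwide
#' prostate-cancer registry (for example, roughly a fifth of surgically
#' treated men receiving adjuvant/salvage radiotherapy within ten years, and
#' a few percent moving from curative treatment to GnRH agonists within two
#' decades), with nonzero age, comorbidity, risk-category and
#' treatment-history effects throughout.
#'
#' @return A `trs_model_set`.
#' @export
default_truth_models <- function() {
  sp <- default_covariate_specs()
  dest <- function(origin, ...) {
    co <- cbind(...)
    multinom_model(origin, colnames(co), sp$destination, co)
  }
  zeta_for <- function(K) stats::qlogis(seq_len(K - 1) / K) + 1
  ord <- function(label) {
    K <- risk_category_counts(label)
    ordinal_model(label, K, zeta_for(K), sp$risk_entry, c(0.3, 0.2, 0.8))
  }
  cci_int <- c(AS = -6.3, WW = -6.0, RP = -6.4, RT = -6.3, RTADJ = -6.3,
               AA = -6.0, GNRH = -5.9)
  cci <- lapply(cci_int, function(b0) {
    list(logit = lp_model(sp$cci_logit, c(b0, 0.4, 0.2)),
         rate = lp_model(sp$cci_rate, log(0.5), family = "log"))
  })
  model_set(
    death_pca = lp_model(sp$death_pca,
                         c(-8.0, 0.3, 0.1, 0.2, 0.3,
                           0.2, -0.2, 0.0, 0.3, 0.3, 0.8,
                           0.35, -0.2)),
    death_other = lp_model(sp$death_other, c(-6.5, 0.9, 0.3, 0.6, 1.0)),
    destination = list(
      AS = dest("AS", RP = c(-6.0, -0.5, -0.3, 0.5),
                RT = c(-6.5, 0.1, -0.2, 0.5)),
      RP = dest("RP", RTADJ = c(-6.9, -0.2, -0.1, 0.5),
                AA = c(-9.0, 0.2, 0.0, 0.4),
                GNRH = c(-9.2, 0.3, 0.1, 0.5)),
      RT = dest("RT", AA = c(-8.8, 0.2, 0.1, 0.4),
                GNRH = c(-9.2, 0.3, 0.1, 0.4)),
      RTADJ = dest("RTADJ", AA = c(-8.5, 0.2, 0.1, 0.4),
                   GNRH = c(-7.6, 0.2, 0.1, 0.4)),
      WW = dest("WW", AA = c(-7.5, 0.2, 0.1, 0.3),
                GNRH = c(-6.8, 0.3, 0.1, 0.3)),
      AA = dest("AA", GNRH = c(-6.5, 0.1, 0.1, 0.3))),
    risk_entry = list(WW = ord("WW"), RP = ord("RP"), RT = ord("RT"),
                      AA = ord("AA"), GNRH = ord("GNRH")),
    cci = cci)
}

#' Default synthetic-cohort configuration
#'
#' Entry conditions mirror the published composition of a nationwide
#' prostate-cancer cohort of 118,743 men: primary-strategy fractions
#' proportional to 23,649 (AS pathway), 7,286 (WW), 32,537 (RP), 19,019
#' (RT), 7,178 (AA) and 29,074 (GnRH); per-strategy age distributions with
#' the published medians and interquartile ranges (normal, truncated to
#' 40..95); per-strategy baseline CCI distributions (marginal approximately
#' 66.5/17.2/9.5/6.8 percent for CCI 0/1/2/3+); and per-strategy entry
#' risk-category distributions. Transition dynamics come from
#' [default_truth_models()].
#'
#' @param n_persons Cohort size (defaults to 10,000; the published cohort
#'   scale is impractical for routine checks).
#' @param seed Integer seed.
#' @param ... Passed on to [synth_config()] to override defaults.
#' @return A `trs_synth_config`.
#' @examples
#' cfg <- default_truth_config(n_persons = 500, seed = 7)
#' cfg$composition[["RP"]]
#' @export
default_truth_config <- function(n_persons = 10000L, seed = 1L, ...) {
  counts <- c(AS = 23649, WW = 7286, RP = 32537, RT = 19019, AA = 7178,
              GNRH = 29074)
  iqr_sd <- function(q1, q3) (q3 - q1) / (2 * stats::qnorm(0.75))
  age <- list(
    AS = list(mean = 69, sd = iqr_sd(64, 74), min = 40, max = 95),
    WW = list(mean = 77, sd = iqr_sd(73, 81), min = 40, max = 95),
    RP = list(mean = 63, sd = iqr_sd(59, 67), min = 40, max = 95),
    RT = list(mean = 67, sd = iqr_sd(62, 71), min = 40, max = 95),
    AA = list(mean = 76, sd = iqr_sd(71, 81), min = 40, max = 95),
    GNRH = list(mean = 77, sd = iqr_sd(71, 82), min = 40, max = 95))
  norm1 <- function(x) x / sum(x)
  cci <- lapply(list(
    AS = c(65.0, 17.9, 10.0, 7.2), WW = c(58.4, 19.7, 13.0, 8.9),
    RP = c(77.6, 12.2, 6.1, 4.2), RT = c(70.3, 16.7, 7.9, 5.1),
    AA = c(59.6, 20.4, 11.2, 8.9), GNRH = c(56.5, 21.3, 12.9, 9.4)), norm1)
  entry_risk <- lapply(list(
    AS = c(31.9, 57.1, 10.9),
    WW = c(13.7, 13.8, 13.0, 17.9, 17.6, 24.0),
    RP = c(27.6, 30.7, 15.7, 18.1, 7.6, 0.3),
    RT = c(19.6, 8.2, 12.0, 14.7, 9.7, 11.3, 14.0, 10.4),
    AA = c(12.8, 12.1, 20.8, 16.2, 14.0, 8.8, 6.9, 8.3),
    GNRH = c(23.6, 8.9, 9.8, 6.2, 12.4, 8.5, 4.2, 26.4)), norm1)
  synth_config(n_persons = n_persons, composition = counts / sum(counts),
               age = age, cci = cci, entry_risk = entry_risk,
               truth_models = default_truth_models(), seed = seed, ...)
}

#' Covariate-free configuration with constant per-step probabilities
#'
#' A degenerate single-entry-state configuration in which every per-step
#' probability is a constant, so first-transition cumulative incidence has
#' the closed form used by [oracle_cuminc()]. Useful as an analytic test
#' bed.
#'
#' @param entry_label Entry state for the whole cohort.
#' @param p_dest Named per-step probabilities of the treatment destinations
#'   (must be destinations of `entry_label`; their sum must be < 1).
#' @param p_pca,p_other Constant per-step death probabilities.
#' @param p_cci Constant per-step probability of a comorbidity increase.
#' @param n_persons,horizon_steps,seed As in [synth_config()].
#' @return A `trs_synth_config` (AS-to-WW rule disabled).
#' @export
constant_hazard_config <- function(entry_label = "WW",
                                   p_dest = c(AA = 0.006, GNRH = 0.004),
                                   p_pca = 0, p_other = 0, p_cci = 0,
                                   n_persons = 10000L, horizon_steps = 326L,
                                   seed = 1L) {
  graph <- build_default_graph()
  stopifnot(sum(p_dest) < 1)
  lp0 <- function(p) if (p <= 0) -Inf else stats::qlogis(p)
  dests_all <- setdiff(allowed_destinations(entry_label, graph),
                       absorbing_labels())
  if (!all(names(p_dest) %in% dests_all)) {
    stop("p_dest names must be treatment destinations of '", entry_label,
         "'", call. = FALSE)
  }
  # multinomial intercepts reproducing the requested per-step probabilities
  dest <- lapply(transient_labels(), function(lab) {
    dd <- setdiff(allowed_destinations(lab, graph), absorbing_labels())
    if (!length(dd)) return(NULL)
    p <- stats::setNames(rep(0, length(dd)), dd)
    if (lab == entry_label) p[names(p_dest)] <- p_dest
    keep <- p > 0
    if (!any(keep)) {
      co <- matrix(-Inf, 1, length(dd), dimnames = list(NULL, dd))
    } else {
      co <- matrix(-Inf, 1, length(dd), dimnames = list(NULL, dd))
      co[1, names(p)[keep]] <- log(p[keep] / (1 - sum(p)))
    }
    multinom_model(lab, dd, "(Intercept)", co)
  })
  names(dest) <- transient_labels()
  dest <- Filter(Negate(is.null), dest)
  ord <- lapply(setdiff(unique(graph$treatment_edges[, 2]), "RTADJ"),
                function(lab) {
    K <- risk_category_counts(lab)
    ordinal_model(lab, K, stats::qlogis(seq_len(K - 1) / K),
                  character(0), numeric(0))
  })
  names(ord) <- setdiff(unique(graph$treatment_edges[, 2]), "RTADJ")
  cci <- lapply(transient_labels(), function(lab) {
    list(logit = lp_model("(Intercept)", lp0(p_cci)),
         rate = lp_model("(Intercept)", log(0.5), family = "log"))
  })
  names(cci) <- transient_labels()
  truth <- model_set(
    death_pca = lp_model("(Intercept)", lp0(p_pca)),
    death_other = lp_model("(Intercept)", lp0(p_other)),
    destination = dest, risk_entry = ord, cci = cci,
    as_ww_thresholds = NULL)
  comp <- stats::setNames(1, entry_label)
  K <- risk_category_counts(entry_label)
  synth_config(
    n_persons = n_persons, composition = comp,
    age = stats::setNames(list(list(mean = 70, sd = 5, min = 40, max = 95)),
                          entry_label),
    cci = stats::setNames(list(c(1, 0, 0, 0)), entry_label),
    entry_risk = stats::setNames(list(rep(1 / K, K)), entry_label),
    truth_models = truth, graph = graph, horizon_steps = horizon_steps,
    seed = seed)
}

# truncated-normal draw via the probability-integral transform
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic registry
#'
#' Draws entry conditions (strategy, age, CCI, risk category, diagnosis date
#' uniform over the configured window), runs the discrete-time step engine
#' under the configuration's truth models (replicate stream 0 of the
#' counter-based generator), dates every step event as
#' `diagnosis_date + 28 t` days, censors horizon survivors, and attaches
#' risk-determinant vectors at every state entry. Deterministic given the
#' configuration seed.
#'
#' @param config A `trs_synth_config`.
#' @return An object of class `trs_registry`: list with data frames
#'   `persons` (`person_id`, `diagnosis_date`, `age_at_diagnosis`,
#'   `cci_at_diagnosis`, `entry_label`, `entry_category`, `end_date`,
#'   `end_status`), `events` (`person_id`, `step`, `date`, `type`, `label`,
#'   `category`, `new_cci`) and `determinants` (`person_id`, `step`,
#'   `label`, `category`, `det1..det3`, `deferred`, `observed`).
#' @export
generate_registry <- function(config) {
  validate_synth_config(config)
  n <- config$n_persons
  labs <- names(config$composition)
  withr_seed <- function(expr) expr # R-side draws under set.seed below
  set.seed(config$seed %% .Machine$integer.max)

  entry_label <- sample(labs, n, replace = TRUE,
                        prob = as.numeric(config$composition))
  age <- numeric(n); cci <- integer(n); cat <- integer(n)
  for (lab in labs) {
    idx <- which(entry_label == lab)
    if (!length(idx)) next
    a <- config$age[[lab]]
    age[idx] <- rtnorm(length(idx), a$mean, a$sd, a$min, a$max)
    cci[idx] <- sample(0:3, length(idx), replace = TRUE,
                       prob = config$cci[[lab]])
    cat[idx] <- sample.int(length(config$entry_risk[[lab]]), length(idx),
                           replace = TRUE, prob = config$entry_risk[[lab]])
  }
  win <- as.integer(config$diagnosis_window)
  diag_date <- as.Date(sample(win[1]:win[2], n, replace = TRUE),
                       origin = "1970-01-01")

  cm <- compile_models(config$truth_models, config$graph)
  res <- .cpp_sim_engine(seq_len(n), label_code(entry_label), cat,
                         age, cci, rep(0L, n), rep(1L, n), cm,
                         config$horizon_steps, 1L, 0L,
                         as.double(config$seed), FALSE)
  events <- engine_events_frame(res$events)
  terminal <- engine_terminal_frame(res$terminal)

  persons <- data.frame(
    person_id = seq_len(n), diagnosis_date = diag_date,
    age_at_diagnosis = age, cci_at_diagnosis = cci,
    entry_label = entry_label, entry_category = cat,
    stringsAsFactors = FALSE)
  ord <- match(persons$person_id, terminal$person_id)
  persons$end_status <- ifelse(terminal$status[ord] == "HORIZON",
                               "CENSORED", terminal$status[ord])
  persons$end_date <- persons$diagnosis_date + 28L * terminal$end_step[ord]
  events$date <- persons$diagnosis_date[events$person_id] + 28L * events$step

  # administrative end of follow-up, if configured
  if (!is.null(config$end_of_followup)) {
    eofu <- config$end_of_followup
    cut <- persons$end_date > eofu
    persons$end_date[cut] <- eofu
    persons$end_status[cut] <- "CENSORED"
    keep <- events$date <= persons$end_date[events$person_id]
    events <- events[keep, , drop = FALSE]
  }

  # determinant vectors at every state entry (primary entry step 0 and each
  # treatment change); deferred entries are the maskable ones
  ch <- events[events$type == "CHANGE", c("person_id", "step", "label",
                                          "category")]
  det_tab <- rbind(
    data.frame(person_id = persons$person_id, step = 0L,
               label = persons$entry_label,
               category = persons$entry_category, deferred = FALSE,
               stringsAsFactors = FALSE),
    if (nrow(ch)) data.frame(person_id = ch$person_id, step = ch$step,
                             label = ch$label, category = ch$category,
                             deferred = TRUE, stringsAsFactors = FALSE))
  dpar <- config$determinants
  m <- nrow(det_tab)
  R <- matrix(dpar$corr, 3, 3); diag(R) <- 1
  L <- chol(R)
  eps <- matrix(stats::rnorm(3 * m), m, 3) %*% L
  dets <- sweep(eps, 2, dpar$sd, `*`)
  for (j in 1:3) {
    dets[, j] <- dpar$base[j] + dpar$slope[j] * (det_tab$category - 1) +
      dets[, j]
  }
  det_tab$det1 <- dets[, 1]; det_tab$det2 <- dets[, 2]
  det_tab$det3 <- dets[, 3]
  det_tab$observed <- TRUE

  reg <- structure(list(persons = persons, events = events,
                        determinants = det_tab),
                   class = "trs_registry")
  attr(reg, "config") <- config
  if (config$missingness_rate > 0) {
    reg <- inject_missingness(reg, config$missingness_rate,
                              seed = config$seed + 1L)
  }
  reg
}

#' @export
print.trs_registry <- function(x, ...) {
  cat("<registry: ", nrow(x$persons), " persons, ", nrow(x$events),
      " events (", sum(x$events$type == "CHANGE"), " treatment changes), ",
      sum(x$persons$end_status != "CENSORED"), " deaths>\n", sep = "")
  invisible(x)
}

#' Mask risk determinants at deferred state entries
#'
#' Emulates the registry's missing-data pattern: staging variables are
#' reported at diagnosis but not routinely at later treatment changes. Each
#' deferred-entry determinant vector is masked independently with the given
#' probability (missing completely at random); the realised risk category at
#' that entry is hidden along with it. Primary-entry determinants are never
#' masked.
#'
#' @param registry A `trs_registry`.
#' @param rate Masking probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The masked registry.
#' @export
inject_missingness <- function(registry, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (rate == 0) return(registry)
  set.seed(seed %% .Machine$integer.max)
  det <- registry$determinants
  mask <- det$deferred & stats::runif(nrow(det)) < rate
  det$det1[mask] <- NA_real_; det$det2[mask] <- NA_real_
  det$det3[mask] <- NA_real_
  det$category[mask] <- NA_integer_
  det$observed[mask] <- FALSE
  registry$determinants <- det
  if (any(mask)) {
    key_ev <- paste(registry$events$person_id, registry$events$step,
                    registry$events$type == "CHANGE")
    key_ms <- paste(det$person_id[mask], det$step[mask], TRUE)
    registry$events$category[key_ev %in% key_ms] <- NA_integer_
  }
  registry
}

#' Ground-truth cumulative incidence of the first transition
#'
#' For a covariate-free configuration (all relevant models intercept-only
#' and the AS-to-WW rule disabled) the first-transition cumulative incidence
#' has the closed form `CIF_k(t) = (h_k / h_tot) (1 - (1 - h_tot)^t)`, where
#' the effective per-step hazards compose the fixed draw order:
#' `h_pca = p_pca`, `h_other = (1 - p_pca) p_other`, and
#' `h_dest = (1 - p_pca)(1 - p_other) p_dest`. For covariate-dependent truth
#' a Monte-Carlo oracle over at least `replicates` generated trajectories is
#' returned instead.
#'
#' @param config A `trs_synth_config`.
#' @param entry_label Entry state.
#' @param horizon_steps Steps to evaluate.
#' @param replicates Trajectory count for the Monte-Carlo branch; required
#'   when the truth models are covariate-dependent.
#' @return A `trs_cuminc` curve (source `"ORACLE"`).
#' @export
oracle_cuminc <- function(config, entry_label,
                          horizon_steps = config$horizon_steps,
                          replicates = NULL) {
  tm <- config$truth_models
  intercept_only <- function(m) identical(m$spec, "(Intercept)")
  dm <- tm$destination[[entry_label]]
  free <- intercept_only(tm$death_pca) && intercept_only(tm$death_other) &&
    (is.null(dm) || identical(dm$spec, "(Intercept)")) &&
    (entry_label != "AS" || is.null(tm$as_ww_thresholds))
  dests <- allowed_destinations(entry_label, config$graph)
  if (free) {
    p_pca <- stats::plogis(tm$death_pca$coef[[1]])
    p_oth <- stats::plogis(tm$death_other$coef[[1]])
    h <- stats::setNames(numeric(length(dests)), dests)
    h["PCA_DEATH"] <- p_pca
    h["OTHER_DEATH"] <- (1 - p_pca) * p_oth
    if (!is.null(dm) && length(dm$destinations)) {
      ex <- exp(dm$coef[1, ])
      pd <- ex / (1 + sum(ex))
      h[dm$destinations] <- (1 - p_pca) * (1 - p_oth) * pd
    }
    htot <- sum(h)
    t <- seq_len(horizon_steps)
    inc <- vapply(dests, function(k) {
      if (htot == 0) rep(0, horizon_steps)
      else (h[[k]] / htot) * (1 - (1 - htot)^t)
    }, numeric(horizon_steps))
    return(new_cuminc(entry_label, inc, surv = (1 - htot)^t,
                      n_at_risk = rep(NA_integer_, horizon_steps),
                      n0 = NA_integer_, source = "ORACLE"))
  }
  if (is.null(replicates)) {
    stop("covariate-dependent truth models need a Monte-Carlo replicate ",
         "count", call. = FALSE)
  }
  cfg <- config
  cfg$n_persons <- as.integer(replicates)
  cfg$composition <- stats::setNames(1, entry_label)
  reg <- generate_registry(cfg)
  crv <- cuminc_first_transition(expand_to_steps(reg, cfg$graph),
                                 cfg$graph)[[entry_label]]
  crv$source <- "ORACLE"
  crv
}

#' Write or read a registry as plain CSV files
#'
#' @param registry A `trs_registry`.
#' @param dir Directory for `persons.csv`, `events.csv`,
#'   `determinants.csv`.
#' @return `write_registry_csv`: `dir`, invisibly. `read_registry_csv`: a
#'   `trs_registry`.
#' @export
write_registry_csv <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(registry$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(registry$determinants,
                   file.path(dir, "determinants.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(dir) {
  persons <- utils::read.csv(file.path(dir, "persons.csv"),
                             stringsAsFactors = FALSE)
  persons$diagnosis_date <- as.Date(persons$diagnosis_date)
  persons$end_date <- as.Date(persons$end_date)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  events$date <- as.Date(events$date)
  determinants <- utils::read.csv(file.path(dir, "determinants.csv"),
                                  stringsAsFactors = FALSE)
  structure(list(persons = persons, events = events,
                 determinants = determinants), class = "trs_registry")
}

#' Entry conditions of a registry cohort
#'
#' @param registry A `trs_registry`.
#' @return Data frame suitable for [simulate_cohort()]: one row per person
#'   at diagnosis.
#' @export
entry_table <- function(registry) {
  p <- registry$persons
  data.frame(person_id = p$person_id, label = p$entry_label,
             risk_category = p$entry_category,
             age_at_diagnosis = p$age_at_diagnosis,
             cci = p$cci_at_diagnosis, stringsAsFactors = FALSE)
}
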