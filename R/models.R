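# Model containers for the fitted (or ground-truth) transition-probability
# models, prediction helpers, and the compiled form handed to the C++ engine.

#' Construct a linear-predictor model (logistic or log-linear)
#'
#' @param spec Covariate specification (see [default_covariate_specs()]).
#' @param coef Numeric coefficient vector aligned with `spec`.
#' @param se Optional standard errors.
#' @param family `"logistic"` (probability via inverse logit) or `"log"`
#'   (positive rate via exp), the latter used for the zero-truncated Poisson
#'   increment rate.
#' @param n Number of rows the model was fitted on (0 for truth models).
#' @return An object of class `trs_lp_model`.
#' @export
lp_model <- function(spec, coef, se = NULL, family = c("logistic", "log"),
                     n = 0L) {
  family <- match.arg(family)
  parse_terms(spec) # validates
  stopifnot(length(coef) == length(spec))
  structure(list(spec = spec, coef = stats::setNames(as.numeric(coef), spec),
                 se = if (!is.null(se)) stats::setNames(as.numeric(se), spec),
                 family = family, n = as.integer(n)),
            class = "trs_lp_model")
}

#' @export
print.trs_lp_model <- function(x, ...) {
  cat("<", x$family, " model, ", length(x$coef), " terms",
      if (x$n > 0) paste0(", n = ", x$n), ">\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

predict_lp <- function(model, df) {
  eta <- drop(build_design(df, model$spec) %*% model$coef)
  if (model$family == "logistic") stats::plogis(eta) else exp(eta)
}

#' Construct a multinomial destination model
#'
#' One multinomial logistic model per origin state, with "stay" as the
#' reference outcome, guarantees that within-step destination probabilities
#' sum to at most one without renormalisation.
#'
#' @param origin Origin state label.
#' @param destinations Destination labels in draw order.
#' @param spec Covariate specification.
#' @param coef p x D matrix (one column per destination).
#' @param se Optional matrix of standard errors.
#' @param n Fitted-on row count.
#' @return An object of class `trs_multinom_model`.
#' @export
multinom_model <- function(origin, destinations, spec, coef, se = NULL,
                           n = 0L) {
  coef <- as.matrix(coef)
  stopifnot(nrow(coef) == length(spec),
            ncol(coef) == length(destinations))
  dimnames(coef) <- list(spec, destinations)
  structure(list(origin = origin, destinations = destinations, spec = spec,
                 coef = coef, se = se, n = as.integer(n)),
            class = "trs_multinom_model")
}

# probabilities over c(destinations, STAY); rows of df
predict_destination <- function(model, df) {
  if (length(model$destinations) == 0) {
    return(matrix(1, nrow(df), 1, dimnames = list(NULL, "STAY")))
  }
  X <- build_design(df, model$spec)
  eta <- X %*% model$coef
  ex <- exp(eta)
  denom <- 1 + rowSums(ex)
  p <- cbind(ex / denom, STAY = 1 / denom)
  colnames(p) <- c(model$destinations, "STAY")
  p
}

#' Construct a proportional-odds ordinal model for risk-category entry
#'
#' Parameterised as in [MASS::polr()]: cumulative logits
#' `P(Y <= j) = plogis(zeta_j - eta)` with `eta` the linear predictor
#' (no intercept term).
#'
#' @param label Destination state label whose category is drawn.
#' @param K Number of categories.
#' @param zeta Strictly increasing threshold vector of length `K - 1`.
#' @param spec Covariate specification (no intercept).
#' @param coef Coefficient vector.
#' @param se,se_zeta Optional standard errors.
#' @param n Fitted-on entry count.
#' @return An object of class `trs_ordinal_model`.
#' @export
ordinal_model <- function(label, K, zeta, spec, coef, se = NULL,
                          se_zeta = NULL, n = 0L) {
  stopifnot(length(zeta) == K - 1, length(coef) == length(spec))
  if (any(diff(zeta) <= 0)) {
    stop("ordinal thresholds must be strictly increasing", call. = FALSE)
  }
  if ("(Intercept)" %in% spec) {
    stop("ordinal models have thresholds in place of an intercept",
         call. = FALSE)
  }
  structure(list(label = label, K = as.integer(K), zeta = as.numeric(zeta),
                 spec = spec, coef = stats::setNames(as.numeric(coef), spec),
                 se = se, se_zeta = se_zeta, n = as.integer(n)),
            class = "trs_ordinal_model")
}

# n x K matrix of category probabilities
predict_ordinal <- function(model, df) {
  eta <- if (length(model$coef)) {
    drop(build_design(df, model$spec) %*% model$coef)
  } else rep(0, nrow(df))
  cum <- stats::plogis(outer(-eta, model$zeta, `+`))
  p <- cbind(cum, 1) - cbind(0, cum)
  colnames(p) <- seq_len(model$K)
  p
}

#' Assemble a fitted model set
#'
#' The complete parameter bundle driving one simulation: the two death
#' models (prostate-cancer death; other-cause death conditional on surviving
#' the first draw), one multinomial destination model per origin state with a
#' treatment successor, one ordinal category-entry model per state that can
#' be entered by a stochastic category draw, and the per-state comorbidity
#' transition model (logistic any-increase plus zero-truncated Poisson
#' increment, capped at CCI 3).
#'
#' @param death_pca,death_other `trs_lp_model` objects.
#' @param destination Named list of `trs_multinom_model`, one per origin
#'   label with at least one treatment destination.
#' @param risk_entry Named list of `trs_ordinal_model`, one per destination
#'   label entered via an ordinal draw (all except the inherited RP to RTADJ
#'   transition and primary entry).
#' @param cci Named list per transient label with elements `logit`
#'   (`trs_lp_model`, logistic) and `rate` (`trs_lp_model`, log family).
#' @param as_ww_thresholds Age thresholds of the deterministic AS-to-WW rule,
#'   or `NULL` to disable the rule.
#' @param meta Optional metadata (e.g. pooling provenance).
#' @return An object of class `trs_model_set`.
#' @export
model_set <- function(death_pca, death_other, destination, risk_entry, cci,
                      as_ww_thresholds = default_as_ww_thresholds(),
                      meta = list()) {
  stopifnot(inherits(death_pca, "trs_lp_model"),
            inherits(death_other, "trs_lp_model"))
  for (m in destination) stopifnot(inherits(m, "trs_multinom_model"))
  for (m in risk_entry) stopifnot(inherits(m, "trs_ordinal_model"))
  for (m in cci) {
    stopifnot(inherits(m$logit, "trs_lp_model"),
              inherits(m$rate, "trs_lp_model"))
  }
  structure(list(death_pca = death_pca, death_other = death_other,
                 destination = destination, risk_entry = risk_entry,
                 cci = cci, as_ww_thresholds = as_ww_thresholds, meta = meta),
            class = "trs_model_set")
}

#' @export
print.trs_model_set <- function(x, ...) {
  cat("<model set: destination models for {",
      paste(names(x$destination), collapse = ", "), "}, ordinal entry for {",
      paste(names(x$risk_entry), collapse = ", "), "}",
      if (length(x$meta$m)) paste0(", pooled over m = ", x$meta$m), ">\n",
      sep = "")
  invisible(x)
}

# check that a model set covers every transient label of a graph
check_model_set <- function(models, graph) {
  for (lab in transient_labels()) {
    dests <- setdiff(allowed_destinations(lab, graph), absorbing_labels())
    if (lab == "AS" && !is.null(models$as_ww_thresholds)) {
      dests <- setdiff(dests, "WW")
    }
    if (length(dests) && is.null(models$destination[[lab]])) {
      stop("model set lacks a destination model for origin '", lab, "'",
           call. = FALSE)
    }
    if (is.null(models$cci[[lab]])) {
      stop("model set lacks a CCI model for state '", lab, "'",
           call. = FALSE)
    }
  }
  # states enterable by ordinal draw: any treatment destination except the
  # inherited RP -> RTADJ edge
  ord <- setdiff(unique(graph$treatment_edges[, 2]), "RTADJ")
  miss <- setdiff(ord, names(models$risk_entry))
  if (length(miss)) {
    stop("model set lacks ordinal entry models for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(models)
}

# --- engine compilation -----------------------------------------------------

compile_lp <- function(m) {
  list(tc = parse_terms(m$spec), beta = unname(m$coef))
}

# Flatten a model set + graph into the plain list structure the C++ engine
# parses: everything indexed by integer label code.
compile_models <- function(models, graph) {
  check_model_set(models, graph)
  dest <- vector("list", 7L)
  ord <- vector("list", 7L)
  cci <- vector("list", 7L)
  for (lab in transient_labels()) {
    i <- label_code(lab)
    dm <- models$destination[[lab]]
    if (!is.null(dm) && length(dm$destinations)) {
      dest[[i]] <- list(dests = label_code(dm$destinations),
                        tc = parse_terms(dm$spec),
                        beta = unname(dm$coef))
    }
    om <- models$risk_entry[[lab]]
    if (!is.null(om)) {
      ord[[i]] <- list(K = om$K, zeta = om$zeta, tc = parse_terms(om$spec),
                       beta = unname(om$coef))
    }
    cm <- models$cci[[lab]]
    cci[[i]] <- list(logit = compile_lp(cm$logit), rate = compile_lp(cm$rate))
  }
  rule <- models$as_ww_thresholds
  list(death_pca = compile_lp(models$death_pca),
       death_other = compile_lp(models$death_other),
       destination = dest, ordinal = ord, cci = cci,
       as_ww_enabled = !is.null(rule),
       as_ww_thresholds = if (is.null(rule)) numeric(4) else unname(rule),
       inherit_from = c(RTADJ = label_code("RP")))
}

# --- JSON serialization -----------------------------------------------------

#' Serialize or restore a model set as JSON
#'
#' @param models A `trs_model_set`.
#' @param path Optional output file; when omitted the JSON string is
#'   returned.
#' @return `model_set_to_json`: the path or JSON string;
#'   `model_set_from_json`: a `trs_model_set`.
#' @export
model_set_to_json <- function(models, path = NULL) {
  ser_lp <- function(m) list(spec = m$spec, coef = unname(m$coef),
                             se = if (!is.null(m$se)) unname(m$se),
                             family = m$family, n = m$n)
  obj <- list(
    death_pca = ser_lp(models$death_pca),
    death_other = ser_lp(models$death_other),
    destination = lapply(models$destination, function(m) {
      list(origin = m$origin, destinations = m$destinations, spec = m$spec,
           coef = m$coef, n = m$n)
    }),
    risk_entry = lapply(models$risk_entry, function(m) {
      list(label = m$label, K = m$K, zeta = m$zeta, spec = m$spec,
           coef = unname(m$coef), n = m$n)
    }),
    cci = lapply(models$cci, function(m) {
      list(logit = ser_lp(m$logit), rate = ser_lp(m$rate))
    }),
    as_ww_thresholds = models$as_ww_thresholds,
    meta = models$meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_set_to_json
#' @export
model_set_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  de_lp <- function(o) lp_model(o$spec, o$coef, se = o$se,
                                family = o$family, n = o$n)
  model_set(
    death_pca = de_lp(obj$death_pca),
    death_other = de_lp(obj$death_other),
    destination = lapply(obj$destination, function(o) {
      multinom_model(o$origin, o$destinations, o$spec,
                     matrix(unlist(o$coef), nrow = length(o$spec)), n = o$n)
    }),
    risk_entry = lapply(obj$risk_entry, function(o) {
      ordinal_model(o$label, o$K, o$zeta, o$spec, o$coef, n = o$n)
    }),
    cci = lapply(obj$cci, function(o) {
      list(logit = de_lp(o$logit), rate = de_lp(o$rate))
    }),
    as_ww_thresholds = if (length(obj$as_ww_thresholds)) {
      stats::setNames(unlist(obj$as_ww_thresholds), 0:3)
    },
    meta = obj$meta)
}
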