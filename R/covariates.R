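# Covariate terms shared between R-side model fitting and the C++ step
# engine. A covariate specification is a character vector of term names; each
# term maps to an integer (code, argument) pair that the engine evaluates on
# the simulated context, and to a design-matrix column that the fitting code
# evaluates on person-period rows. Keeping one term vocabulary on both sides
# is what makes estimation and simulation congruent.
#
# Vocabulary:
#   "(Intercept)"        constant 1
#   "age10"              (attained age - 70) / 10
#   "cci1","cci2","cci3" indicators of the exact CCI level (3 = 3+)
#   "cci"                CCI as a 0..3 score
#   "state:<LABEL>"      indicator of the current state label
#   "risk<k>"            indicator of risk category k
#   "risk"               risk category - 1 as an ordinal score
#   "hist:<LABEL>"       indicator that <LABEL> occurs in the treatment history
#   "tis"                steps already spent in the current state / 13

TERM_INTERCEPT <- 0L
TERM_AGE       <- 1L
TERM_CCI_IND   <- 2L
TERM_STATE_IND <- 3L
TERM_RISK_IND  <- 4L
TERM_HIST_IND  <- 5L
TERM_RISK_LIN  <- 6L
TERM_CCI_LIN   <- 7L
TERM_TIS       <- 8L

AGE_CENTER <- 70
AGE_SCALE  <- 10

# parse a character spec into a 2 x p integer matrix (code, arg)
parse_terms <- function(spec) {
  out <- vapply(spec, function(s) {
    if (s == "(Intercept)") return(c(TERM_INTERCEPT, 0L))
    if (s == "age10") return(c(TERM_AGE, 0L))
    if (s == "cci") return(c(TERM_CCI_LIN, 0L))
    if (s == "risk") return(c(TERM_RISK_LIN, 0L))
    if (s == "tis") return(c(TERM_TIS, 0L))
    if (grepl("^cci[1-3]$", s)) {
      return(c(TERM_CCI_IND, as.integer(substring(s, 4))))
    }
    if (grepl("^risk[1-9]$", s)) {
      return(c(TERM_RISK_IND, as.integer(substring(s, 5))))
    }
    if (grepl("^state:", s)) {
      return(c(TERM_STATE_IND, label_code(sub("^state:", "", s))))
    }
    if (grepl("^hist:", s)) {
      return(c(TERM_HIST_IND, label_code(sub("^hist:", "", s))))
    }
    stop("unknown covariate term '", s, "'", call. = FALSE)
  }, integer(2))
  matrix(out, nrow = 2, dimnames = list(c("code", "arg"), spec))
}

# Evaluate a covariate spec on person-period (or entry) rows. `df` must carry
# age, cci, state (label), risk_category, steps_in_state and hist_<LABEL>
# logical columns for any history terms used.
build_design <- function(df, spec) {
  tm <- parse_terms(spec)
  n <- nrow(df)
  X <- matrix(0, n, length(spec), dimnames = list(NULL, spec))
  for (j in seq_along(spec)) {
    code <- tm["code", j]; arg <- tm["arg", j]
    X[, j] <- switch(as.character(code),
      "0" = rep(1, n),
      "1" = (df$age - AGE_CENTER) / AGE_SCALE,
      "2" = as.numeric(df$cci == arg),
      "3" = as.numeric(df$state == code_label(arg)),
      "4" = as.numeric(df$risk_category == arg),
      "5" = as.numeric(df[[paste0("hist_", code_label(arg))]]),
      "6" = df$risk_category - 1,
      "7" = as.numeric(df$cci),
      "8" = df$steps_in_state / 13,
      stop("unhandled term code"))
  }
  X
}

#' Default covariate specifications for the transition models
#'
#' Transition probabilities depend on attained age, comorbidity, treatment
#' history and treatment-specific risk category. The default encodings are:
#' age linear (centred at 70, per decade), CCI as three level indicators in
#' the death models and as a 0..3 score elsewhere, the current state as
#' indicators in the death models (which pool all states), risk category as
#' an ordinal 0-based score, and history as a per-label indicator (previous
#' radical prostatectomy in the death models). The ordinal score for risk
#' category -- rather than per-level indicators -- is used by default because
#' category spaces differ between states (3 to 8 levels) and a shared
#' indicator basis across states is weakly identified in strata where high
#' categories are rare.
#'
#' @return Named list of character vectors: `death_pca`, `death_other`,
#'   `destination`, `risk_entry`, `cci_logit`, `cci_rate`.
#' @export
default_covariate_specs <- function() {
  list(
    death_pca = c("(Intercept)", "age10", "cci1", "cci2", "cci3",
                  paste0("state:", c("WW", "RP", "RT", "RTADJ", "AA", "GNRH")),
                  "risk", "hist:RP"),
    death_other = c("(Intercept)", "age10", "cci1", "cci2", "cci3"),
    destination = c("(Intercept)", "age10", "cci", "risk"),
    risk_entry = c("age10", "cci", "risk"),
    cci_logit = c("(Intercept)", "age10", "cci"),
    cci_rate = "(Intercept)")
}
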