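# Estimation of all transition-probability models from the person-period
# training table: the two sequential death models, one multinomial
# destination model per origin state, proportional-odds category-entry
# models, the per-state comorbidity model (logistic any-increase plus
# zero-truncated Poisson increment with cap censoring), chained-equation
# multiple imputation for masked deferred risk categories, and Rubin
# pooling across imputations.

GLM_EPS <- 1e-8
GLM_MAXIT <- 100L
RIDGE_PENALTY <- 1e-6

# logistic fit on a prebuilt design matrix, with a tiny-ridge fallback on
# separation / non-convergence
fit_logistic_design <- function(X, y, what) {
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (!any(y) || all(y)) {
    stop("cannot fit ", what, ": outcome never (or always) occurs",
         call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(y), family = stats::binomial(),
                   control = stats::glm.control(epsilon = GLM_EPS,
                                                maxit = GLM_MAXIT)))
  co <- fit$coefficients
  if (anyNA(co)) {
    stop("cannot fit ", what, ": design is rank deficient (aliased: ",
         paste(colnames(X)[is.na(co)], collapse = ", "), ")", call. = FALSE)
  }
  separated <- any(abs(co) > 15)
  if (!fit$converged || separated) {
    warning(what, ": ", if (separated) "quasi-separation" else
              "non-convergence",
            " detected; refitting with ridge penalty ", RIDGE_PENALTY,
            call. = FALSE)
    co <- ridge_logistic(X, as.numeric(y), RIDGE_PENALTY)
  }
  eta <- drop(X %*% co)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X * sqrt(w)) + diag(RIDGE_PENALTY, ncol(X))
  se <- sqrt(diag(solve(info)))
  lp_model(colnames(X), co, se = se, n = nrow(X))
}

ridge_logistic <- function(X, y, penalty, maxit = 200L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X * sqrt(w)) + diag(penalty, ncol(X)),
                 crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  stats::setNames(beta, colnames(X))
}

#' Fit the two sequential death models
#'
#' The probability of prostate-cancer death is a logistic regression on all
#' person-period rows; the probability of death from other causes is a
#' second logistic regression conditioned on surviving the first draw, i.e.
#' fitted on all rows except those ending in prostate-cancer death. Under
#' this composition the per-step probability of death from any cause is
#' `p1 + (1 - p1) p2`.
#'
#' @param long A `trs_long` person-period table.
#' @param specs Covariate specifications (see [default_covariate_specs()]);
#'   only `death_pca` and `death_other` are used.
#' @return List with `death_pca` and `death_other`, both `trs_lp_model`
#'   with standard errors.
#' @export
fit_death_models <- function(long, specs = default_covariate_specs()) {
  if (!any(long$outcome == "PCA_DEATH")) {
    stop("cannot fit death models: no PCA_DEATH outcomes in data",
         call. = FALSE)
  }
  if (!any(long$outcome == "OTHER_DEATH")) {
    stop("cannot fit death models: no OTHER_DEATH outcomes in data",
         call. = FALSE)
  }
  X1 <- build_design(long, specs$death_pca)
  m1 <- fit_logistic_design(X1, long$outcome == "PCA_DEATH",
                            "prostate-cancer death model")
  cond <- long$outcome != "PCA_DEATH"
  X2 <- build_design(long[cond, , drop = FALSE], specs$death_other)
  m2 <- fit_logistic_design(X2, long$outcome[cond] == "OTHER_DEATH",
                            "other-cause death model")
  list(death_pca = m1, death_other = m2)
}

#' Fit the treatment-destination model of one origin state
#'
#' A multinomial logistic model with "stay" as the reference outcome over
#' the origin's allowed treatment destinations, fitted by maximum likelihood
#' on the origin's person-period rows with outcome stay or treatment change.
#' Death rows are excluded: vital status is drawn first in the simulation,
#' so the destination model is conditional on surviving the step. For origin
#' AS the change to WW is produced by the deterministic age/CCI rule, not by
#' this model, so such rows are excluded and WW is not a stochastic
#' destination (disable with `rule_handled_ww = FALSE`). A destination with
#' no observed events is dropped with a warning and simulates with
#' probability zero.
#'
#' @param long A `trs_long` table.
#' @param origin Origin state label.
#' @param graph A `trs_graph`.
#' @param specs Covariate specifications.
#' @param rule_handled_ww Is AS to WW handled by the deterministic rule?
#' @return A `trs_multinom_model`.
#' @export
fit_destination_model <- function(long, origin,
                                  graph = build_default_graph(),
                                  specs = default_covariate_specs(),
                                  rule_handled_ww = TRUE) {
  dests <- setdiff(allowed_destinations(origin, graph), absorbing_labels())
  rows <- long[long$state == origin &
                 long$outcome %in% c("STAY", "CHANGE"), , drop = FALSE]
  if (origin == "AS" && rule_handled_ww) {
    dests <- setdiff(dests, "WW")
    rows <- rows[is.na(rows$dest_label) | rows$dest_label != "WW", ,
                 drop = FALSE]
  }
  if (nrow(rows) == 0) {
    stop("no person-period rows for origin '", origin, "'", call. = FALSE)
  }
  y <- ifelse(rows$outcome == "STAY", "STAY", rows$dest_label)
  observed <- intersect(dests, unique(y))
  dropped <- setdiff(dests, observed)
  if (length(dropped)) {
    warning("origin ", origin, ": no observed transitions to ",
            paste(dropped, collapse = ", "),
            "; destination(s) dropped (probability 0)", call. = FALSE)
  }
  if (length(observed) == 0) {
    return(multinom_model(origin, character(0), specs$destination,
                          matrix(numeric(0), length(specs$destination), 0),
                          n = nrow(rows)))
  }
  X <- build_design(rows, specs$destination)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  yf <- factor(y, levels = c("STAY", observed))
  dat <- data.frame(.y = yf, X, check.names = FALSE)
  form <- stats::as.formula(paste(
    ".y ~ 0 +", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- nnet::multinom(form, data = dat, Hess = TRUE, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(observed, names(co)))
  co <- t(co[observed, , drop = FALSE]) # p x D
  V <- tryCatch(solve(fit$Hessian), error = function(e) NULL)
  se <- if (!is.null(V)) {
    matrix(sqrt(pmax(diag(V), 0)), nrow = ncol(X),
           dimnames = list(colnames(X), observed))
  }
  multinom_model(origin, observed, specs$destination, co, se = se,
                 n = nrow(X))
}

#' Fit the ordinal category-entry model of one destination state
#'
#' Proportional-odds regression of the risk category realised at entry into
#' `dest_label` on the entry covariates (age, CCI, origin risk category by
#' default), fitted on non-inherited entry records with observed category.
#'
#' @param entries Entry records from [deferred_entries()].
#' @param dest_label Destination state.
#' @param specs Covariate specifications (`risk_entry` is used).
#' @param graph A `trs_graph`.
#' @return A `trs_ordinal_model`.
#' @export
fit_risk_category_model <- function(entries, dest_label,
                                    specs = default_covariate_specs(),
                                    graph = build_default_graph()) {
  K <- graph$risk_category_counts[[dest_label]]
  rows <- entries[entries$dest == dest_label & !entries$inherited &
                    !is.na(entries$category), , drop = FALSE]
  if (length(unique(rows$category)) < 2) {
    stop("cannot fit ordinal entry model for '", dest_label,
         "': fewer than 2 observed categories", call. = FALSE)
  }
  if (length(specs$risk_entry) == 0) {
    # thresholds-only proportional odds: the MLE is the empirical
    # cumulative logit
    cum <- cumsum(tabulate(rows$category, K)[-K]) / nrow(rows)
    cum <- pmin(pmax(cum, 1e-9), 1 - 1e-9)
    return(ordinal_model(dest_label, K, stats::qlogis(cum), character(0),
                         numeric(0),
                         se_zeta = sqrt(1 / (nrow(rows) * cum * (1 - cum))),
                         n = nrow(rows)))
  }
  X <- build_design(rows, specs$risk_entry)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  cat <- rows$category[keep]
  dat <- data.frame(.y = factor(cat, levels = seq_len(K)), X,
                    check.names = FALSE)
  form <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  start <- c(rep(0, ncol(X)),
             stats::qlogis(pmin(pmax(cumsum(tabulate(cat, K)[-K]) /
                                       length(cat), 1e-3), 1 - 1e-3)))
  fit <- MASS::polr(form, data = dat, method = "logistic", Hess = TRUE,
                    start = start)
  V <- stats::vcov(fit)
  p <- ncol(X)
  ordinal_model(dest_label, K, fit$zeta, specs$risk_entry,
                stats::setNames(fit$coefficients, colnames(X)),
                se = sqrt(diag(V))[seq_len(p)],
                se_zeta = sqrt(diag(V))[p + seq_len(K - 1)],
                n = nrow(X))
}

# zero-truncated Poisson regression, with right censoring at the CCI cap:
# an observed increment that hits the cap only says the true increment was
# at least that large
fit_ztp <- function(X, k, censored, what) {
  negll <- function(beta) {
    lam <- exp(drop(X %*% beta))
    ll_unc <- k * log(lam) - lam - lgamma(k + 1) - log1p(-exp(-lam))
    if (any(censored)) {
      cc <- which(censored)
      surv <- vapply(cc, function(i) {
        km <- k[i]
        if (km <= 1) return(1)
        1 - sum(stats::dpois(seq_len(km - 1), lam[i])) /
          (1 - exp(-lam[i]))
      }, numeric(1))
      ll_unc[cc] <- log(pmax(surv, 1e-300))
    }
    -sum(ll_unc)
  }
  opt <- stats::optim(rep(0, ncol(X)), negll, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("zero-truncated Poisson fit failed for ", what, call. = FALSE)
  }
  se <- sqrt(diag(tryCatch(solve(opt$hessian),
                           error = function(e) {
                             matrix(NA_real_, ncol(X), ncol(X))
                           })))
  lp_model(colnames(X), opt$par, se = se, family = "log", n = nrow(X))
}

#' Fit the per-state comorbidity transition model
#'
#' For each transient state: a logistic model for the probability of any
#' CCI increase in a step (fitted on rows with CCI below the cap of 3) and
#' a zero-truncated Poisson model for the increment size given an increase.
#' Increments that hit the cap are treated as right-censored in the Poisson
#' likelihood. A state with observed rows but no observed increases gets a
#' floored intercept (per-step probability 1e-6) with a warning.
#'
#' @param long A `trs_long` table.
#' @param specs Covariate specifications (`cci_logit`, `cci_rate`).
#' @param states States to fit (default: all with rows).
#' @return Named list per state with elements `logit` and `rate`.
#' @export
fit_cci_model <- function(long, specs = default_covariate_specs(),
                          states = NULL) {
  if (is.null(states)) states <- intersect(transient_labels(),
                                           unique(long$state))
  out <- list()
  for (lab in states) {
    rows <- long[long$state == lab & long$cci < 3, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop("no person-period rows at risk of CCI increase in state '", lab,
           "'", call. = FALSE)
    }
    Xl <- build_design(rows, specs$cci_logit)
    keep <- stats::complete.cases(Xl)
    rows <- rows[keep, , drop = FALSE]; Xl <- Xl[keep, , drop = FALSE]
    if (!any(rows$cci_increased)) {
      warning("state ", lab, ": no observed CCI increases; ",
              "intercept floored at probability 1e-6", call. = FALSE)
      co <- stats::setNames(rep(0, length(specs$cci_logit)),
                            specs$cci_logit)
      co["(Intercept)"] <- stats::qlogis(1e-6)
      logit <- lp_model(specs$cci_logit, co, n = nrow(rows))
      rate <- lp_model(specs$cci_rate,
                       rep(0, length(specs$cci_rate)), family = "log")
    } else {
      logit <- fit_logistic_design(Xl, rows$cci_increased,
                                   paste0("CCI increase model (", lab, ")"))
      inc <- rows[rows$cci_increased, , drop = FALSE]
      kk <- inc$new_cci - inc$cci
      censored <- inc$new_cci == 3L
      Xr <- build_design(inc, specs$cci_rate)
      rate <- fit_ztp(Xr, kk, censored,
                      paste0("CCI increment model (", lab, ")"))
    }
    out[[lab]] <- list(logit = logit, rate = rate)
  }
  out
}

#' Fit the complete transition-model set from a person-period table
#'
#' Orchestrates [fit_death_models()], [fit_destination_model()] per origin,
#' [fit_risk_category_model()] per ordinal-entry destination and
#' [fit_cci_model()], returning a simulation-ready [model_set()]. A
#' destination state with too few observed entries for an ordinal fit falls
#' back to its empirical category distribution (intercept-only thresholds)
#' with a warning.
#'
#' @param long A `trs_long` table.
#' @param graph A `trs_graph`.
#' @param specs Covariate specifications.
#' @param as_ww_thresholds Thresholds of the deterministic AS-to-WW rule
#'   (`NULL` disables the rule and lets AS to WW be fitted
#'   stochastically).
#' @return A `trs_model_set`.
#' @export
fit_model_set <- function(long, graph = build_default_graph(),
                          specs = default_covariate_specs(),
                          as_ww_thresholds = default_as_ww_thresholds()) {
  death <- fit_death_models(long, specs)
  dest <- list()
  for (lab in transient_labels()) {
    dd <- setdiff(allowed_destinations(lab, graph), absorbing_labels())
    if (lab == "AS" && !is.null(as_ww_thresholds)) dd <- setdiff(dd, "WW")
    if (!length(dd)) next
    dest[[lab]] <- fit_destination_model(
      long, lab, graph, specs,
      rule_handled_ww = !is.null(as_ww_thresholds))
  }
  entries <- deferred_entries(long)
  ord_labels <- setdiff(unique(graph$treatment_edges[, 2]), "RTADJ")
  risk_entry <- list()
  for (lab in ord_labels) {
    risk_entry[[lab]] <- tryCatch(
      fit_risk_category_model(entries, lab, specs, graph),
      error = function(e) {
        warning("ordinal entry model for '", lab,
                "' could not be fitted (", conditionMessage(e),
                "); falling back to the empirical category distribution",
                call. = FALSE)
        empirical_ordinal(entries, lab, graph)
      })
  }
  cci <- fit_cci_model(long, specs, states = transient_labels())
  model_set(death$death_pca, death$death_other, dest, risk_entry, cci,
            as_ww_thresholds = as_ww_thresholds,
            meta = list(n_rows = nrow(long)))
}

empirical_ordinal <- function(entries, lab, graph) {
  K <- graph$risk_category_counts[[lab]]
  rows <- entries[entries$dest == lab & !is.na(entries$category), ]
  counts <- tabulate(rows$category, K) + 0.5 # smoothed
  cum <- pmin(pmax(cumsum(counts)[-K] / sum(counts), 1e-6), 1 - 1e-6)
  ordinal_model(lab, K, sort(stats::qlogis(cum)), character(0), numeric(0),
                n = nrow(rows))
}

# ---- multiple imputation ---------------------------------------------------

#' Multiple imputation of masked deferred risk categories
#'
#' Chained-equation imputation of the missing deferred-entry determinants
#' and risk categories. Within each cycle the three determinant variables
#' are imputed from Bayesian linear regressions (posterior draws of the
#' residual variance and coefficients, then a predictive draw) and the
#' category from a per-destination proportional-odds model with a parameter
#' draw, falling back to the observed marginal when a destination has too
#' few observed entries. Predictors are the companion determinants, the
#' entry covariates (age, CCI, origin category), destination indicators and
#' post-entry outcome summaries (follow-up length after entry and cause of
#' death), so the imputation model sees the information the analysis models
#' use. Deterministic given the seed.
#'
#' @param registry A `trs_registry` with masked deferred entries.
#' @param graph A `trs_graph`.
#' @param m Number of imputations (at least 2; pooling is undefined below
#'   that).
#' @param iterations Chained-equation cycles (default 10).
#' @param seed Integer seed.
#' @param horizon_steps Passed to the internal person-period expansion.
#' @return List of `m` completed registries.
#' @export
mice_impute <- function(registry, graph = build_default_graph(), m = 5L,
                        iterations = 10L, seed = 1L, horizon_steps = 326L) {
  if (m < 2) stop("m must be at least 2 (pooling is undefined)",
                  call. = FALSE)
  det <- registry$determinants
  miss <- !det$observed
  if (!any(miss)) return(replicate(m, registry, simplify = FALSE))

  long <- expand_to_steps(registry, graph, horizon_steps = horizon_steps)
  ends <- registry$persons[, c("person_id", "end_status")]
  end_step <- tapply(long$t, long$person_id, max)
  det$age <- registry$persons$age_at_diagnosis[
    match(det$person_id, registry$persons$person_id)] +
    28 * det$step / 365.25
  ent <- deferred_entries(long)
  key_det <- paste(det$person_id, det$step)
  key_ent <- paste(ent$person_id, ent$step)
  ix <- match(key_det, key_ent)
  det$cci_entry <- ifelse(is.na(ix), registry$persons$cci_at_diagnosis[
    match(det$person_id, registry$persons$person_id)], ent$cci[ix])
  det$origin_risk <- ifelse(is.na(ix), det$category, ent$risk_category[ix])
  # an origin category can itself be hidden (entry following a masked
  # entry); fall back to the observed median rather than chain it
  if (anyNA(det$origin_risk)) {
    det$origin_risk[is.na(det$origin_risk)] <-
      stats::median(det$origin_risk, na.rm = TRUE)
  }
  det$fu <- (end_step[as.character(det$person_id)] - det$step) / 13
  st <- ends$end_status[match(det$person_id, ends$person_id)]
  det$died_pca <- as.numeric(st == "PCA_DEATH")
  det$died_other <- as.numeric(st == "OTHER_DEATH")
  # origin_risk of a masked row is its own (hidden) category only for
  # primary rows, which are never masked; for masked deferred rows the
  # origin category comes from the entry record and is observed
  base_pred <- function(d) {
    M <- cbind(1, d$age10, d$cci_entry, d$origin_risk, d$fu, d$died_pca,
               d$died_other)
    labs <- sort(unique(det$label))
    for (lab in labs[-1]) M <- cbind(M, as.numeric(d$label == lab))
    M
  }
  det$age10 <- (det$age - AGE_CENTER) / AGE_SCALE
  det_cols <- c("det1", "det2", "det3")
  K_of <- graph$risk_category_counts

  out <- vector("list", m)
  for (imp in seq_len(m)) {
    set.seed((seed + 7919L * imp) %% .Machine$integer.max)
    d <- det
    # initialise from observed marginals within destination label
    for (j in det_cols) {
      for (lab in unique(d$label[miss])) {
        rows <- miss & d$label == lab
        pool <- d[[j]][!miss & d$label == lab]
        if (!length(pool)) pool <- d[[j]][!miss]
        d[[j]][rows] <- sample(pool, sum(rows), replace = TRUE)
      }
    }
    for (lab in unique(d$label[miss])) {
      rows <- miss & d$label == lab
      pool <- d$category[!miss & d$label == lab]
      if (length(pool) < 2) pool <- seq_len(K_of[[lab]])
      d$category[rows] <- sample(pool, sum(rows), replace = TRUE)
    }
    for (cycle in seq_len(iterations)) {
      for (j in det_cols) {
        others <- setdiff(det_cols, j)
        P <- cbind(base_pred(d), d[[others[1]]], d[[others[2]]],
                   d$category)
        d[[j]][miss] <- bayes_lm_draw(P[!miss, , drop = FALSE],
                                      d[[j]][!miss],
                                      P[miss, , drop = FALSE])
      }
      for (lab in unique(d$label[miss])) {
        rows <- which(miss & d$label == lab)
        obs <- which(!miss & d$label == lab)
        K <- K_of[[lab]]
        # no label dummies here: the model is per destination label
        P <- cbind(d$age10, d$cci_entry, d$origin_risk, d$fu, d$died_pca,
                   d$died_other, d$det1, d$det2, d$det3)
        d$category[rows] <- draw_ordinal_imp(P[obs, , drop = FALSE],
                                             d$category[obs],
                                             P[rows, , drop = FALSE], K)
      }
    }
    reg <- registry
    reg$determinants[det_cols] <- d[det_cols]
    reg$determinants$category <- d$category
    # propagate imputed categories into the event stream
    ev_key <- paste(reg$events$person_id, reg$events$step,
                    reg$events$type == "CHANGE")
    d_key <- paste(d$person_id, d$step, d$deferred)
    hit <- match(ev_key, d_key)
    take <- !is.na(hit) & is.na(reg$events$category)
    reg$events$category[take] <- d$category[hit[take]]
    attr(reg, "imputation") <- imp
    out[[imp]] <- reg
  }
  out
}

# posterior-predictive draw from a Bayesian linear regression
bayes_lm_draw <- function(X, y, Xnew) {
  qr_ <- qr(X)
  r <- qr_$rank
  use <- qr_$pivot[seq_len(r)]
  Xu <- X[, use, drop = FALSE]
  XtX <- crossprod(Xu)
  bh <- solve(XtX, crossprod(Xu, y))
  rss <- sum((y - Xu %*% bh)^2)
  df <- max(nrow(X) - r, 1)
  sigma2 <- rss / stats::rchisq(1, df)
  Sig <- solve(XtX) * sigma2
  bdraw <- bh + drop(t(chol(Sig)) %*% stats::rnorm(r))
  drop(Xnew[, use, drop = FALSE] %*% bdraw) +
    stats::rnorm(nrow(Xnew), 0, sqrt(sigma2))
}

# ordinal predictive draw with approximate parameter uncertainty; marginal
# fallback when the fit is not possible
draw_ordinal_imp <- function(Xobs, yobs, Xnew, K) {
  marginal <- function() {
    counts <- tabulate(yobs, K) + 0.5
    sample.int(K, nrow(Xnew), replace = TRUE, prob = counts / sum(counts))
  }
  if (length(unique(yobs)) < 2 || nrow(Xobs) < ncol(Xobs) + K + 5) {
    return(marginal())
  }
  dat <- data.frame(.y = factor(yobs, levels = seq_len(K)), Xobs)
  form <- stats::as.formula(paste(".y ~",
                                  paste(colnames(dat)[-1], collapse = "+")))
  fit <- tryCatch(
    MASS::polr(form, data = dat, method = "logistic", Hess = TRUE),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$zeta) != K - 1 ||
      length(fit$coefficients) != ncol(Xobs)) {
    return(marginal())
  }
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  p <- ncol(Xobs)
  par <- c(fit$coefficients, fit$zeta)
  if (!is.null(V) && all(is.finite(V))) {
    par <- par + drop(t(chol(V + diag(1e-10, length(par)))) %*%
                        stats::rnorm(length(par)))
  }
  beta <- par[seq_len(p)]; zeta <- sort(par[p + seq_len(K - 1)])
  eta <- drop(as.matrix(Xnew) %*% beta)
  cum <- stats::plogis(outer(-eta, zeta, `+`))
  pr <- cbind(cum, 1) - cbind(0, cum)
  pr[pr < 0] <- 0
  apply(pr, 1, function(w) sample.int(K, 1, prob = w))
}

# ---- pooling ---------------------------------------------------------------

#' Pool fitted model sets across imputations
#'
#' Coefficients are pooled as the across-imputation mean; the pooled
#' variance combines the mean within-imputation variance and the
#' between-imputation variance as `W + (1 + 1/m) B`. The simulation uses
#' pooled point estimates; per-imputation estimates and both variance
#' components are kept in the set's metadata.
#'
#' @param sets List of structurally identical `trs_model_set` objects.
#' @return A pooled `trs_model_set`.
#' @export
pool_models <- function(sets) {
  m <- length(sets)
  if (m < 1) stop("nothing to pool", call. = FALSE)
  if (m == 1) return(sets[[1]])
  pool_vec <- function(mats, ses) {
    est <- do.call(rbind, mats)
    qbar <- colMeans(est)
    between <- apply(est, 2, stats::var)
    within <- if (!is.null(ses[[1]])) colMeans(do.call(rbind, ses)^2)
    total <- if (!is.null(within)) within + (1 + 1 / m) * between
    list(coef = qbar, between = between, within = within,
         se = if (!is.null(total)) sqrt(total))
  }
  same <- function(f) {
    vals <- lapply(sets, f)
    if (!all(vapply(vals[-1], identical, logical(1), vals[[1]]))) {
      stop("model sets are structurally mismatched and cannot be pooled",
           call. = FALSE)
    }
    vals[[1]]
  }
  meta <- list(m = m, pooling = list())
  pool_lp <- function(get, name) {
    same(function(s) get(s)$spec)
    pl <- pool_vec(lapply(sets, function(s) get(s)$coef),
                   lapply(sets, function(s) get(s)$se))
    meta$pooling[[name]] <<- pl[c("between", "within")]
    x <- get(sets[[1]])
    lp_model(x$spec, pl$coef, se = pl$se, family = x$family, n = x$n)
  }
  dp <- pool_lp(function(s) s$death_pca, "death_pca")
  do <- pool_lp(function(s) s$death_other, "death_other")
  dest <- lapply(stats::setNames(nm = names(sets[[1]]$destination)),
                 function(lab) {
    same(function(s) s$destination[[lab]]$destinations)
    x <- sets[[1]]$destination[[lab]]
    if (!length(x$destinations)) return(x)
    pl <- pool_vec(lapply(sets, function(s) {
      as.vector(s$destination[[lab]]$coef)
    }), lapply(sets, function(s) {
      se <- s$destination[[lab]]$se
      if (is.null(se)) NULL else as.vector(se)
    }))
    meta$pooling[[paste0("destination_", lab)]] <<-
      pl[c("between", "within")]
    multinom_model(lab, x$destinations, x$spec,
                   matrix(pl$coef, nrow = length(x$spec)),
                   se = if (!is.null(pl$se)) {
                     matrix(pl$se, nrow = length(x$spec))
                   }, n = x$n)
  })
  risk <- lapply(stats::setNames(nm = names(sets[[1]]$risk_entry)),
                 function(lab) {
    x <- sets[[1]]$risk_entry[[lab]]
    same(function(s) s$risk_entry[[lab]]$spec)
    pz <- pool_vec(lapply(sets, function(s) s$risk_entry[[lab]]$zeta),
                   lapply(sets, function(s) s$risk_entry[[lab]]$se_zeta))
    pc <- if (length(x$coef)) {
      pool_vec(lapply(sets, function(s) s$risk_entry[[lab]]$coef),
               lapply(sets, function(s) s$risk_entry[[lab]]$se))
    }
    meta$pooling[[paste0("risk_entry_", lab)]] <<-
      list(between = c(pz$between, pc$between))
    ordinal_model(lab, x$K, pz$coef, x$spec,
                  if (length(x$coef)) pc$coef else numeric(0),
                  se = pc$se, se_zeta = pz$se, n = x$n)
  })
  cci <- lapply(stats::setNames(nm = names(sets[[1]]$cci)), function(lab) {
    list(logit = pool_lp(function(s) s$cci[[lab]]$logit,
                         paste0("cci_logit_", lab)),
         rate = pool_lp(function(s) s$cci[[lab]]$rate,
                        paste0("cci_rate_", lab)))
  })
  model_set(dp, do, dest, risk, cci,
            as_ww_thresholds = sets[[1]]$as_ww_thresholds, meta = meta)
}

#' Fit with multiple imputation and pool
#'
#' Convenience pipeline: impute the registry `m` times with
#' [mice_impute()], expand and fit each completed registry with
#' [fit_model_set()], and pool with [pool_models()].
#'
#' @param registry A `trs_registry`.
#' @param graph A `trs_graph`.
#' @param m,iterations,seed Passed to [mice_impute()].
#' @param specs,as_ww_thresholds Passed to [fit_model_set()].
#' @param horizon_steps Person-period horizon.
#' @return A pooled `trs_model_set`.
#' @export
fit_with_imputation <- function(registry, graph = build_default_graph(),
                                m = 5L, iterations = 10L, seed = 1L,
                                specs = default_covariate_specs(),
                                as_ww_thresholds =
                                  default_as_ww_thresholds(),
                                horizon_steps = 326L) {
  imps <- mice_impute(registry, graph, m = m, iterations = iterations,
                      seed = seed, horizon_steps = horizon_steps)
  sets <- lapply(imps, function(reg) {
    fit_model_set(expand_to_steps(reg, graph,
                                  horizon_steps = horizon_steps),
                  graph, specs, as_ww_thresholds)
  })
  pool_models(sets)
}
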