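# State space: treatment states with ordinal risk categories, two absorbing
# death states, and the irreversible transition graph that every other module
# (generation, estimation, simulation, validation) is checked against.

#' Transient and absorbing state labels
#'
#' The default disease model distinguishes seven transient treatment states --
#' active surveillance (`AS`), watchful waiting (`WW`), radical prostatectomy
#' (`RP`), radiotherapy (`RT`), adjuvant/salvage radiotherapy after RP
#' (`RTADJ`), antiandrogen monotherapy (`AA`) and GnRH agonists (`GNRH`) --
#' and two absorbing states, death from prostate cancer (`PCA_DEATH`) and
#' death from other causes (`OTHER_DEATH`).
#'
#' @return Character vector of labels.
#' @export
transient_labels <- function() {
  c("AS", "WW", "RP", "RT", "RTADJ", "AA", "GNRH")
}

#' @rdname transient_labels
#' @export
absorbing_labels <- function() {
  c("PCA_DEATH", "OTHER_DEATH")
}

#' @rdname transient_labels
#' @export
all_labels <- function() {
  c(transient_labels(), absorbing_labels())
}

# integer codes shared with the C++ engine (AS=1 ... OTHER_DEATH=9)
label_code <- function(label) {
  code <- match(label, all_labels())
  if (anyNA(code)) {
    stop("unknown state label(s): ",
         paste(unique(label[is.na(code)]), collapse = ", "),
         call. = FALSE)
  }
  code
}

code_label <- function(code) all_labels()[code]

#' Number of risk categories per treatment state
#'
#' Each transient state carries an ordinal treatment-specific risk category
#' with state-dependent range: 3 levels for AS, 6 for WW and RP, 8 for RT and
#' for the two androgen-deprivation states (AA, GNRH). Adjuvant/salvage
#' radiotherapy keeps the RP category of the man entering it, so its category
#' space coincides with RP's (6 levels). Absorbing states carry no category.
#'
#' @param label Optional state label; when omitted the full named vector is
#'   returned.
#' @return Named integer vector, or a single integer when `label` is given.
#' @export
risk_category_counts <- function(label = NULL) {
  k <- c(AS = 3L, WW = 6L, RP = 6L, RT = 8L, RTADJ = 6L, AA = 8L, GNRH = 8L)
  if (is.null(label)) return(k)
  if (!label %in% names(k)) {
    stop("no risk categories defined for state '", label, "'", call. = FALSE)
  }
  k[[label]]
}

#' Construct a state identifier
#'
#' @param label State label (see [transient_labels()]).
#' @param risk_category Ordinal risk category, required for transient states
#'   and disallowed for absorbing states.
#' @return An object of class `trs_state`.
#' @examples
#' state_id("RP", 3)
#' state_id("PCA_DEATH")
#' @export
state_id <- function(label, risk_category = NULL) {
  label <- match.arg(label, all_labels())
  absorbing <- label %in% absorbing_labels()
  if (absorbing) {
    if (!is.null(risk_category)) {
      stop("absorbing state '", label, "' carries no risk category",
           call. = FALSE)
    }
    risk_category <- NA_integer_
  } else {
    if (is.null(risk_category)) {
      stop("transient state '", label, "' requires a risk category",
           call. = FALSE)
    }
    risk_category <- as.integer(risk_category)
    k <- risk_category_counts(label)
    if (is.na(risk_category) || risk_category < 1L || risk_category > k) {
      stop("risk category for '", label, "' must be in 1..", k, call. = FALSE)
    }
  }
  structure(
    list(kind = if (absorbing) "ABSORBING" else "TRANSIENT",
         label = label, risk_category = risk_category),
    class = "trs_state")
}

#' @export
print.trs_state <- function(x, ...) {
  if (x$kind == "ABSORBING") {
    cat("<state ", x$label, " (absorbing)>\n", sep = "")
  } else {
    cat("<state ", x$label, "_", x$risk_category, ">\n", sep = "")
  }
  invisible(x)
}

#' Build the default treatment-transition graph
#'
#' The default graph is irreversible and acyclic. Men enter in one of the six
#' primary management strategies (AS, WW, RP, RT, AA, GNRH); the allowed
#' treatment changes are AS to RP, RT or WW; RP to RTADJ, AA or GNRH; RT,
#' RTADJ and WW to AA or GNRH; and AA to GNRH. Every transient state can in
#' addition move to either absorbing death state. `RTADJ` is reachable only
#' after RP; direct AS entry into androgen deprivation is not part of the
#' default graph (it must pass through WW), but the graph is a plain data
#' structure and alternative edge sets can be supplied to
#' [transition_graph()].
#'
#' @return An object of class `trs_graph` with elements `nodes`, `edges`
#'   (two-column character matrix), `entry_labels` and `risk_category_counts`.
#' @examples
#' g <- build_default_graph()
#' allowed_destinations(state_id("AS", 1), g)
#' @export
build_default_graph <- function() {
  treatment_edges <- rbind(
    c("AS", "RP"), c("AS", "RT"), c("AS", "WW"),
    c("RP", "RTADJ"), c("RP", "AA"), c("RP", "GNRH"),
    c("RT", "AA"), c("RT", "GNRH"),
    c("RTADJ", "AA"), c("RTADJ", "GNRH"),
    c("WW", "AA"), c("WW", "GNRH"),
    c("AA", "GNRH"))
  transition_graph(
    treatment_edges = treatment_edges,
    entry_labels = c("AS", "WW", "RP", "RT", "AA", "GNRH"))
}

#' Construct and validate a transition graph
#'
#' @param treatment_edges Two-column character matrix of directed edges
#'   between transient states, in the order used for destination draws.
#' @param entry_labels Labels in which individuals may start.
#' @param risk_counts Named integer vector of per-state category counts;
#'   defaults to [risk_category_counts()].
#' @return A `trs_graph` object. Edges to both absorbing states are added for
#'   every transient node automatically.
#' @export
transition_graph <- function(treatment_edges, entry_labels,
                             risk_counts = risk_category_counts()) {
  stopifnot(is.matrix(treatment_edges), ncol(treatment_edges) == 2)
  nodes <- transient_labels()
  bad <- setdiff(unique(c(treatment_edges)), nodes)
  if (length(bad)) {
    stop("treatment edges may only join transient states; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(entry_labels %in% nodes)) {
    stop("entry labels must be transient states", call. = FALSE)
  }
  death_edges <- cbind(rep(nodes, each = 2), rep(absorbing_labels(), 7))
  edges <- rbind(treatment_edges, death_edges)
  dimnames(edges) <- list(NULL, c("from", "to"))
  g <- structure(
    list(nodes = c(nodes, absorbing_labels()),
         edges = edges,
         treatment_edges = treatment_edges,
         entry_labels = entry_labels,
         risk_category_counts = risk_counts),
    class = "trs_graph")
  check_graph(g)
  g
}

# acyclicity by Kahn topological sort over treatment edges; reachability from
# the entry set; absorbing out-degree is zero by construction
check_graph <- function(g) {
  te <- g$treatment_edges
  nodes <- transient_labels()
  indeg <- table(factor(te[, 2], levels = nodes))
  queue <- nodes[indeg == 0]
  seen <- character(0)
  left <- te
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- c(seen, v)
    out <- left[, 1] == v
    heads <- left[out, 2]
    left <- left[!out, , drop = FALSE]
    for (h in unique(heads)) {
      if (!any(left[, 2] == h)) queue <- c(queue, h)
    }
  }
  if (nrow(left) > 0) {
    stop("transition graph has a cycle (transitions must be irreversible)",
         call. = FALSE)
  }
  reach <- g$entry_labels
  repeat {
    nxt <- unique(c(reach, te[te[, 1] %in% reach, 2]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  unreachable <- setdiff(unique(c(te)), reach)
  if (length(unreachable)) {
    stop("transient state(s) unreachable from any entry label: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  invisible(g)
}

#' @export
print.trs_graph <- function(x, ...) {
  cat("<transition graph: ", length(x$nodes), " states, ",
      nrow(x$edges), " edges, entry {",
      paste(x$entry_labels, collapse = ", "), "}>\n", sep = "")
  invisible(x)
}

#' Has the graph a given directed edge?
#'
#' @param graph A `trs_graph`.
#' @param from,to State labels.
#' @return Logical scalar.
#' @export
has_edge <- function(graph, from, to) {
  any(graph$edges[, 1] == from & graph$edges[, 2] == to)
}

#' Allowed destinations of a state
#'
#' Treatment destinations first, in the fixed order in which they appear in
#' the graph's edge list (this order is also the order of the cumulative
#' probability comparison in destination draws, so random draws are
#' reproducible), followed by `PCA_DEATH` and `OTHER_DEATH`. Absorbing states
#' have no destinations.
#'
#' @param state A `trs_state` or a state label.
#' @param graph A `trs_graph`.
#' @return Character vector of destination labels (possibly empty).
#' @export
allowed_destinations <- function(state, graph) {
  label <- if (inherits(state, "trs_state")) state$label else state
  if (!label %in% graph$nodes) {
    stop("unknown state label '", label, "'", call. = FALSE)
  }
  if (label %in% absorbing_labels()) return(character(0))
  te <- graph$treatment_edges
  c(te[te[, 1] == label, 2], absorbing_labels())
}

#' Validate a state trajectory against a graph
#'
#' A trajectory is valid when every consecutive pair of states is either a
#' repeat of the same state or a directed edge of the graph, and no state
#' label recurs after having been left (irreversibility).
#'
#' @param traj Character vector of state labels in time order (risk-category
#'   changes within a state are not part of the label sequence).
#' @param graph A `trs_graph`.
#' @return A list with `valid` (logical) and `first_violation` (integer index
#'   of the first offending position, or `NA` when valid).
#' @examples
#' g <- build_default_graph()
#' validate_trajectory(c("AS", "AS", "RP", "RP", "GNRH"), g)
#' validate_trajectory(c("RP", "AS"), g)$first_violation
#' @export
validate_trajectory <- function(traj, graph) {
  if (length(traj) == 0) {
    stop("trajectory must contain at least one state", call. = FALSE)
  }
  if (!all(traj %in% graph$nodes)) {
    stop("unknown state label(s) in trajectory: ",
         paste(setdiff(traj, graph$nodes), collapse = ", "), call. = FALSE)
  }
  left <- character(0)
  for (i in seq_along(traj)) {
    if (i == 1) next
    a <- traj[i - 1]; b <- traj[i]
    if (a == b) next
    if (!has_edge(graph, a, b) || b %in% left) {
      return(list(valid = FALSE, first_violation = i))
    }
    left <- c(left, a)
  }
  list(valid = TRUE, first_violation = NA_integer_)
}

#' Deterministic switch rule from active surveillance to watchful waiting
#'
#' The change from AS to WW is not a dated registry event: it reflects the
#' clinical decision that curative intent is no longer warranted. It is
#' handled by a deterministic age/comorbidity threshold rule rather than a
#' fitted transition model: a man on AS switches to WW in the first time step
#' at the end of which his attained age reaches the threshold for his current
#' Charlson comorbidity level. The default thresholds are 80/75/70/65 years
#' for CCI 0/1/2/3+. The same rule is used by the synthetic-registry
#' generator and by the simulator, keeping the two congruent.
#'
#' @param age Attained age in years.
#' @param cci Charlson comorbidity index level, 0..3 (3 = 3+).
#' @param thresholds Named or positional numeric vector of length 4 giving
#'   the age threshold for CCI 0, 1, 2, 3+; must be non-increasing in CCI.
#' @return Logical: does the rule fire?
#' @examples
#' as_ww_switch(81, 0)
#' as_ww_switch(64, 3)
#' @export
as_ww_switch <- function(age, cci, thresholds = default_as_ww_thresholds()) {
  if (length(thresholds) != 4 || anyNA(thresholds)) {
    stop("thresholds must give an age for each CCI level 0..3", call. = FALSE)
  }
  if (any(diff(thresholds) > 0)) {
    stop("thresholds must be non-increasing in CCI", call. = FALSE)
  }
  if (any(cci < 0 | cci > 3)) stop("cci must be in 0..3", call. = FALSE)
  age >= thresholds[cci + 1]
}

#' @rdname as_ww_switch
#' @export
default_as_ww_thresholds <- function() {
  c(`0` = 80, `1` = 75, `2` = 70, `3` = 65)
}

#' Serialize a transition graph to JSON
#'
#' @param graph A `trs_graph`.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
graph_to_json <- function(graph, path = NULL) {
  obj <- list(
    nodes = graph$nodes,
    edges = apply(graph$edges, 1, function(e) list(from = e[1], to = e[2])),
    entry_labels = graph$entry_labels,
    risk_category_counts = as.list(graph$risk_category_counts))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a transition graph from JSON
#'
#' @param path File path or JSON string produced by [graph_to_json()].
#' @return A `trs_graph`.
#' @export
graph_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  te <- as.matrix(obj$edges[obj$edges$to %in% transient_labels(),
                            c("from", "to")])
  rc <- unlist(obj$risk_category_counts)
  transition_graph(te, obj$entry_labels,
                   risk_counts = stats::setNames(as.integer(rc), names(rc)))
}
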