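# Assignment engine: evaluate each property against a proteome's match
# table, producing YES/PARTIAL/NO with per-step detail, and format the
# three report forms (summary, step-level long form, protein-centric).
#
# Semantics: a step matches if any of its evidence lines matches; an
# InterPro evidence matches when at least one protein carries the
# accession, a property evidence when the referenced property already
# evaluated to YES (or PARTIAL, under `partial_counts`).  Only required
# steps decide the state: all required matched => YES; more than
# `threshold` matched => PARTIAL; otherwise NO.  Optional steps are
# reported but never change the state.

#' Evaluate one step
#'
#' @param step A [gp_step()].
#' @param table A [match_table()].
#' @param resolved Named list of prior results, one per GENPROP evidence
#'   of this step (evaluation order is the caller's responsibility;
#'   [evaluate_all()] guarantees it).
#' @param partial_counts When `TRUE`, PARTIAL sub-properties satisfy
#'   property evidence; the default requires YES.
#' @param signature_fallback When `TRUE`, an InterPro evidence with no
#'   integrated match may be satisfied by one of its member-database
#'   signatures at the signature level.
#' @param by_acc Optional precomputed inversion of the match table
#'   (internal use by [evaluate_all()]).
#' @return Object of class `gp_step_result`: `number`, `matched`, and
#'   `matched_by` (named list, evidence accession to matching protein
#'   ids; property evidence satisfied by a sub-property contributes an
#'   entry with zero protein ids).
#' @export
evaluate_step <- function(step, table, resolved = list(),
                          partial_counts = FALSE,
                          signature_fallback = FALSE,
                          by_acc = NULL) {
  stopifnot(inherits(step, "gp_step"))
  if (is.null(by_acc)) by_acc <- matches_by_accession(table)
  matched_by <- list()
  for (e in step$evidences) {
    if (e$kind == "INTERPRO") {
      prot <- unique(by_acc[[e$accession]])
      if (is.null(prot) && signature_fallback &&
          length(e$raw_signatures)) {
        sig_hits <- vapply(table$signature_matches, function(s)
          any(e$raw_signatures %in% s), logical(1))
        if (any(sig_hits)) prot <- names(table$signature_matches)[sig_hits]
      }
      if (length(prot)) matched_by[[e$accession]] <- sort(prot)
    } else {
      sub <- resolved[[e$accession]]
      if (is.null(sub))
        stop("unresolved property evidence: ", e$accession, call. = FALSE)
      ok <- sub$state == "YES" ||
        (partial_counts && sub$state == "PARTIAL")
      if (ok) matched_by[[e$accession]] <- character()
    }
  }
  structure(
    list(number = step$number, matched = length(matched_by) > 0L,
         matched_by = matched_by),
    class = "gp_step_result"
  )
}

#' Evaluate one property
#'
#' @param property A [genome_property()].
#' @param table A [match_table()].
#' @inheritParams evaluate_step
#' @return Object of class `gp_result`: `accession`, `state` (one of
#'   [gp_states()]), `step_results` (ordered list of step results),
#'   `required_total` and `required_matched`. A property with zero steps
#'   (or zero required steps) is NO, with a warning in the zero-step case.
#' @export
evaluate_property <- function(property, table, resolved = list(),
                              partial_counts = FALSE,
                              signature_fallback = FALSE,
                              by_acc = NULL) {
  stopifnot(inherits(property, "genome_property"))
  if (is.null(by_acc)) by_acc <- matches_by_accession(table)
  if (!length(property$steps))
    warning(property$accession, ": property has no steps; state is NO",
            call. = FALSE)
  step_results <- lapply(property$steps, evaluate_step, table = table,
                         resolved = resolved,
                         partial_counts = partial_counts,
                         signature_fallback = signature_fallback,
                         by_acc = by_acc)
  required <- vapply(property$steps, `[[`, logical(1), "required")
  matched <- vapply(step_results, `[[`, logical(1), "matched")
  required_total <- sum(required)
  required_matched <- sum(required & matched)
  state <- if (required_total > 0L && required_matched == required_total) {
    "YES"
  } else if (required_matched > property$threshold) {
    "PARTIAL"
  } else {
    "NO"
  }
  structure(
    list(accession = property$accession, state = state,
         step_results = step_results,
         required_total = required_total,
         required_matched = required_matched),
    class = "gp_result"
  )
}

#' @export
print.gp_result <- function(x, ...) {
  cat(sprintf("<gp_result> %s: %s (%d/%d required steps matched)\n",
              x$accession, x$state, x$required_matched, x$required_total))
  invisible(x)
}

#' Evaluate every property of a registry against one proteome
#'
#' Properties are evaluated in topological order of their
#' property-evidence dependencies, so metapaths and categories always see
#' the results of the properties they cite. Evaluation is deterministic;
#' there is no randomness anywhere in assignment.
#'
#' @param registry A [gp_registry()]; its evidence graph must be acyclic
#'   and fully resolved (checked; a cycle aborts with its path).
#' @param table A [match_table()].
#' @inheritParams evaluate_step
#' @return Named list of [evaluate_property()] results, in registry
#'   order, one per property.
#' @export
evaluate_all <- function(registry, table, partial_counts = FALSE,
                         signature_fallback = FALSE) {
  stopifnot(inherits(registry, "gp_registry"),
            inherits(table, "gp_match_table"))
  audit <- validate_graph(registry)
  if (length(audit$cycles))
    stop("evidence graph has a cycle: ",
         paste(audit$cycles[[1]], collapse = " -> "), call. = FALSE)
  if (nrow(audit$unresolved))
    stop("unresolved property evidence: ",
         paste(unique(audit$unresolved$to), collapse = ", "),
         call. = FALSE)
  accs <- names(registry$properties)
  g <- igraph::graph_from_data_frame(registry$edges, directed = TRUE,
                                     vertices = accs)
  # edges point citing -> cited; evaluate cited first
  order <- rev(names(igraph::topo_sort(g, mode = "out")))
  by_acc <- matches_by_accession(table)
  resolved <- list()
  for (acc in order)
    resolved[[acc]] <- evaluate_property(
      registry$properties[[acc]], table, resolved,
      partial_counts = partial_counts,
      signature_fallback = signature_fallback, by_acc = by_acc)
  resolved[accs]
}

report_accessions <- function(results, registry, include_categories) {
  accs <- sort(names(results))
  if (!include_categories)
    accs <- accs[vapply(accs, function(a)
      registry$properties[[a]]$type != "CATEGORY", logical(1))]
  accs
}

#' Assignment reports
#'
#' Three tabular report forms over a set of results: `summary_report`
#' (one row per property: accession, name, state), `long_report` (the
#' summary rows interleaved with one row per step carrying its matched
#' flag) and `protein_report` (protein-centric: one row per protein
#' matching an evidence of a step). All are sorted by property accession,
#' then step number. State strings are exactly `"YES"`, `"PARTIAL"`,
#' `"NO"`. Organizational CATEGORY properties are excluded from the
#' summary and long forms unless `include_categories = TRUE`.
#'
#' @param results Result list from [evaluate_all()].
#' @param registry The registry the results were computed from.
#' @param include_categories Include CATEGORY properties.
#' @return A data frame; see Details for the columns of each form.
#' @details `summary_report`: `accession`, `name`, `state`.
#'   `long_report`: adds `line` (`"PROPERTY"` or `"STEP"`),
#'   `step_number`, `step_id`, `required`, `matched` (NA on property
#'   rows). `protein_report`: `protein`, `property`, `step_number`,
#'   `evidence`.
#' @export
summary_report <- function(results, registry, include_categories = FALSE) {
  stopifnot(length(results) > 0L)
  accs <- report_accessions(results, registry, include_categories)
  data.frame(
    accession = accs,
    name = vapply(accs, function(a) registry$properties[[a]]$name,
                  character(1)),
    state = vapply(accs, function(a) results[[a]]$state, character(1)),
    row.names = NULL
  )
}

#' @rdname summary_report
#' @export
long_report <- function(results, registry, include_categories = FALSE) {
  stopifnot(length(results) > 0L)
  accs <- report_accessions(results, registry, include_categories)
  rows <- lapply(accs, function(a) {
    prop <- registry$properties[[a]]
    res <- results[[a]]
    head_row <- data.frame(
      accession = a, line = "PROPERTY", name = prop$name,
      state = res$state, step_number = NA_integer_,
      step_id = NA_character_, required = NA, matched = NA)
    if (!length(prop$steps)) return(head_row)
    step_rows <- do.call(rbind, lapply(seq_along(prop$steps), function(i) {
      s <- prop$steps[[i]]
      data.frame(
        accession = a, line = "STEP", name = prop$name,
        state = NA_character_, step_number = s$number,
        step_id = s$id, required = s$required,
        matched = res$step_results[[i]]$matched)
    }))
    step_rows <- step_rows[order(step_rows$step_number), ]
    rbind(head_row, step_rows)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname summary_report
#' @export
protein_report <- function(results, registry) {
  stopifnot(length(results) > 0L)
  rows <- list()
  for (a in sort(names(results))) {
    for (sr in results[[a]]$step_results) {
      for (ev in names(sr$matched_by)) {
        prot <- sr$matched_by[[ev]]
        if (length(prot))
          rows[[length(rows) + 1L]] <- data.frame(
            protein = prot, property = a, step_number = sr$number,
            evidence = ev)
      }
    }
  }
  if (!length(rows))
    return(data.frame(protein = character(), property = character(),
                      step_number = integer(), evidence = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$property, out$step_number, out$protein,
                   out$evidence), ]
  rownames(out) <- NULL
  out
}
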