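# Release-time quality control: hierarchy connectivity, evidence validity
# against an InterPro accession universe, FASTA sidecar presence,
# per-type release statistics, and the curation heuristic for selecting
# one InterPro evidence among candidates.

#' Check hierarchy connectivity
#'
#' Every property must be reachable from the organizational hierarchy so
#' the browse view has a path to it: a non-category property is connected
#' iff some CATEGORY or METAPATH cites it as evidence; a category is
#' connected iff another category cites it or it is a designated root.
#'
#' @param registry An acyclic [gp_registry()].
#' @param roots Accessions of the root categories (configuration, not
#'   hard-coded).
#' @return Character vector of orphan accessions (sorted; empty when the
#'   hierarchy is fully connected).
#' @export
check_connectivity <- function(registry, roots = character()) {
  stopifnot(inherits(registry, "gp_registry"))
  props <- registry$properties
  types <- vapply(props, `[[`, character(1), "type")
  edges <- registry$edges
  from_type <- types[edges$from]
  orphans <- character()
  for (acc in names(props)) {
    citers <- from_type[edges$to == acc]
    ok <- if (types[[acc]] == "CATEGORY")
      acc %in% roots || any(citers == "CATEGORY")
    else
      any(citers %in% c("CATEGORY", "METAPATH"))
    if (!ok) orphans <- c(orphans, acc)
  }
  sort(orphans)
}

#' Check evidence validity against an accession universe
#'
#' Every InterPro accession used as step evidence must exist in the
#' accession universe of the InterProScan release the data are built
#' against. Property (GENPROP) evidence is resolved within the registry
#' and is never checked against the universe.
#'
#' @param registry A [gp_registry()].
#' @param valid_accessions Character vector: the release's InterPro
#'   accession universe.
#' @return Data frame with columns `property`, `accession`, one row per
#'   invalid evidence use (zero rows when all are valid).
#' @export
check_evidence_validity <- function(registry, valid_accessions) {
  rows <- lapply(names(registry$properties), function(acc) {
    ev <- property_evidence(registry$properties[[acc]], kind = "INTERPRO")
    bad <- setdiff(ev, valid_accessions)
    if (length(bad)) data.frame(property = acc, accession = sort(bad))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(property = character(), accession = character())
  rownames(out) <- NULL
  out
}

#' Check FASTA sidecar presence
#'
#' A property with at least one InterPro-evidenced step needs a FASTA
#' sidecar holding an example sequence for each such step. CATEGORY
#' properties (property evidence only, no sequences to exemplify) are
#' exempt.
#'
#' @param registry A [gp_registry()].
#' @param sidecars Named list of [load_fasta()] sidecars, keyed by
#'   property accession.
#' @return Data frame with columns `property`, `missing_steps`
#'   (comma-separated step numbers; all InterPro steps when the sidecar
#'   is absent entirely).
#' @export
check_fasta_presence <- function(registry, sidecars = list()) {
  rows <- list()
  for (acc in names(registry$properties)) {
    prop <- registry$properties[[acc]]
    if (prop$type == "CATEGORY") next
    ipr_steps <- vapply(prop$steps, function(s)
      if (any(vapply(s$evidences, `[[`, character(1), "kind") == "INTERPRO"))
        s$number else NA_integer_, integer(1))
    ipr_steps <- ipr_steps[!is.na(ipr_steps)]
    if (!length(ipr_steps)) next
    covered <- if (acc %in% names(sidecars))
      unique(sidecars[[acc]]$step_map) else integer()
    missing <- sort(setdiff(ipr_steps, covered))
    if (length(missing))
      rows[[length(rows) + 1L]] <- data.frame(
        property = acc,
        missing_steps = paste(missing, collapse = ","))
  }
  if (!length(rows))
    return(data.frame(property = character(), missing_steps = character()))
  out <- do.call(rbind, rows)
  out[order(out$property), , drop = FALSE]
}

#' Release statistics
#'
#' Counts of properties added between two releases, broken down by type,
#' as reported in release notes.
#'
#' @param old_registry,new_registry Registries for the two releases.
#' @return Named integer vector over [gp_types()] of added-property
#'   counts, with a final `TOTAL` element.
#' @export
release_stats <- function(old_registry, new_registry) {
  added <- setdiff(names(new_registry$properties),
                   names(old_registry$properties))
  types <- vapply(new_registry$properties[added], `[[`, character(1), "type")
  counts <- vapply(gp_types(), function(tp) sum(types == tp), integer(1))
  c(counts, TOTAL = length(added))
}

#' Select evidence among candidate InterPro entries
#'
#' Curation heuristic for semi-automatically generated properties, where
#' an example protein matches several InterPro entries: prefer entries of
#' type family over domain or homologous superfamily (families tend to be
#' more specific), then take the most specific entry, i.e. the one lowest
#' (deepest) in its InterPro hierarchy. Remaining ties are broken by
#' greater taxonomic breadth (candidates with no recorded breadth rank
#' last), then by lexicographic accession so the choice is deterministic
#' and independent of candidate order.
#'
#' @param candidates Data frame with columns `accession`, `entry_type`
#'   (one of `FAMILY`, `DOMAIN`, `HOMOLOGOUS_SUPERFAMILY`, `OTHER`),
#'   `hierarchy_depth` (0 = hierarchy root) and optionally
#'   `taxonomic_breadth`.
#' @return The chosen accession (length-1 character).
#' @export
select_evidence <- function(candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L,
            all(c("accession", "entry_type", "hierarchy_depth") %in%
                  names(candidates)))
  stopifnot(all(candidates$hierarchy_depth >= 0L))
  pool <- candidates
  if (any(pool$entry_type == "FAMILY"))
    pool <- pool[pool$entry_type == "FAMILY", , drop = FALSE]
  pool <- pool[pool$hierarchy_depth == max(pool$hierarchy_depth), ,
               drop = FALSE]
  breadth <- if ("taxonomic_breadth" %in% names(pool))
    ifelse(is.na(pool$taxonomic_breadth), -Inf, pool$taxonomic_breadth)
  else rep(-Inf, nrow(pool))
  pool <- pool[breadth == max(breadth), , drop = FALSE]
  sort(pool$accession)[1L]
}

#' Full release QC report
#'
#' Aggregates the individual checks into one report; a release is ready
#' iff the report is empty.
#'
#' @param registry A [gp_registry()].
#' @param valid_accessions InterPro accession universe for
#'   [check_evidence_validity()]; `NULL` skips the check.
#' @param sidecars Sidecar list for [check_fasta_presence()].
#' @param roots Root categories for [check_connectivity()].
#' @return Object of class `gp_qc_report`: list with `orphans`,
#'   `invalid_evidence`, `missing_fasta`, `warnings` (free text, e.g.
#'   properties with no required step, or graph problems) and logical
#'   `release_ready`.
#' @export
qc_report <- function(registry, valid_accessions = NULL,
                      sidecars = list(), roots = character()) {
  audit <- validate_graph(registry)
  warnings <- character()
  if (length(audit$cycles))
    warnings <- c(warnings, vapply(audit$cycles, function(cy)
      paste("evidence cycle:", paste(cy, collapse = " -> ")), character(1)))
  if (nrow(audit$unresolved))
    warnings <- c(warnings, paste("unresolved property evidence:",
                                  unique(audit$unresolved$to)))
  for (acc in names(registry$properties)) {
    prop <- registry$properties[[acc]]
    n_req <- sum(vapply(prop$steps, `[[`, logical(1), "required"))
    if (prop$type != "CATEGORY" && n_req == 0L)
      warnings <- c(warnings,
                    paste0(acc, ": no required step; always NO"))
    if (n_req > 0L && prop$threshold >= n_req)
      warnings <- c(warnings,
                    paste0(acc, ": threshold ", prop$threshold,
                           " not below required step count ", n_req))
  }
  orphans <- check_connectivity(registry, roots)
  invalid <- if (is.null(valid_accessions))
    data.frame(property = character(), accession = character())
  else check_evidence_validity(registry, valid_accessions)
  missing_fasta <- check_fasta_presence(registry, sidecars)
  structure(
    list(orphans = orphans, invalid_evidence = invalid,
         missing_fasta = missing_fasta, warnings = warnings,
         release_ready = !length(orphans) && !nrow(invalid) &&
           !nrow(missing_fasta) && !length(warnings)),
    class = "gp_qc_report"
  )
}

#' @export
print.gp_qc_report <- function(x, ...) {
  cat("<gp_qc_report>",
      if (x$release_ready) "release-ready\n" else "NOT release-ready\n")
  if (length(x$orphans))
    cat("  orphans:", paste(x$orphans, collapse = ", "), "\n")
  if (nrow(x$invalid_evidence))
    cat("  invalid evidence:", nrow(x$invalid_evidence), "pair(s)\n")
  if (nrow(x$missing_fasta))
    cat("  missing FASTA coverage:", nrow(x$missing_fasta), "propertie(s)\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
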