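# Domain model: evidence lines, steps, genome properties, and the registry
# that holds a release worth of properties together with the directed graph
# of property-to-property evidence references.

#' Admissible genome property types
#'
#' Six types exist: five functional classes (pathway, metapath, system,
#' guild, complex) and the purely organizational category type used to
#' arrange properties into a browsable hierarchy.
#'
#' @return Character vector of the six type tokens.
#' @export
gp_types <- function() {
  c("PATHWAY", "METAPATH", "SYSTEM", "GUILD", "COMPLEX", "CATEGORY")
}

#' Result states and their numeric encoding
#'
#' Assignment results take one of three states. The fixed numeric encoding
#' (NO = 0, PARTIAL = 1, YES = 2) is what profile matrices use for distance
#' and ordination work; it is a strict monotone bijection so the state
#' ordering NO < PARTIAL < YES is preserved.
#'
#' @return `gp_states()` returns the three state strings in increasing
#'   order; `gp_state_codes()` returns the named integer encoding.
#' @export
gp_states <- function() c("NO", "PARTIAL", "YES")

#' @rdname gp_states
#' @export
gp_state_codes <- function() c(NO = 0L, PARTIAL = 1L, YES = 2L)

is_interpro_acc <- function(x) grepl("^IPR[0-9]{6}$", x)
is_genprop_acc  <- function(x) grepl("^GenProp[0-9]{4}$", x)

#' Construct an evidence line
#'
#' Evidence for a step is either an InterPro entry (accession `IPRnnnnnn`)
#' or another genome property (`GenPropnnnn`); the kind is derived from the
#' accession pattern. Member-database signature accessions seen alongside
#' the InterPro accession may be kept as informational `raw_signatures`.
#'
#' @param accession Evidence accession (`IPRnnnnnn` or `GenPropnnnn`).
#' @param raw_signatures Optional character vector of member-database
#'   signature identifiers (informational only).
#' @param strict When `TRUE` (default) the accession must match one of the
#'   two patterns exactly; `FALSE` admits legacy identifiers, classifying
#'   by prefix.
#' @return An object of class `gp_evidence` with fields `kind`
#'   (`"INTERPRO"` or `"GENPROP"`), `accession` and `raw_signatures`.
#' @export
gp_evidence <- function(accession, raw_signatures = character(), strict = TRUE) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  if (is_interpro_acc(accession)) {
    kind <- "INTERPRO"
  } else if (is_genprop_acc(accession)) {
    kind <- "GENPROP"
  } else if (!strict && grepl("^IPR", accession)) {
    kind <- "INTERPRO"
  } else if (!strict && grepl("^GenProp", accession)) {
    kind <- "GENPROP"
  } else {
    stop("malformed evidence accession: ", accession, call. = FALSE)
  }
  structure(
    list(kind = kind, accession = accession,
         raw_signatures = as.character(raw_signatures)),
    class = "gp_evidence"
  )
}

#' Construct a property step
#'
#' One functional component of a property (e.g. one enzyme of a pathway).
#' A step is satisfied by any one of its evidence lines, and is either
#' required (counts toward the assignment threshold) or optional
#' (reported but never decisive).
#'
#' @param number Positive integer ordinal, unique within the property.
#' @param id Short step label.
#' @param required Logical; `TRUE` for required steps.
#' @param evidences Non-empty list of [gp_evidence()] objects.
#' @param display_name Optional longer display text.
#' @param extra Named character vector of unrecognized flatfile annotations
#'   carried through for forward compatibility.
#' @return An object of class `gp_step`.
#' @export
gp_step <- function(number, id, required = TRUE, evidences = list(),
                    display_name = NULL, extra = character()) {
  number <- as.integer(number)
  stopifnot(length(number) == 1L, !is.na(number), number >= 1L,
            is.character(id), length(id) == 1L)
  if (length(evidences) == 0L)
    stop("step ", number, " has no evidence line", call. = FALSE)
  if (!all(vapply(evidences, inherits, logical(1), "gp_evidence")))
    stop("evidences must be gp_evidence objects", call. = FALSE)
  structure(
    list(number = number, id = id,
         display_name = display_name,
         required = isTRUE(required),
         evidences = evidences,
         extra = extra),
    class = "gp_step"
  )
}

#' Construct a genome property
#'
#' A genome property describes a higher-order functional attribute as an
#' ordered series of steps. The integer `threshold` governs assignment: a
#' proteome matching all required steps gets YES; more than `threshold` but
#' not all gets PARTIAL; at or below `threshold` gets NO.
#'
#' @param accession `GenPropnnnn` accession.
#' @param name One-line description.
#' @param type One of [gp_types()].
#' @param threshold Non-negative integer; number of matched required steps
#'   that must be exceeded for a PARTIAL call.
#' @param steps Ordered list of [gp_step()] objects (may be empty for a
#'   header-only record).
#' @param author,description Free-text metadata.
#' @param references Data frame with columns `number`, `pmid`, `title`,
#'   `authors`, `journal` (may be empty).
#' @param xrefs Data frame with columns `database`, `id` (may be empty).
#' @param public Logical from the status sidecar; defaults to `TRUE`.
#' @param extra Named character vector of unrecognized flatfile lines.
#' @param strict Passed through to accession validation.
#' @return An object of class `genome_property`.
#' @details A CATEGORY property may carry only property-type (GENPROP)
#'   evidence. If `threshold` is not below the number of required steps
#'   (and that number is positive), PARTIAL is unreachable; this is flagged
#'   with a warning, not an error, because curation may intend it.
#' @export
genome_property <- function(accession, name, type, threshold = 0L,
                            steps = list(), author = NULL,
                            description = NULL,
                            references = NULL, xrefs = NULL,
                            public = TRUE, extra = character(),
                            strict = TRUE) {
  stopifnot(is.character(accession), length(accession) == 1L)
  if (strict && !is_genprop_acc(accession))
    stop("malformed property accession: ", accession, call. = FALSE)
  type <- toupper(type)
  if (!type %in% gp_types())
    stop("unknown property type: ", type, call. = FALSE)
  threshold <- as.integer(threshold)
  stopifnot(length(threshold) == 1L, !is.na(threshold), threshold >= 0L)
  if (!all(vapply(steps, inherits, logical(1), "gp_step")))
    stop("steps must be gp_step objects", call. = FALSE)
  nums <- vapply(steps, `[[`, integer(1), "number")
  if (anyDuplicated(nums))
    stop(accession, ": duplicate step numbers", call. = FALSE)
  if (type == "CATEGORY") {
    kinds <- unlist(lapply(steps, function(s)
      vapply(s$evidences, `[[`, character(1), "kind")))
    if (any(kinds == "INTERPRO"))
      stop(accession, ": CATEGORY properties carry only property evidence",
           call. = FALSE)
  }
  n_req <- sum(vapply(steps, `[[`, logical(1), "required"))
  if (n_req > 0L && threshold >= n_req)
    warning(accession, ": threshold (", threshold,
            ") not below required step count (", n_req,
            "); PARTIAL is unreachable", call. = FALSE)
  if (is.null(references))
    references <- data.frame(number = integer(), pmid = character(),
                             title = character(), authors = character(),
                             journal = character())
  if (is.null(xrefs))
    xrefs <- data.frame(database = character(), id = character())
  structure(
    list(accession = accession, name = name, type = type,
         threshold = threshold, author = author,
         description = description, references = references,
         xrefs = xrefs, steps = steps, public = isTRUE(public),
         extra = extra),
    class = "genome_property"
  )
}

#' @export
print.genome_property <- function(x, ...) {
  n_req <- sum(vapply(x$steps, `[[`, logical(1), "required"))
  cat(sprintf("<genome_property> %s  %s\n  type %s, threshold %d, %d step(s) (%d required)\n",
              x$accession, x$name, x$type, x$threshold,
              length(x$steps), n_req))
  invisible(x)
}

# All evidence accessions of a property, optionally restricted by kind.
property_evidence <- function(property, kind = NULL) {
  ev <- unlist(lapply(property$steps, function(s)
    lapply(s$evidences, function(e)
      if (is.null(kind) || e$kind == kind) e$accession else NULL)))
  unique(as.character(ev))
}

#' Create an empty property registry
#'
#' A registry maps accessions to properties and maintains the directed
#' evidence graph: one edge per GENPROP evidence, from the citing property
#' to the property it cites. The graph must stay acyclic for assignment to
#' be well defined; see [validate_graph()].
#'
#' @return An object of class `gp_registry`.
#' @export
gp_registry <- function() {
  structure(
    list(properties = list(),
         edges = data.frame(from = character(), to = character())),
    class = "gp_registry"
  )
}

#' @export
print.gp_registry <- function(x, ...) {
  cat(sprintf("<gp_registry> %d properties, %d evidence edges\n",
              length(x$properties), nrow(x$edges)))
  invisible(x)
}

#' @export
length.gp_registry <- function(x) length(x$properties)

#' Register a property
#'
#' @param registry A [gp_registry()].
#' @param property A [genome_property()].
#' @return The updated registry, with the property retrievable by
#'   accession and one evidence-graph edge added per GENPROP evidence.
#' @export
register <- function(registry, property) {
  stopifnot(inherits(registry, "gp_registry"),
            inherits(property, "genome_property"))
  acc <- property$accession
  if (acc %in% names(registry$properties))
    stop("duplicate accession: ", acc, call. = FALSE)
  registry$properties[[acc]] <- property
  cited <- property_evidence(property, kind = "GENPROP")
  if (length(cited))
    registry$edges <- rbind(registry$edges,
                            data.frame(from = acc, to = cited))
  registry
}

#' Validate the evidence graph
#'
#' Checks that every GENPROP evidence resolves to a registered property and
#' that the evidence graph is acyclic (a requirement for safe recursive
#' evaluation). Unresolved references are reported separately from cycles.
#'
#' @param registry A [gp_registry()].
#' @return List with elements `cycles` (list of accession sequences, one
#'   per cycle; empty iff the graph of resolved edges is acyclic) and
#'   `unresolved` (data frame of `from`/`to` edges whose target is not
#'   registered).
#' @export
validate_graph <- function(registry) {
  stopifnot(inherits(registry, "gp_registry"))
  known <- names(registry$properties)
  edges <- registry$edges
  missing_to <- !(edges$to %in% known)
  unresolved <- edges[missing_to, , drop = FALSE]
  rownames(unresolved) <- NULL
  edges <- edges[!missing_to, , drop = FALSE]

  # Iterative DFS with colouring; each back edge yields one cycle path.
  adj <- split(edges$to, factor(edges$from, levels = known))
  colour <- stats::setNames(rep(0L, length(known)), known)  # 0 new, 1 open, 2 done
  cycles <- list()
  visit <- function(v, path) {
    colour[[v]] <<- 1L
    for (w in adj[[v]]) {
      if (colour[[w]] == 0L) {
        visit(w, c(path, w))
      } else if (colour[[w]] == 1L) {
        i <- match(w, path)
        cycles[[length(cycles) + 1L]] <<- path[i:length(path)]
      }
    }
    colour[[v]] <<- 2L
  }
  for (v in known) if (colour[[v]] == 0L) visit(v, v)
  list(cycles = cycles, unresolved = unresolved)
}

#' Search property names
#'
#' Case-insensitive substring search against the one-line property names,
#' as used by the hierarchical browse search.
#'
#' @param registry A [gp_registry()].
#' @param query Non-empty search string (fixed substring, not a regex).
#' @return Character vector of matching accessions, sorted.
#' @export
search_names <- function(registry, query) {
  stopifnot(inherits(registry, "gp_registry"),
            is.character(query), length(query) == 1L, nzchar(query))
  nm <- vapply(registry$properties, `[[`, character(1), "name")
  hits <- names(nm)[grepl(tolower(query), tolower(nm), fixed = TRUE)]
  sort(hits)
}

#' Numeric encoding of result states
#'
#' Maps result states to the fixed integer codes NO = 0, PARTIAL = 1,
#' YES = 2, and back.
#'
#' @param states Character vector (or matrix) of states.
#' @param codes Integer vector (or matrix) of codes in 0:2.
#' @return `encode_states` returns integers; `decode_states` returns state
#'   strings. Shape and dimnames are preserved.
#' @export
encode_states <- function(states) {
  codes <- gp_state_codes()
  bad <- !(states %in% names(codes))
  if (any(bad))
    stop("unknown state(s): ", paste(unique(states[bad]), collapse = ", "),
         call. = FALSE)
  out <- codes[states]
  attributes(out) <- attributes(states)
  if (is.null(dim(states))) names(out) <- names(states)
  out
}

#' @rdname encode_states
#' @export
decode_states <- function(codes) {
  if (!all(codes %in% 0:2))
    stop("codes must be in 0:2", call. = FALSE)
  out <- gp_states()[as.integer(codes) + 1L]
  attributes(out) <- attributes(codes)
  if (is.null(dim(codes))) names(out) <- names(codes)
  out
}
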