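# InterProScan TSV input: build a per-proteome match table (protein to
# InterPro entries, plus member-database signature matches) and the
# promiscuous-evidence filter used when comparing annotation coverage
# across resources.

#' Construct a match table
#'
#' @param proteome_label Name of the proteome.
#' @param matches Named list, protein id to character vector of InterPro
#'   accessions.
#' @param signature_matches Named list, protein id to character vector of
#'   member-database signature accessions.
#' @return Object of class `gp_match_table`. Sets are deduplicated and
#'   `-` placeholders are never stored.
#' @export
match_table <- function(proteome_label, matches = list(),
                        signature_matches = list()) {
  clean <- function(l) {
    l <- lapply(l, function(v) sort(unique(v[v != "-" & nzchar(v)])))
    l[lengths(l) > 0L]
  }
  structure(
    list(proteome_label = proteome_label,
         matches = clean(matches),
         signature_matches = clean(signature_matches)),
    class = "gp_match_table"
  )
}

#' @export
print.gp_match_table <- function(x, ...) {
  cat(sprintf("<gp_match_table> %s: %d protein(s), %d distinct InterPro accession(s)\n",
              x$proteome_label, length(x$matches),
              length(unique(unlist(x$matches)))))
  invisible(x)
}

#' Parse InterProScan TSV output
#'
#' Reads the standard InterProScan tab-separated output: column 1 is the
#' protein accession, column 5 the member-database signature accession and
#' column 12 the integrated InterPro accession when one exists (`-` or
#' absent otherwise). Rows without an integrated InterPro accession
#' contribute only to the signature-level matches; duplicate
#' (protein, accession) pairs from multiple domain hits collapse to one.
#'
#' A simplified two-column `protein<TAB>accession` layout is accepted with
#' `simple = TRUE`, convenient for hand-built fixtures.
#'
#' @param x Path to a TSV file, or its text.
#' @param label Proteome label for the resulting table.
#' @param simple `TRUE` for the two-column layout.
#' @return A [match_table()]. Rows with fewer than 5 columns (2 when
#'   `simple`) are skipped, with one warning giving the count.
#' @export
parse_interproscan_tsv <- function(x, label, simple = FALSE) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  lines <- desc_lines(x)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(match_table(label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (simple) 2L else 5L
  short <- lengths(fields) < min_cols
  if (any(short))
    warning(sum(short), " row(s) with fewer than ", min_cols,
            " columns skipped", call. = FALSE)
  fields <- fields[!short]
  if (!length(fields)) return(match_table(label))
  prot <- vapply(fields, `[`, character(1), 1L)
  if (simple) {
    ipr <- vapply(fields, `[`, character(1), 2L)
    return(match_table(label, matches = split(ipr, prot)))
  }
  sig <- vapply(fields, `[`, character(1), 5L)
  ipr <- vapply(fields, function(f) if (length(f) >= 12L) f[12L] else "-",
                character(1))
  ipr[is.na(ipr)] <- "-"
  match_table(label,
              matches = split(ipr, prot),
              signature_matches = split(sig, prot))
}

# Invert a match table: accession -> protein ids carrying it.
matches_by_accession <- function(table) {
  if (!length(table$matches)) return(list())
  long <- data.frame(
    protein = rep(names(table$matches), lengths(table$matches)),
    accession = unlist(table$matches, use.names = FALSE))
  split(long$protein, long$accession)
}

#' Exclude promiscuous step evidence
#'
#' For fair comparison of annotation coverage across resources, matches to
#' a few non-specific models can over-inflate counts. This filter removes
#' all protein matches for any InterPro accession that (a) is used as step
#' evidence somewhere in the registry and (b) matches more than
#' `max_proteins` distinct proteins in the table. Accessions not used as
#' evidence are untouched. The filter is idempotent.
#'
#' @param table A [match_table()].
#' @param registry A [gp_registry()] defining which accessions count as
#'   step evidence.
#' @param max_proteins Largest allowed number of distinct proteins per
#'   evidence accession (default 3).
#' @return A filtered [match_table()] (signature matches untouched).
#' @export
apply_promiscuity_filter <- function(table, registry, max_proteins = 3L) {
  stopifnot(inherits(table, "gp_match_table"),
            inherits(registry, "gp_registry"),
            max_proteins >= 1L)
  evidence_accs <- unique(unlist(lapply(registry$properties,
                                        property_evidence,
                                        kind = "INTERPRO")))
  by_acc <- matches_by_accession(table)
  n_prot <- vapply(by_acc, function(p) length(unique(p)), integer(1))
  drop <- names(by_acc)[names(by_acc) %in% evidence_accs &
                          n_prot > max_proteins]
  if (!length(drop)) return(table)
  match_table(table$proteome_label,
              matches = lapply(table$matches, setdiff, drop),
              signature_matches = table$signature_matches)
}
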