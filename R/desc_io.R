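# DESC flatfile dialect: per-property records in the two-letter line-code
# style of the Pfam/TIGRFAMs DESC files, a concatenated release flatfile,
# tab-separated status sidecars, and FASTA example sidecars.
#
# Line format: CODE, two spaces, value.  Header half: AC DE TP AU TH,
# reference blocks RN/RM/RT/RA/RL, CC (multi-line description), DR
# cross-references "DB; ID;".  Step half starts at the first SN line; each
# step carries ID, optional DN, RQ (1/0), one EV line per evidence
# ("IPR000001; SIG1; SIG2;" -- signatures after the accession are kept as
# informational raw_signatures), optional TG ontology pass-through.
# Records end with "//".  Unknown codes are preserved as opaque
# annotations so newer files survive a round-trip.

CC_WRAP_WIDTH <- 74L

desc_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sub("[ \t\r]+$", "", text)
}

split_code <- function(line) {
  # "XX  value"; value may itself contain double spaces
  code <- substr(line, 1L, 2L)
  value <- sub("^..[ ]{2}", "", line)
  list(code = code, value = value)
}

parse_ev_value <- function(value, lineno, strict) {
  toks <- trimws(strsplit(value, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  ok <- grepl("^IPR", toks) | grepl("^GenProp", toks)
  if (!any(ok))
    stop("line ", lineno, ": EV line with no parsable accession: ", value,
         call. = FALSE)
  acc <- toks[ok][1L]
  gp_evidence(acc, raw_signatures = setdiff(toks, acc), strict = strict)
}

#' Parse one DESC record
#'
#' @param text One complete DESC record, as a single string or a character
#'   vector of lines; a trailing `//` terminator is optional.
#' @param strict Passed to accession validation; `FALSE` admits legacy
#'   identifiers.
#' @return A [genome_property()]. Step order is preserved; multi-line CC
#'   text is joined with single spaces; unknown line codes are kept in the
#'   `extra` fields (property- or step-level) for forward compatibility.
#' @seealso [write_desc()] for the inverse, [parse_flatfile()] for
#'   concatenated release files.
#' @export
parse_desc <- function(text, strict = TRUE) {
  lines <- desc_lines(text)
  keep <- nzchar(lines) & lines != "//"
  linenos <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty DESC record", call. = FALSE)

  hdr <- list(AC = NULL, DE = NULL, TP = NULL, AU = NULL, TH = NULL)
  cc <- character()
  refs <- list()
  xrefs <- list()
  extra <- character()
  steps <- list()
  cur <- NULL   # current step accumulator

  flush_step <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) cur$id <<- cur$dn %||% paste0("step_", cur$number)
    steps[[length(steps) + 1L]] <<- gp_step(
      number = cur$number, id = cur$id, required = cur$required %||% FALSE,
      evidences = cur$ev, display_name = cur$dn, extra = cur$extra)
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    p <- split_code(lines[[i]])
    code <- p$code; value <- p$value; lineno <- linenos[[i]]
    if (is.null(cur)) {
      switch(code,
        AC = { hdr$AC <- value },
        DE = { hdr$DE <- value },
        TP = { hdr$TP <- value },
        AU = { hdr$AU <- value },
        TH = {
          if (!grepl("^[0-9]+$", value))
            stop("line ", lineno, ": non-integer TH value: ", value,
                 call. = FALSE)
          hdr$TH <- as.integer(value)
        },
        CC = { cc <- c(cc, value) },
        RN = { refs[[length(refs) + 1L]] <-
                 list(number = as.integer(gsub("[^0-9]", "", value)),
                      pmid = "", title = "", authors = "", journal = "") },
        RM = { refs[[length(refs)]]$pmid <- value },
        RT = { refs[[length(refs)]]$title <-
                 paste(c(refs[[length(refs)]]$title, value)[
                   nzchar(c(refs[[length(refs)]]$title, value))],
                   collapse = " ") },
        RA = { refs[[length(refs)]]$authors <- value },
        RL = { refs[[length(refs)]]$journal <- value },
        DR = {
          toks <- trimws(strsplit(value, ";", fixed = TRUE)[[1]])
          toks <- toks[nzchar(toks)]
          xrefs[[length(xrefs) + 1L]] <- list(database = toks[1],
                                             id = toks[2])
        },
        SN = { cur <- list(number = as.integer(value), ev = list(),
                           extra = character()) },
        { extra[[code]] <- value }
      )
    } else {
      switch(code,
        SN = { flush_step()
               cur <- list(number = as.integer(value), ev = list(),
                           extra = character()) },
        ID = { cur$id <- value },
        DN = { cur$dn <- value },
        RQ = { cur$required <- value == "1" },
        EV = { cur$ev[[length(cur$ev) + 1L]] <-
                 parse_ev_value(value, lineno, strict) },
        { cur$extra[[code]] <- value }
      )
    }
  }
  flush_step()

  miss <- c("AC", "DE", "TP")[vapply(hdr[c("AC", "DE", "TP")],
                                     is.null, logical(1))]
  if (length(miss))
    stop("missing mandatory field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  references <-
    if (length(refs)) do.call(rbind, lapply(refs, as.data.frame)) else NULL
  xr <- if (length(xrefs)) do.call(rbind, lapply(xrefs, as.data.frame)) else NULL

  genome_property(
    accession = hdr$AC, name = hdr$DE, type = hdr$TP,
    threshold = hdr$TH %||% 0L,
    steps = steps, author = hdr$AU,
    description = if (length(cc)) paste(cc, collapse = " ") else NULL,
    references = references, xrefs = xr, extra = extra, strict = strict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one DESC record
#'
#' Serializes a property to the DESC dialect so that
#' `parse_desc(write_desc(p))` is structurally equal to `p` (the
#' description is reflowed at a fixed column; its whitespace-normalized
#' text is preserved).
#'
#' @param property A [genome_property()].
#' @return A single string, ending with the `//` record terminator and a
#'   final newline.
#' @export
write_desc <- function(property) {
  stopifnot(inherits(property, "genome_property"))
  out <- character()
  put <- function(code, value) out <<- c(out, paste0(code, "  ", value))
  put("AC", property$accession)
  put("DE", property$name)
  put("TP", property$type)
  if (!is.null(property$author)) put("AU", property$author)
  put("TH", property$threshold)
  if (nrow(property$references)) {
    for (i in seq_len(nrow(property$references))) {
      r <- property$references[i, ]
      put("RN", paste0("[", r$number, "]"))
      if (nzchar(r$pmid))    put("RM", r$pmid)
      if (nzchar(r$title))   put("RT", r$title)
      if (nzchar(r$authors)) put("RA", r$authors)
      if (nzchar(r$journal)) put("RL", r$journal)
    }
  }
  if (!is.null(property$description))
    for (l in strwrap(property$description, width = CC_WRAP_WIDTH))
      put("CC", l)
  if (nrow(property$xrefs))
    for (i in seq_len(nrow(property$xrefs)))
      put("DR", paste0(property$xrefs$database[i], "; ",
                       property$xrefs$id[i], ";"))
  for (code in names(property$extra)) put(code, property$extra[[code]])
  for (s in property$steps) {
    put("SN", s$number)
    put("ID", s$id)
    if (!is.null(s$display_name)) put("DN", s$display_name)
    put("RQ", if (s$required) "1" else "0")
    for (e in s$evidences)
      put("EV", paste0(paste(c(e$accession, e$raw_signatures),
                             collapse = "; "), ";"))
    for (code in names(s$extra)) put(code, s$extra[[code]])
  }
  paste0(paste(c(out, "//"), collapse = "\n"), "\n")
}

#' Parse a concatenated release flatfile
#'
#' Release flatfiles (`genomeProperties.txt`) are a concatenation of DESC
#' records separated by `//` lines. The default lenient mode collects
#' per-record parse errors and keeps going, as suits release files of
#' unknown provenance; strict mode fails on the first malformed record, as
#' suits curation.
#'
#' @param x Path to a flatfile, or its text (single string with newlines,
#'   or character vector of lines).
#' @param strict `TRUE` to fail fast on the first malformed record.
#' @param status Optional status table from [load_status()]; when given,
#'   only records that are both checked and public are registered.
#' @return A [gp_registry()] with attribute `"parse_errors"`, a character
#'   vector of collected error messages (empty when all records parsed).
#'   Dangling property references are not an error here; audit them with
#'   [validate_graph()].
#' @export
parse_flatfile <- function(x, strict = FALSE, status = NULL) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  lines <- desc_lines(x)
  if (!length(lines)) {
    registry <- gp_registry()
    attr(registry, "parse_errors") <- character()
    return(registry)
  }
  idx <- cumsum(c(0L, utils::head(lines == "//", -1L)))
  records <- split(lines, idx)
  registry <- gp_registry()
  errors <- character()
  for (rec in records) {
    rec <- rec[nzchar(rec) & rec != "//"]
    if (!length(rec)) next
    prop <- tryCatch(parse_desc(rec, strict = strict), error = identity)
    if (inherits(prop, "error")) {
      if (strict) stop(prop)
      errors <- c(errors, conditionMessage(prop))
      next
    }
    if (!is.null(status)) {
      row <- match(prop$accession, status$accession)
      if (!is.na(row) && !(status$checked[row] && status$public[row])) next
      prop$public <- is.na(row) || status$public[row]
    }
    reg2 <- tryCatch(register(registry, prop), error = identity)
    if (inherits(reg2, "error")) {
      if (strict) stop(reg2)
      errors <- c(errors, conditionMessage(reg2))
      next
    }
    registry <- reg2
  }
  attr(registry, "parse_errors") <- errors
  registry
}

#' Write a concatenated release flatfile
#'
#' @param registry A [gp_registry()].
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The flatfile text (invisibly when written to `path`).
#' @export
write_flatfile <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "gp_registry"))
  txt <- paste(vapply(registry$properties, write_desc, character(1)),
               collapse = "")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Load a status sidecar
#'
#' Status sidecars are two-column text, `accession<TAB>checked,public`
#' with 1/0 flags; a property is releasable only when both flags are set.
#'
#' @param x Path or text (string or lines).
#' @return Data frame with columns `accession`, `checked`, `public` and
#'   logical `releasable`.
#' @export
load_status <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  lines <- desc_lines(x)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(accession = character(), checked = logical(),
                      public = logical(), releasable = logical()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  acc <- vapply(parts, `[`, character(1), 1L)
  flags <- strsplit(vapply(parts, `[`, character(1), 2L), ",", fixed = TRUE)
  checked <- vapply(flags, function(f) f[1] == "1", logical(1))
  public  <- vapply(flags, function(f) f[2] == "1", logical(1))
  data.frame(accession = acc, checked = checked, public = public,
             releasable = checked & public)
}

#' Load a FASTA example sidecar
#'
#' Sidecars hold at least one example amino-acid sequence per
#' InterPro-evidenced step, as static validation examples. The step a
#' sequence exemplifies is encoded in its header as a `step=N` token;
#' headers lacking the token keep their sequence but get no step-map entry
#' (with a warning).
#'
#' @param x Path to a FASTA file, or FASTA text.
#' @param accession The property the sidecar belongs to.
#' @return Object of class `gp_fasta_sidecar`: list with `accession`,
#'   `sequences` (named character, header to sequence) and `step_map`
#'   (named integer, header to step number).
#' @export
load_fasta <- function(x, accession) {
  path <- x
  if (length(x) > 1L || grepl("\n", x[1], fixed = TRUE) || !file.exists(x)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(desc_lines(x), path)
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  if (anyDuplicated(headers))
    stop("duplicate FASTA headers: ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "),
         call. = FALSE)
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence in FASTA sidecar", call. = FALSE)
  step_tok <- regmatches(headers, regexpr("step=[0-9]+", headers))
  has_tok <- grepl("step=[0-9]+", headers)
  if (any(!has_tok))
    warning("FASTA header(s) without step=N token: ",
            paste(headers[!has_tok], collapse = ", "), call. = FALSE)
  step_map <- as.integer(sub("step=", "", step_tok, fixed = TRUE))
  names(step_map) <- headers[has_tok]
  structure(
    list(accession = accession,
         sequences = stats::setNames(as.character(seqs), headers),
         step_map = step_map),
    class = "gp_fasta_sidecar"
  )
}
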