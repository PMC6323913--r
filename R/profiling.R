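# Phylogenetic profiling: property-by-proteome state matrices, the fixed
# numeric encoding, Gower distances between proteome fingerprints, a
# rank-based ANOSIM permutation test, and the three-source
# annotation-overlap partition.

#' Build a property-by-proteome profile matrix
#'
#' @param results_by_proteome Named list, one element per proteome:
#'   either an [evaluate_all()] result list or a named character vector
#'   of states. All proteomes must cover the same property set.
#' @return Character matrix of states, rows = sorted property accessions,
#'   columns = proteomes in input order.
#' @export
build_matrix <- function(results_by_proteome) {
  stopifnot(is.list(results_by_proteome),
            length(results_by_proteome) >= 1L,
            !is.null(names(results_by_proteome)))
  states <- lapply(results_by_proteome, function(r) {
    if (is.list(r))
      vapply(r, function(x) x$state, character(1))
    else
      r
  })
  accs <- sort(names(states[[1]]))
  for (lab in names(states)) {
    got <- sort(names(states[[lab]]))
    if (!identical(got, accs)) {
      diff <- c(setdiff(accs, got), setdiff(got, accs))
      stop("proteome ", lab, " does not cover the same properties; ",
           "mismatched accession(s): ", paste(diff, collapse = ", "),
           call. = FALSE)
    }
  }
  m <- vapply(states, function(s) s[accs], character(length(accs)))
  m <- matrix(m, nrow = length(accs),
              dimnames = list(accs, names(states)))
  bad <- !(m %in% gp_states())
  if (any(bad))
    stop("invalid state value(s): ", paste(unique(m[bad]), collapse = ", "),
         call. = FALSE)
  m
}

#' Numerically encode a profile matrix
#'
#' Elementwise NO = 0, PARTIAL = 1, YES = 2; [decode_matrix()] inverts.
#'
#' @param m Character state matrix from [build_matrix()].
#' @return Integer matrix with the same dimnames.
#' @export
encode_matrix <- function(m) {
  out <- matrix(gp_state_codes()[m], nrow = nrow(m), dimnames = dimnames(m))
  storage.mode(out) <- "integer"
  if (anyNA(out))
    stop("invalid state value(s) in matrix", call. = FALSE)
  out
}

#' @rdname encode_matrix
#' @param codes Integer matrix with values in 0:2.
#' @export
decode_matrix <- function(codes) {
  if (!all(codes %in% 0:2)) stop("codes must be in 0:2", call. = FALSE)
  matrix(gp_states()[codes + 1L], nrow = nrow(codes),
         dimnames = dimnames(codes))
}

#' Gower distance between two fingerprints
#'
#' Mean over features of `|x_i - y_i| / range_i`. Features whose range is
#' zero carry no information and are dropped from the mean.
#'
#' @param x,y Equal-length numeric vectors.
#' @param ranges Per-feature ranges (recycled if length 1). On encoded
#'   profile vectors the natural range is 2 (NO at 0 to YES at 2).
#' @return A number in `[0, 1]`; 0 if every feature has zero range.
#' @export
gower_distance <- function(x, y, ranges = 2) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  ranges <- rep_len(ranges, length(x))
  keep <- ranges > 0
  if (!any(keep)) return(0)
  mean(abs(x[keep] - y[keep]) / ranges[keep])
}

#' Gower distance matrix over proteome fingerprints
#'
#' Computes all pairwise [gower_distance()] values between the columns of
#' an encoded profile matrix, using the observed per-property range
#' across proteomes (properties constant across all proteomes are
#' dropped).
#'
#' @param codes Integer matrix from [encode_matrix()]; columns are
#'   proteomes.
#' @return A [stats::dist] object over the columns.
#' @export
gower_dist <- function(codes) {
  stopifnot(is.matrix(codes), ncol(codes) >= 2L)
  ranges <- apply(codes, 1L, max) - apply(codes, 1L, min)
  n <- ncol(codes)
  d <- matrix(0, n, n, dimnames = list(colnames(codes), colnames(codes)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- gower_distance(codes[, i], codes[, j], ranges)
  stats::as.dist(d)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether distances between groups exceed distances
#' within groups. All `n(n-1)/2` pairwise distances are ranked (mid-ranks
#' for ties) and the statistic is
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' in `[-1, 1]`. Significance comes from permuting group labels:
#' `p = (1 + #[permuted R >= observed R]) / (1 + n_permutations)`.
#'
#' @param d A [stats::dist] or square symmetric zero-diagonal matrix.
#' @param groups Group label per sample; at least 2 groups, each of size
#'   at least 2.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer; fixes the permutation stream without
#'   disturbing the caller's RNG state.
#' @return Object of class `gp_anosim`: list with `statistic` (R),
#'   `p_value`, `n_permutations` and `perm_stats` (the permuted R
#'   values).
#' @export
anosim_test <- function(d, groups, n_permutations = 999L, seed = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("groups length must equal the number of samples", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("every group must have at least 2 members", call. = FALSE)
  stopifnot(n_permutations >= 1L)

  ranks <- rank(as.vector(d))  # mid-ranks for ties
  pair_i <- unlist(lapply(seq_len(n - 1L), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  denom <- n * (n - 1L) / 4

  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(ranks[!within]) - mean(ranks[within])) / denom
  }
  observed <- r_stat(groups)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  perm_stats <- vapply(seq_len(n_permutations),
                       function(k) r_stat(sample(groups)), numeric(1))
  p <- (1 + sum(perm_stats >= observed)) / (1 + n_permutations)
  structure(
    list(statistic = observed, p_value = p,
         n_permutations = as.integer(n_permutations),
         perm_stats = perm_stats),
    class = "gp_anosim"
  )
}

#' @export
print.gp_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Three-source annotation overlap partition
#'
#' Partitions the proteins of a proteome by which of three annotation
#' sources cover them: the 7 disjoint regions of the three sets (all
#' three; each pairwise-only overlap; each source-only remainder), plus
#' the unannotated remainder. The 8 counts always sum to `total`.
#'
#' @param annotations_by_source Named list of exactly 3 character vectors
#'   of protein ids, one per source.
#' @param total Total number of proteins in the proteome; must be at
#'   least the size of the union.
#' @return Object of class `gp_overlap`: list with `sources`, `counts`
#'   (named integer vector of the 7 region counts, in the order ALL,
#'   A&B, B&C, C&A, A only, B only, C only), `unannotated` and `total`.
#' @export
overlap_partition <- function(annotations_by_source, total) {
  stopifnot(is.list(annotations_by_source),
            length(annotations_by_source) == 3L,
            !is.null(names(annotations_by_source)))
  sets <- lapply(annotations_by_source, unique)
  src <- names(sets)
  a <- sets[[1]]; b <- sets[[2]]; c_ <- sets[[3]]
  un <- unique(c(a, b, c_))
  if (total < length(un))
    stop("total (", total, ") is below the union size (", length(un), ")",
         call. = FALSE)
  in_a <- un %in% a; in_b <- un %in% b; in_c <- un %in% c_
  counts <- c(
    sum(in_a & in_b & in_c),
    sum(in_a & in_b & !in_c),
    sum(in_b & in_c & !in_a),
    sum(in_c & in_a & !in_b),
    sum(in_a & !in_b & !in_c),
    sum(in_b & !in_c & !in_a),
    sum(in_c & !in_a & !in_b))
  names(counts) <- c("ALL",
                     paste0(src[1], "&", src[2]),
                     paste0(src[2], "&", src[3]),
                     paste0(src[3], "&", src[1]),
                     paste0(src[1], " only"),
                     paste0(src[2], " only"),
                     paste0(src[3], " only"))
  structure(
    list(sources = src, counts = counts,
         unannotated = total - length(un), total = as.integer(total)),
    class = "gp_overlap"
  )
}

#' @export
print.gp_overlap <- function(x, ...) {
  cat("<gp_overlap> total", x$total, "\n")
  print(c(x$counts, Unannotated = x$unannotated))
  invisible(x)
}

#' Export a profile matrix for downstream viewers
#'
#' Writes a long-form table (property, proteome, state, numeric code) and
#' a JSON matrix document.
#'
#' @param m State matrix from [build_matrix()].
#' @param tsv_path,json_path Optional output paths.
#' @return The long-form data frame, invisibly when either path is given.
#' @export
export_profiles <- function(m, tsv_path = NULL, json_path = NULL) {
  codes <- encode_matrix(m)
  long <- data.frame(
    property = rep(rownames(m), times = ncol(m)),
    proteome = rep(colnames(m), each = nrow(m)),
    state = as.vector(m),
    numeric = as.vector(codes))
  if (!is.null(tsv_path))
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    col_lists <- function(x) lapply(seq_len(ncol(x)), function(j)
      as.list(unname(x[, j])))
    doc <- list(properties = rownames(m), proteomes = colnames(m),
                states = col_lists(m), numeric = col_lists(codes))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE)
  }
  if (is.null(tsv_path) && is.null(json_path)) long else invisible(long)
}
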