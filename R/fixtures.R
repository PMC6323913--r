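# Deterministic synthetic fixtures: registries wired so every QC check
# passes, InterProScan-style match tables with planted YES/PARTIAL/NO
# ground truth, FASTA sidecars, and grouped profile sets for exercising
# the ANOSIM machinery.  Synthetic InterPro accessions come from a
# reserved IPR9xxxxx test range and protein ids are label_P000N, so
# fixtures can never collide with real accessions.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

fixture_words <- c("Threonine", "Biotin", "Proline", "Histidine",
                   "Menaquinone", "Cobalamin", "Lysine", "Chorismate",
                   "Heme", "Molybdopterin", "Thiamine", "Riboflavin")
fixture_processes <- c("biosynthesis", "utilization", "transport system",
                       "degradation", "salvage pathway")

#' Generate a synthetic property registry
#'
#' Builds a deterministic registry of leaf properties (functional types
#' with InterPro evidence only), metapaths citing disjoint subsets of the
#' leaves, and categories wiring everything to a root so the hierarchy
#' connectivity check passes. Every leaf has at least two required steps
#' and a threshold at most `required - 2`, so all three planted states
#' are always feasible.
#'
#' @param n_leaves Number of leaf properties.
#' @param n_metapath,n_category Numbers of metapaths and categories (at
#'   least one category; the first is the root).
#' @param steps_range Length-2 integer range of steps per leaf (min 2).
#' @param required_fraction Probability that a step beyond the first two
#'   is required.
#' @param seed Integer seed; the same seed yields byte-identical
#'   flatfiles.
#' @return A [gp_registry()] with attribute `"roots"` naming the root
#'   category.
#' @export
make_registry <- function(n_leaves = 6L, n_metapath = 1L, n_category = 1L,
                          steps_range = c(2L, 4L),
                          required_fraction = 0.8, seed = 1L) {
  stopifnot(n_leaves >= 1L, n_metapath >= 0L, n_category >= 1L,
            steps_range[1] >= 2L, steps_range[2] >= steps_range[1])
  with_seed(seed, {
    ipr_n <- 900000L
    next_ipr <- function() {
      ipr_n <<- ipr_n + 1L
      sprintf("IPR%06d", ipr_n)
    }
    leaf_types <- c("PATHWAY", "SYSTEM", "GUILD", "COMPLEX")
    registry <- gp_registry()
    mk_name <- function()
      paste(sample(fixture_words, 1), sample(fixture_processes, 1))

    leaf_accs <- sprintf("GenProp9%03d", seq_len(n_leaves))
    for (i in seq_len(n_leaves)) {
      n_steps <- sample(steps_range[1]:steps_range[2], 1L)
      required <- c(TRUE, TRUE,
                    if (n_steps > 2L)
                      stats::runif(n_steps - 2L) < required_fraction)
      steps <- lapply(seq_len(n_steps), function(k)
        gp_step(number = k, id = sprintf("enzyme_%d", k),
                required = required[k],
                evidences = list(gp_evidence(next_ipr()))))
      n_req <- sum(required)
      threshold <- sample(0:(n_req - 2L), 1L)
      prop <- genome_property(
        accession = leaf_accs[i], name = mk_name(),
        type = sample(leaf_types, 1L), threshold = threshold,
        steps = steps, author = "Fixture curator",
        description = paste("Synthetic", tolower(mk_name()),
                            "property generated for testing."),
        references = if (i %% 2L == 1L)
          data.frame(number = 1L, pmid = as.character(10000000L + i),
                     title = "A synthetic reference.",
                     authors = "Doe J, Roe R.", journal = "J Synth Biol.")
        else NULL,
        xrefs = if (i %% 3L == 1L)
          data.frame(database = "MetaCyc", id = sprintf("PWY-%04d", i))
        else NULL)
      registry <- register(registry, prop)
    }

    # metapaths cite disjoint leaf subsets so planted states stay independent
    meta_accs <- character()
    leaf_pool <- leaf_accs
    if (n_metapath > 0L) {
      chunks <- split(leaf_pool,
                      sort(rep_len(seq_len(n_metapath), length(leaf_pool))))
      meta_accs <- sprintf("GenProp95%02d", seq_len(n_metapath))
      for (i in seq_len(n_metapath)) {
        children <- chunks[[i]]
        steps <- lapply(seq_along(children), function(k)
          gp_step(number = k, id = sprintf("component_%d", k),
                  required = TRUE,
                  evidences = list(gp_evidence(children[k]))))
        threshold <- if (length(children) >= 2L)
          sample(0:(length(children) - 2L), 1L) else 0L
        registry <- register(registry, genome_property(
          accession = meta_accs[i], name = paste("Metapath:", mk_name()),
          type = "METAPATH", threshold = threshold, steps = steps,
          author = "Fixture curator"))
      }
    }

    cat_accs <- sprintf("GenProp99%02d", seq_len(n_category))
    root <- cat_accs[1]
    # root category cites the metapaths, any leaves not under a metapath,
    # and the remaining categories
    root_children <- c(meta_accs,
                       if (n_metapath == 0L) leaf_accs,
                       cat_accs[-1])
    extra_cited <- character()
    if (n_category > 1L) {
      # spread a leaf under each extra category for hierarchy depth
      extra <- utils::head(rep_len(leaf_accs, n_category - 1L),
                           n_category - 1L)
      extra_cited <- extra
    }
    for (i in rev(seq_len(n_category))) {
      children <- if (i == 1L) root_children else extra_cited[i - 1L]
      steps <- lapply(seq_along(children), function(k)
        gp_step(number = k, id = sprintf("member_%d", k), required = TRUE,
                evidences = list(gp_evidence(children[k]))))
      registry <- register(registry, genome_property(
        accession = cat_accs[i], name = paste("Category:", mk_name()),
        type = "CATEGORY", threshold = 0L, steps = steps,
        author = "Fixture curator"))
    }
    attr(registry, "roots") <- root
    registry
  })
}

# Leaf = property whose evidence is all InterPro.
leaf_accessions <- function(registry) {
  accs <- names(registry$properties)
  accs[vapply(accs, function(a)
    length(property_evidence(registry$properties[[a]],
                             kind = "GENPROP")) == 0L, logical(1))]
}

# Expected state of every property given leaf states, straight from the
# threshold definition (used as fixture ground truth).
derive_truth <- function(registry, leaf_states) {
  truth <- leaf_states
  remaining <- setdiff(names(registry$properties), names(truth))
  while (length(remaining)) {
    progressed <- FALSE
    for (acc in remaining) {
      prop <- registry$properties[[acc]]
      children <- vapply(prop$steps, function(s)
        s$evidences[[1]]$accession, character(1))
      if (!all(children %in% names(truth))) next
      required <- vapply(prop$steps, `[[`, logical(1), "required")
      matched <- truth[children] == "YES"
      n_req <- sum(required)
      m <- sum(required & matched)
      truth[[acc]] <- if (n_req > 0L && m == n_req) "YES"
        else if (m > prop$threshold) "PARTIAL" else "NO"
      progressed <- TRUE
    }
    remaining <- setdiff(names(registry$properties), names(truth))
    if (!progressed) stop("cyclic fixture registry", call. = FALSE)
  }
  truth[names(registry$properties)]
}

#' Generate a match table with planted states
#'
#' Emits InterProScan-style TSV text such that evaluating the registry
#' against it reproduces a planted state per leaf property exactly. For a
#' PARTIAL plant, the number of matched required steps is drawn uniformly
#' from the open interval between the threshold and the required count;
#' for NO, from 0 up to the threshold; optional steps match at random
#' (they never affect the state). States of metapaths and categories
#' follow from the planted leaves; the full expected vector is returned
#' as ground truth.
#'
#' @param registry Registry from [make_registry()].
#' @param planted_states Named character vector of states over the leaf
#'   properties (defaults to a uniform random draw).
#' @param seed Integer seed.
#' @param label Proteome label used in protein ids.
#' @return List with `tsv` (the match text), `truth` (named expected
#'   state for every property) and `planted` (the leaf plants).
#' @export
make_matches <- function(registry, planted_states = NULL, seed = 1L,
                         label = "fixture") {
  leaves <- leaf_accessions(registry)
  with_seed(seed, {
    if (is.null(planted_states))
      planted_states <- stats::setNames(
        sample(gp_states(), length(leaves), replace = TRUE), leaves)
    stopifnot(setequal(names(planted_states), leaves),
              all(planted_states %in% gp_states()))
    prot_n <- 0L
    rows <- character()
    add_match <- function(ipr) {
      for (k in seq_len(sample(1:2, 1L))) {
        prot_n <<- prot_n + 1L
        prot <- sprintf("%s_P%04d", label, prot_n)
        sig <- sub("IPR", "SYN", ipr)
        rows <<- c(rows, paste(
          prot, "md5", "300", "SYNTHDB", sig, "synthetic signature",
          "1", "250", "1e-30", "T", "01-01-2026", ipr,
          "synthetic entry", sep = "\t"))
      }
    }
    for (acc in leaves) {
      prop <- registry$properties[[acc]]
      required <- vapply(prop$steps, `[[`, logical(1), "required")
      n_req <- sum(required)
      state <- planted_states[[acc]]
      m <- switch(state,
        YES = n_req,
        PARTIAL = {
          lo <- prop$threshold + 1L
          hi <- n_req - 1L
          if (lo > hi)
            stop(acc, ": PARTIAL infeasible (threshold ", prop$threshold,
                 ", required ", n_req, ")", call. = FALSE)
          if (lo == hi) lo else sample(lo:hi, 1L)
        },
        NO = if (prop$threshold == 0L) 0L else sample(0:prop$threshold, 1L))
      req_idx <- which(required)
      hit_idx <- if (m > 0L) sort(sample(req_idx, m)) else integer()
      opt_idx <- which(!required)
      hit_idx <- c(hit_idx, opt_idx[stats::runif(length(opt_idx)) < 0.5])
      for (i in hit_idx) {
        ev <- prop$steps[[i]]$evidences
        add_match(ev[[sample(length(ev), 1L)]]$accession)
      }
    }
    list(tsv = paste0(paste(rows, collapse = "\n"),
                      if (length(rows)) "\n" else ""),
         truth = derive_truth(registry, planted_states),
         planted = planted_states)
  })
}

#' Generate FASTA example sidecars
#'
#' One random amino-acid example sequence per InterPro-evidenced step of
#' every non-category property, with the `step=N` header token, so the
#' sidecar presence check passes on generated registries.
#'
#' @param registry Registry from [make_registry()].
#' @param seed Integer seed.
#' @return Named list of [load_fasta()] sidecars keyed by accession.
#' @export
make_sidecars <- function(registry, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    out <- list()
    for (acc in names(registry$properties)) {
      prop <- registry$properties[[acc]]
      if (prop$type == "CATEGORY") next
      ipr_steps <- Filter(function(s)
        any(vapply(s$evidences, `[[`, character(1), "kind") == "INTERPRO"),
        prop$steps)
      if (!length(ipr_steps)) next
      fasta <- unlist(lapply(ipr_steps, function(s) c(
        sprintf(">%s_%d step=%d example", acc, s$number, s$number),
        paste(sample(aa, 60L, replace = TRUE), collapse = ""))))
      out[[acc]] <- load_fasta(paste(fasta, collapse = "\n"), acc)
    }
    out
  })
}

#' Accession universe of a registry
#'
#' All InterPro accessions used as evidence; serves as the valid-accession
#' universe when QC-checking a registry against itself.
#'
#' @param registry A [gp_registry()].
#' @return Sorted character vector.
#' @export
fixture_universe <- function(registry) {
  sort(unique(unlist(lapply(registry$properties, property_evidence,
                            kind = "INTERPRO"))))
}

#' Generate grouped profile fingerprints
#'
#' Emulates the group structure seen when profiling many genomes: each
#' group carries its own block of properties (present with probability
#' `separation` inside the group, absent outside), over a background of
#' properties whose base state is shared by all proteomes and flipped to
#' a random state with probability `0.3 * (1 - separation)`. At
#' `separation = 1` groups are perfectly separated (within-group Gower
#' distance 0) so ANOSIM R is exactly 1; at `separation = 0` there is no
#' group signal and R fluctuates around 0.
#'
#' @param n_groups,n_per_group Grouping layout (each group needs at least
#'   2 members for ANOSIM).
#' @param separation Number in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_block Block properties per group.
#' @param n_background Shared background properties.
#' @return List with `results_by_proteome` (named list of state vectors,
#'   ready for [build_matrix()]) and `groups` (label per proteome).
#' @export
make_grouped_profiles <- function(n_groups = 3L, n_per_group = 6L,
                                  separation = 1, seed = 1L,
                                  n_block = 20L, n_background = 40L) {
  stopifnot(n_groups >= 2L, n_per_group >= 2L,
            separation >= 0, separation <= 1, n_groups <= 9L)
  with_seed(seed, {
    block_accs <- lapply(seq_len(n_groups), function(g)
      sprintf("GenProp7%d%02d", g, seq_len(n_block)))
    bg_accs <- sprintf("GenProp60%02d", seq_len(n_background))
    bg_base <- sample(gp_states(), n_background, replace = TRUE)
    noise <- 0.3 * (1 - separation)
    results <- list()
    groups <- character()
    for (g in seq_len(n_groups)) {
      for (s in seq_len(n_per_group)) {
        lab <- sprintf("g%d_s%02d", g, s)
        states <- character()
        for (h in seq_len(n_groups)) {
          v <- if (h == g)
            ifelse(stats::runif(n_block) < separation, "YES", "NO")
          else rep("NO", n_block)
          states <- c(states, stats::setNames(v, block_accs[[h]]))
        }
        bg <- bg_base
        flip <- stats::runif(n_background) < noise
        if (any(flip))
          bg[flip] <- sample(gp_states(), sum(flip), replace = TRUE)
        states <- c(states, stats::setNames(bg, bg_accs))
        results[[lab]] <- states
        groups <- c(groups, sprintf("group%d", g))
      }
    }
    list(results_by_proteome = results,
         groups = stats::setNames(groups, names(results)))
  })
}
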