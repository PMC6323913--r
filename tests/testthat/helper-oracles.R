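# Independent oracles: a fixed-point brute-force evaluator, exhaustive
# cycle detection, one-step reverse-citation scan, and an enumeration
# comparator for evidence selection.  These deliberately avoid the
# package's graph/topological machinery.

# Fixed-point evaluation: start everything at NO and recompute each
# property's state from the current vector until nothing changes.
brute_force_evaluate <- function(registry, table, partial_counts = FALSE) {
  props <- registry$properties
  acc_of_protein <- table$matches
  has_ipr <- function(acc) any(vapply(acc_of_protein, function(v)
    acc %in% v, logical(1)))
  states <- setNames(rep("NO", length(props)), names(props))
  repeat {
    prev <- states
    for (a in names(props)) {
      p <- props[[a]]
      matched <- vapply(p$steps, function(s) {
        any(vapply(s$evidences, function(e) {
          if (e$kind == "INTERPRO") has_ipr(e$accession)
          else states[[e$accession]] == "YES" ||
            (partial_counts && states[[e$accession]] == "PARTIAL")
        }, logical(1)))
      }, logical(1))
      required <- vapply(p$steps, `[[`, logical(1), "required")
      n_req <- sum(required)
      m <- sum(required & matched)
      states[[a]] <- if (n_req > 0 && m == n_req) "YES"
        else if (m > p$threshold) "PARTIAL" else "NO"
    }
    if (identical(states, prev)) return(states)
  }
}

# Exhaustive path search: is there a path from any node back to itself?
brute_has_cycle <- function(nodes, edges) {
  reach <- function(from, to, seen = character()) {
    if (from %in% seen) return(FALSE)
    nxt <- edges$to[edges$from == from]
    if (to %in% nxt) return(TRUE)
    any(vapply(nxt, reach, logical(1), to = to, seen = c(seen, from)))
  }
  any(vapply(nodes, function(v) reach(v, v), logical(1)))
}

# One-step reverse-citation scan over raw step structures (never the
# registry's edge table).
brute_orphans <- function(registry, roots = character()) {
  props <- registry$properties
  orphans <- character()
  for (a in names(props)) {
    citers <- Filter(function(citer) {
      any(vapply(props[[citer]]$steps, function(s)
        any(vapply(s$evidences, function(e)
          e$kind == "GENPROP" && e$accession == a, logical(1))),
        logical(1)))
    }, names(props))
    citer_types <- vapply(props[citers], `[[`, character(1), "type")
    ok <- if (props[[a]]$type == "CATEGORY")
      a %in% roots || any(citer_types == "CATEGORY")
    else any(citer_types %in% c("CATEGORY", "METAPATH"))
    if (!ok) orphans <- c(orphans, a)
  }
  sort(orphans)
}

# Pairwise comparator + argmax enumeration for evidence selection.
brute_select <- function(candidates) {
  better <- function(i, j) {
    a <- candidates[i, ]; b <- candidates[j, ]
    fam_a <- a$entry_type == "FAMILY"; fam_b <- b$entry_type == "FAMILY"
    if (fam_a != fam_b) return(fam_a)
    if (a$hierarchy_depth != b$hierarchy_depth)
      return(a$hierarchy_depth > b$hierarchy_depth)
    ba <- if (is.null(candidates$taxonomic_breadth) ||
              is.na(a$taxonomic_breadth)) -Inf else a$taxonomic_breadth
    bb <- if (is.null(candidates$taxonomic_breadth) ||
              is.na(b$taxonomic_breadth)) -Inf else b$taxonomic_breadth
    if (ba != bb) return(ba > bb)
    a$accession < b$accession
  }
  best <- 1L
  for (i in seq_len(nrow(candidates))[-1L])
    if (better(i, best)) best <- i
  candidates$accession[best]
}

# Hand-rolled ANOSIM: explicit rank computation by counting, then the
# statistic, with no shared code with anosim_test().
brute_anosim_r <- function(dmat, groups) {
  n <- nrow(dmat)
  dv <- numeric(); within <- logical()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- c(dv, dmat[i, j])
      within <- c(within, groups[i] == groups[j])
    }
  }
  # mid-ranks by counting smaller and equal values
  ranks <- vapply(dv, function(v)
    sum(dv < v) + (sum(dv == v) + 1) / 2, numeric(1))
  (mean(ranks[!within]) - mean(ranks[within])) / (n * (n - 1) / 4)
}

# Small random registry (leaves + up to two tiers of metapaths) and a
# random match table, for oracle-equivalence sweeps.
random_registry_and_table <- function(seed) {
  set.seed(seed)
  n_leaf <- sample(3:12, 1)
  reg <- gp_registry()
  ipr <- sprintf("IPR9%05d", seq_len(60))
  ipr_i <- 0L
  leaf_accs <- sprintf("GenProp8%03d", seq_len(n_leaf))
  for (a in leaf_accs) {
    n_steps <- sample(1:4, 1)
    steps <- lapply(seq_len(n_steps), function(k) {
      ipr_i <<- ipr_i + 1L
      gp_step(k, sprintf("s%d", k), required = runif(1) < 0.8,
              evidences = list(gp_evidence(ipr[ipr_i])))
    })
    n_req <- sum(vapply(steps, `[[`, logical(1), "required"))
    th <- if (n_req > 1) sample(0:(n_req - 1), 1) else 0L
    reg <- register(reg, suppressWarnings(genome_property(
      a, paste("leaf", a), sample(c("PATHWAY", "SYSTEM", "GUILD"), 1),
      threshold = th, steps = steps)))
  }
  tier1 <- character()
  for (k in seq_len(sample(0:3, 1))) {
    a <- sprintf("GenProp87%02d", k)
    children <- sample(leaf_accs, min(sample(2:4, 1), n_leaf))
    steps <- lapply(seq_along(children), function(i)
      gp_step(i, sprintf("c%d", i), required = runif(1) < 0.9,
              evidences = list(gp_evidence(children[i]))))
    reg <- register(reg, suppressWarnings(genome_property(
      a, paste("meta", a), "METAPATH",
      threshold = sample(0:1, 1), steps = steps)))
    tier1 <- c(tier1, a)
  }
  if (length(tier1) >= 2) {
    children <- sample(tier1, 2)
    steps <- lapply(1:2, function(i)
      gp_step(i, sprintf("c%d", i), required = TRUE,
              evidences = list(gp_evidence(children[i]))))
    reg <- register(reg, genome_property(
      "GenProp8800", "meta top", "METAPATH", threshold = 0L,
      steps = steps))
  }
  hit <- sample(ipr[seq_len(ipr_i)], size = rbinom(1, ipr_i, 0.5))
  matches <- lapply(seq_along(hit), function(i) hit[i])
  names(matches) <- sprintf("rt_P%03d", seq_along(hit))
  list(registry = reg, table = match_table("rt", matches = matches))
}

states_of <- function(results) vapply(results, function(x) x$state,
                                      character(1))

with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}
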