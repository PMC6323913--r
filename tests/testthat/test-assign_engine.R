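# Small builders used throughout: a leaf property with n required steps
# (evidence IPR00000k for step k) and a table matching the first m of them.
leaf_prop <- function(n_req, threshold, n_opt = 0, acc = "GenProp0001") {
  steps <- c(
    lapply(seq_len(n_req), function(k)
      gp_step(k, sprintf("req_%d", k),
              evidences = list(gp_evidence(sprintf("IPR%06d", k))))),
    lapply(seq_len(n_opt), function(k)
      gp_step(n_req + k, sprintf("opt_%d", k), required = FALSE,
              evidences = list(gp_evidence(sprintf("IPR%06d", n_req + k))))))
  suppressWarnings(genome_property(acc, acc, "PATHWAY",
                                   threshold = threshold, steps = steps))
}

table_matching <- function(idx) {
  if (!length(idx)) return(match_table("t"))
  matches <- lapply(idx, function(k) sprintf("IPR%06d", k))
  names(matches) <- sprintf("P%d", idx)
  match_table("t", matches = matches)
}

test_that("a step matches when any one of its evidences matches", {
  tab <- table_matching(1)
  s1 <- gp_step(1, "s", evidences = list(gp_evidence("IPR000001")))
  r1 <- evaluate_step(s1, tab)
  expect_true(r1$matched)
  expect_equal(r1$matched_by, list(IPR000001 = "P1"))

  s2 <- gp_step(1, "s", evidences = list(gp_evidence("IPR000099"),
                                         gp_evidence("IPR000001")))
  expect_true(evaluate_step(s2, tab)$matched)
  expect_false(evaluate_step(
    gp_step(1, "s", evidences = list(gp_evidence("IPR000099"))),
    tab)$matched)
})

test_that("property evidence requires YES unless partial_counts is on", {
  s <- gp_step(1, "s", evidences = list(gp_evidence("GenProp0002")))
  partial_sub <- list(GenProp0002 = structure(
    list(accession = "GenProp0002", state = "PARTIAL"), class = "gp_result"))
  expect_false(evaluate_step(s, match_table("t"), partial_sub)$matched)
  expect_true(evaluate_step(s, match_table("t"), partial_sub,
                            partial_counts = TRUE)$matched)
  expect_error(evaluate_step(s, match_table("t"), list()), "unresolved")
})

test_that("states follow the threshold rule on required steps", {
  p <- leaf_prop(3, threshold = 1)
  expect_equal(evaluate_property(p, table_matching(1:3))$state, "YES")
  expect_equal(evaluate_property(p, table_matching(1:2))$state, "PARTIAL")
  expect_equal(evaluate_property(p, table_matching(1))$state, "NO")
  expect_equal(evaluate_property(p, table_matching(integer()))$state, "NO")
})

test_that("optional steps are reported but never change the state", {
  p <- leaf_prop(2, threshold = 0, n_opt = 1)
  # both required matched, optional not: YES
  res <- evaluate_property(p, table_matching(1:2))
  expect_equal(res$state, "YES")
  expect_false(res$step_results[[3]]$matched)
  # only the optional matched: still NO
  expect_equal(evaluate_property(p, table_matching(3))$state, "NO")
  expect_equal(evaluate_property(p, table_matching(3))$required_matched, 0)
})

test_that("a property with zero steps is NO with a warning", {
  p <- genome_property("GenProp0009", "empty", "PATHWAY")
  expect_warning(res <- evaluate_property(p, match_table("t")), "no steps")
  expect_equal(res$state, "NO")
})

test_that("evaluate_all resolves metapaths after their children", {
  reg <- register(gp_registry(), leaf_prop(2, 0, acc = "GenProp0001"))
  reg <- register(reg, leaf_prop(2, 0, acc = "GenProp0002"))
  # the second leaf uses the same IPR accessions 1:2; give it unreachable ones
  p2 <- genome_property(
    "GenProp0003", "other leaf", "PATHWAY", threshold = 0,
    steps = list(gp_step(1, "s",
                         evidences = list(gp_evidence("IPR000777")))))
  reg <- register(reg, p2)
  meta <- genome_property(
    "GenProp0100", "meta", "METAPATH", threshold = 0,
    steps = list(
      gp_step(1, "c1", evidences = list(gp_evidence("GenProp0001"))),
      gp_step(2, "c2", evidences = list(gp_evidence("GenProp0003")))))
  reg <- register(reg, meta)
  res <- evaluate_all(reg, table_matching(1:2))
  expect_equal(states_of(res)[c("GenProp0001", "GenProp0003", "GenProp0100")],
               c(GenProp0001 = "YES", GenProp0003 = "NO",
                 GenProp0100 = "PARTIAL"))
  # empty table: everything NO
  expect_true(all(states_of(evaluate_all(reg, match_table("t"))) == "NO"))
})

test_that("evaluate_all aborts on a cyclic registry with the cycle path", {
  mk <- function(acc, cites) genome_property(
    acc, acc, "METAPATH",
    steps = list(gp_step(1, "c", evidences = list(gp_evidence(cites)))))
  reg <- register(register(gp_registry(), mk("GenProp0001", "GenProp0002")),
                  mk("GenProp0002", "GenProp0001"))
  expect_error(evaluate_all(reg, match_table("t")), "cycle.*GenProp000")
})

test_that("evaluate_all equals the fixed-point oracle on random registries", {
  for (seed in 1:40) {
    fx <- random_registry_and_table(seed)
    got <- states_of(suppressWarnings(evaluate_all(fx$registry, fx$table)))
    want <- suppressWarnings(brute_force_evaluate(fx$registry, fx$table))
    expect_identical(got, want, info = paste("seed", seed))
  }
})

test_that("adding matches never demotes a state", {
  rank_of <- function(s) match(s, gp_states())
  for (seed in 1:10) {
    fx <- random_registry_and_table(seed)
    base <- states_of(suppressWarnings(evaluate_all(fx$registry, fx$table)))
    # add matches for every evidence accession in the registry
    all_ev <- unique(unlist(lapply(fx$registry$properties, function(p)
      unlist(lapply(p$steps, function(s)
        vapply(s$evidences, `[[`, character(1), "accession"))))))
    all_ev <- grep("^IPR", all_ev, value = TRUE)
    bigger <- match_table("t", matches = c(
      fx$table$matches,
      setNames(as.list(all_ev), sprintf("extra_P%d", seq_along(all_ev)))))
    more <- states_of(suppressWarnings(evaluate_all(fx$registry, bigger)))
    expect_true(all(rank_of(more) >= rank_of(base)),
                info = paste("seed", seed))
  }
})

report_fixture <- function() {
  reg <- register(gp_registry(), leaf_prop(2, 0))
  cat_prop <- genome_property(
    "GenProp0900", "a category", "CATEGORY",
    steps = list(gp_step(1, "m",
                         evidences = list(gp_evidence("GenProp0001")))))
  reg <- register(reg, cat_prop)
  list(registry = reg, results = evaluate_all(reg, table_matching(1:2)))
}

test_that("summary, long and protein reports have the stated shapes", {
  fx <- report_fixture()
  sm <- summary_report(fx$results, fx$registry)
  expect_equal(nrow(sm), 1)  # category excluded by default
  expect_equal(sm$state, "YES")
  expect_true(all(sm$state %in% c("YES", "PARTIAL", "NO")))
  sm_all <- summary_report(fx$results, fx$registry,
                           include_categories = TRUE)
  expect_equal(nrow(sm_all), 2)

  lg <- long_report(fx$results, fx$registry)
  expect_equal(nrow(lg), 3)  # 1 property row + 2 step rows
  expect_equal(lg$line, c("PROPERTY", "STEP", "STEP"))
  expect_equal(lg$matched[-1], c(TRUE, TRUE))

  pr <- protein_report(fx$results, fx$registry)
  expect_equal(nrow(pr), 2)  # one matched evidence per step
  expect_equal(pr$protein, c("P1", "P2"))
  expect_equal(pr$step_number, 1:2)
})

test_that("the protein report is empty when nothing matched", {
  reg <- register(gp_registry(), leaf_prop(2, 0))
  res <- evaluate_all(reg, match_table("t"))
  expect_equal(nrow(protein_report(res, reg)), 0)
})
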