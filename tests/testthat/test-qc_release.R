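leaf <- function(acc, ipr = "IPR000001") genome_property(
  acc, paste("leaf", acc), "PATHWAY",
  steps = list(gp_step(1, "s", evidences = list(gp_evidence(ipr)))))

category <- function(acc, cites) genome_property(
  acc, paste("category", acc), "CATEGORY",
  steps = lapply(seq_along(cites), function(k)
    gp_step(k, sprintf("m%d", k),
            evidences = list(gp_evidence(cites[k])))))

test_that("connectivity requires citation from a category or metapath", {
  reg <- register(gp_registry(), leaf("GenProp0001"))
  reg <- register(reg, leaf("GenProp0002", "IPR000002"))
  reg <- register(reg, category("GenProp0900",
                                c("GenProp0001", "GenProp0002")))
  expect_equal(check_connectivity(reg, roots = "GenProp0900"), character())

  reg2 <- register(gp_registry(), leaf("GenProp0001"))
  reg2 <- register(reg2, leaf("GenProp0002", "IPR000002"))
  reg2 <- register(reg2, category("GenProp0900", "GenProp0001"))
  expect_equal(check_connectivity(reg2, roots = "GenProp0900"),
               "GenProp0002")
  # an undesignated root category is itself an orphan
  expect_true("GenProp0900" %in% check_connectivity(reg2))
})

test_that("connectivity matches the brute-force reverse-citation scan", {
  for (seed in 1:15) {
    set.seed(seed)
    reg <- gp_registry()
    accs <- sprintf("GenProp0%03d", 1:8)
    for (i in 1:5) reg <- register(reg, leaf(accs[i], sprintf("IPR%06d", i)))
    # two categories citing random leaves, one metapath citing others
    reg <- register(reg, category(accs[6], sample(accs[1:5], 2)))
    reg <- register(reg, category(accs[7], c(sample(accs[1:5], 1), accs[6])))
    mp_children <- sample(accs[1:5], 2)
    reg <- register(reg, genome_property(
      accs[8], "mp", "METAPATH",
      steps = lapply(1:2, function(k)
        gp_step(k, sprintf("c%d", k),
                evidences = list(gp_evidence(mp_children[k]))))))
    roots <- accs[7]
    expect_equal(check_connectivity(reg, roots), brute_orphans(reg, roots),
                 info = paste("seed", seed))
  }
})

test_that("evidence validity is checked against the accession universe only", {
  reg <- register(gp_registry(), leaf("GenProp0001", "IPR000001"))
  reg <- register(reg, leaf("GenProp0002", "IPR000099"))
  expect_equal(nrow(check_evidence_validity(
    reg, c("IPR000001", "IPR000099"))), 0)
  bad <- check_evidence_validity(reg, "IPR000001")
  expect_equal(bad, data.frame(property = "GenProp0002",
                               accession = "IPR000099"))
  # property evidence is never checked against the universe
  reg2 <- register(gp_registry(), category("GenProp0900", "GenProp0001"))
  expect_equal(nrow(check_evidence_validity(reg2, character())), 0)
})

test_that("FASTA presence check flags absent and partial sidecars", {
  p <- genome_property(
    "GenProp0001", "two-step", "PATHWAY",
    steps = list(
      gp_step(1, "a", evidences = list(gp_evidence("IPR000001"))),
      gp_step(2, "b", evidences = list(gp_evidence("IPR000002")))))
  reg <- register(gp_registry(), p)
  reg <- register(reg, category("GenProp0900", "GenProp0001"))

  full <- load_fasta(">x step=1\nMK\n>y step=2\nMT", "GenProp0001")
  expect_equal(nrow(check_fasta_presence(
    reg, list(GenProp0001 = full))), 0)

  absent <- check_fasta_presence(reg, list())
  expect_equal(absent$property, "GenProp0001")  # category exempt
  expect_equal(absent$missing_steps, "1,2")

  half <- load_fasta(">x step=1\nMK", "GenProp0001")
  partial <- check_fasta_presence(reg, list(GenProp0001 = half))
  expect_equal(partial$missing_steps, "2")
})

test_that("release statistics count added properties per type", {
  old <- register(gp_registry(), leaf("GenProp0001"))
  expect_true(all(release_stats(old, old) == 0))

  new <- old
  new <- register(new, leaf("GenProp0002", "IPR000002"))
  new <- register(new, leaf("GenProp0003", "IPR000003"))
  cx <- genome_property(
    "GenProp0004", "complex", "COMPLEX",
    steps = list(gp_step(1, "s",
                         evidences = list(gp_evidence("IPR000004")))))
  new <- register(new, cx)
  st <- release_stats(old, new)
  expect_equal(st[["PATHWAY"]], 2)
  expect_equal(st[["COMPLEX"]], 1)
  expect_equal(st[["TOTAL"]], 3)

  # disjoint registries: counts equal the new registry's type histogram
  disj <- release_stats(gp_registry(), new)
  types <- vapply(new$properties, `[[`, character(1), "type")
  for (tp in gp_types())
    expect_equal(disj[[tp]], sum(types == tp))
})

test_that("evidence selection prefers family entries, then depth", {
  cands <- data.frame(
    accession = c("IPR000002", "IPR000001"),
    entry_type = c("DOMAIN", "FAMILY"),
    hierarchy_depth = c(5L, 0L))
  expect_equal(select_evidence(cands), "IPR000001")

  fam2 <- data.frame(
    accession = c("IPR000001", "IPR000002"),
    entry_type = "FAMILY", hierarchy_depth = c(1L, 3L))
  expect_equal(select_evidence(fam2), "IPR000002")
})

test_that("evidence selection matches enumeration and ignores input order", {
  types <- c("FAMILY", "DOMAIN", "HOMOLOGOUS_SUPERFAMILY", "OTHER")
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(2:8, 1)
    cands <- data.frame(
      accession = sample(sprintf("IPR%06d", 1:50), n),
      entry_type = sample(types, n, replace = TRUE),
      hierarchy_depth = sample(0:4, n, replace = TRUE),
      taxonomic_breadth = ifelse(runif(n) < 0.3, NA,
                                 sample(1:500, n, replace = TRUE)))
    expect_equal(select_evidence(cands), brute_select(cands),
                 info = paste("seed", seed))
    shuffled <- cands[sample(n), , drop = FALSE]
    expect_equal(select_evidence(shuffled), select_evidence(cands))
  }
})

test_that("a generated registry passes the full QC report and re-evaluates", {
  reg <- make_registry(n_leaves = 6, n_metapath = 2, n_category = 2,
                       seed = 13)
  rep <- qc_report(reg,
                   valid_accessions = fixture_universe(reg),
                   sidecars = make_sidecars(reg, seed = 13),
                   roots = attr(reg, "roots"))
  expect_true(rep$release_ready)
  # and the registry round-trips through the flatfile, then evaluates
  reg2 <- parse_flatfile(write_flatfile(reg), strict = TRUE)
  res <- evaluate_all(reg2, match_table("empty"))
  expect_length(res, length(reg))
})

test_that("QC warnings cover unreachable PARTIAL and missing required steps", {
  p <- suppressWarnings(genome_property(
    "GenProp0001", "tight", "PATHWAY", threshold = 1,
    steps = list(gp_step(1, "s",
                         evidences = list(gp_evidence("IPR000001"))))))
  opt_only <- genome_property(
    "GenProp0002", "optional only", "PATHWAY",
    steps = list(gp_step(1, "s", required = FALSE,
                         evidences = list(gp_evidence("IPR000002")))))
  reg <- register(register(gp_registry(), p), opt_only)
  reg <- register(reg, category("GenProp0900",
                                c("GenProp0001", "GenProp0002")))
  rep <- qc_report(reg, roots = "GenProp0900")
  expect_false(rep$release_ready)
  expect_true(any(grepl("threshold 1 not below", rep$warnings)))
  expect_true(any(grepl("no required step", rep$warnings)))
})
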