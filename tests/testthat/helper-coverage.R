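# Reference annotation-coverage counts for six microbial proteomes:
# numbers of sequences annotated by all three resources (Genome
# Properties, SEED subsystems, KEGG), by each pair only, by each resource
# only, plus the unannotated remainder and the proteome size.

coverage_counts <- data.frame(
  proteome = c("Prochlorococcus marinus subsp. pastoris str. CCMP1986",
               "Methanohalophilus halophilus strain Z-7982",
               "Escherichia coli K-12 strain K-12 C3026",
               "Burkholderia ambifaria AMMD",
               "Halanaerobium praevalens DSM 2228",
               "Xanthomonas campestris pv. campestris str. B100"),
  all = c(208, 151, 498, 496, 216, 381),
  gp_ss = c(88, 75, 387, 345, 171, 303),
  ss_kegg = c(39, 71, 136, 309, 49, 135),
  kegg_gp = c(102, 60, 146, 133, 84, 93),
  kegg_only = c(44, 122, 112, 309, 70, 121),
  ss_only = c(151, 106, 715, 780, 278, 466),
  gp_only = c(197, 127, 298, 272, 180, 210),
  unannotated = c(541, 1245, 2257, 4537, 1083, 2817),
  total = c(1370, 1957, 4549, 7181, 2131, 4526))

# Synthesize protein-id sets whose 7 disjoint regions have exactly the
# given sizes; the ids themselves are arbitrary.
reconstruct_coverage_sets <- function(row) {
  sizes <- c(row$all, row$gp_ss, row$ss_kegg, row$kegg_gp,
             row$gp_only, row$ss_only, row$kegg_only)
  # membership of each region in (GP, SS, KEGG)
  member <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1),
                  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ids <- split(sprintf("prot%05d", seq_len(sum(sizes))),
               rep(seq_along(sizes), sizes))
  sets <- lapply(1:3, function(s)
    unlist(ids[which(member[, s] == 1)], use.names = FALSE))
  names(sets) <- c("GP", "SS", "KEGG")
  sets
}
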