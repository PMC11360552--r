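ctgOne <- function(score = 0.9, L = 10000L,
                   region = IRanges::IRanges(1L, L)) {
  makeContigSet("c1", L, score, regions = list(region))
}

test_that("permissive gates: bit score, module/known-AMG, auxiliary score", {
  ctg <- ctgOne()
  g <- rbind(
    makeGene("aux4", "c1", 100, 400, bit = 100, aux = 4L,
             modules = "M0001"),
    makeGene("bit59", "c1", 500, 900, bit = 59, aux = 1L,
             modules = "M0001"),
    makeGene("edge", "c1", 1000, 1400, bit = 60, aux = 3L, known = TRUE),
    makeGene("nosig", "c1", 1500, 1900, bit = 100, aux = 1L))
  cat <- callPermissive(g, ctg)
  expect_equal(amgCandidates(cat)$gene_id, "edge")
})

test_that("genes referencing unknown contigs are an error", {
  g <- makeGene("g1", "ghost", 1, 300, modules = "M0001")
  expect_error(callPermissive(g, ctgOne()), "unknown contig")
})

test_that("R1 keeps viral-region genes or confident contigs only", {
  region <- IRanges::IRanges(4000L, 7000L)
  low <- makeContigSet("c1", 10000L, 0.80, regions = list(region))
  g_out <- makeGene("outside", "c1", 1000, 1500, modules = "M0001")
  g_in <- makeGene("inside", "c1", 4500, 5000, modules = "M0001")
  cat <- applyConservativeRules(
    callPermissive(rbind(g_out, g_in), low), low, rbind(g_out, g_in))
  cons <- conservativeSet(cat)$gene_id
  expect_equal(cons, "inside")
  dec <- as.data.frame(amgDecisions(cat))
  expect_equal(dec$outcome[dec$gene_id == "outside" &
                             dec$rule_id == "R1_virus_region"], "fail")

  # inside a CheckV region on a low-score contig is enough
  low2 <- makeContigSet("c1", 10000L, 0.60, regions = list(region))
  cat2 <- applyConservativeRules(callPermissive(g_in, low2), low2, g_in)
  expect_equal(conservativeSet(cat2)$gene_id, "inside")

  # confident score rescues an outside gene
  hi <- makeContigSet("c1", 10000L, 0.96, regions = list(region))
  cat3 <- applyConservativeRules(callPermissive(g_out, hi), hi, g_out)
  expect_equal(conservativeSet(cat3)$gene_id, "outside")
})

test_that("R3 drops every candidate on a blacklist-carrying contig", {
  ctg <- ctgOne(score = 0.99)
  amgs <- rbind(
    makeGene("a1", "c1", 1000, 1500, modules = "M0001"),
    makeGene("a2", "c1", 2000, 2500, modules = "M0001"),
    makeGene("a3", "c1", 3000, 3500, modules = "M0001"))
  tnp <- makeGene("tnp", "c1", 6000, 6500, flags = "transposase")
  cat <- applyConservativeRules(callPermissive(amgs, ctg), ctg,
                                rbind(amgs, tnp))
  expect_equal(nrow(conservativeSet(cat)), 0)
  dec <- as.data.frame(amgDecisions(cat))
  r3 <- dec[dec$rule_id == "R3_blacklist", ]
  expect_true(all(r3$outcome == "fail"))
})

test_that("R2 confines candidates to the inferred phage interval", {
  ctg <- ctgOne(score = 0.99)
  g_in <- makeGene("in", "c1", 3000, 3500, modules = "M0001")
  g_out <- makeGene("out", "c1", 200, 700, modules = "M0001")
  ends <- list(c1 = list(contig_id = "c1",
                         evidence = data.frame(),
                         inferred_interval = c(2000, 8000)))
  cat <- applyConservativeRules(callPermissive(rbind(g_in, g_out), ctg),
                                ctg, rbind(g_in, g_out), ends = ends)
  expect_equal(conservativeSet(cat)$gene_id, "in")
  # R2 can be switched off
  cat2 <- applyConservativeRules(callPermissive(rbind(g_in, g_out), ctg),
                                 ctg, rbind(g_in, g_out), ends = ends,
                                 use_phage_ends = FALSE)
  expect_setequal(conservativeSet(cat2)$gene_id, c("in", "out"))
})

test_that("conservative tier is a subset with a complete decision trail", {
  for (seed in c(3L, 17L)) {
    sim <- generateSurveyContigs(amgSimParams(n_contigs = 50L, seed = seed))
    sc <- screenContigs(sim$contigs)
    genes <- sim$genes[sim$genes$contig_id %in% contigIds(sc), ]
    perm <- callPermissive(genes, sc)
    ends <- detectPhageEndsSet(sc, sim$trna)
    cat <- applyConservativeRules(perm, sc, genes, ends)
    cons <- conservativeSet(cat)$gene_id
    expect_true(all(cons %in% amgCandidates(perm)$gene_id))
    dec <- as.data.frame(amgDecisions(cat))
    for (rule in c("R1_virus_region", "R2_phage_ends", "R3_blacklist")) {
      expect_setequal(dec$gene_id[dec$rule_id == rule],
                      amgCandidates(cat)$gene_id)
    }
  }
})

test_that("catalog summaries follow the survey arithmetic", {
  bk <- bookkeepingChain(86913, 51666, 579904, factor = 2.1,
                         n_previous = 488130)
  expect_equal(round(bk$mean_per_carrier, 1), 1.7)
  expect_equal(round(100 * bk$observed_fraction), 9)
  expect_equal(round(100 * bk$growth_fraction), 16)

  # zero candidates: all counts zero
  ctg <- ctgOne()
  empty <- callPermissive(makeGene("g", "c1", 1, 300, bit = 10), ctg)
  pops <- clusterPopulations(data.frame(contig_id = "c1", length = 10000),
                             NULL)
  s <- catalogSummary(empty, pops)
  expect_equal(s$n_amgs, 0)
  expect_equal(s$observed_fraction, 0)
})
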