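test_that("parameter validation rejects degenerate settings", {
  expect_error(amgSimParams(genome_length_range = c(5000L, 1000L)),
               "degenerate")
  expect_error(amgSimParams(p_amg_genome = 1.2), "probability")
  expect_error(amgSimParams(n_samples = 3L), "paired")
})

test_that("zero genomes give an empty community", {
  com <- generateReferenceGenomes(amgSimParams(n_genomes = 0L, seed = 1L))
  expect_length(genomeSequences(com), 0)
  expect_equal(nrow(genomePopulations(com)), 0)
})

test_that("per-genome AMG bookkeeping is recomputable from the gene table", {
  params <- amgSimParams(n_genomes = 81L, p_amg_genome = 0.86,
                         amg_count_mean = 11.1, amg_count_max = 25L,
                         seed = 7L)
  com <- generateReferenceGenomes(params)
  genes <- as.data.frame(genomeGenes(com))
  recount <- tapply(genes$is_amg, genes$genome_id, sum)
  claimed <- S4Vectors::metadata(com)$amg_counts
  expect_equal(unname(recount[names(claimed)]), unname(claimed),
               ignore_attr = TRUE)
  carriers <- claimed[claimed > 0]
  expect_lte(max(carriers), 25)
  # realized carrier fraction and mean track the configured distribution
  expect_gt(mean(claimed > 0), 0.86 - 0.15)
  expect_lt(abs(mean(carriers) - 11.1), 2.5)
})

test_that("gene intervals stay inside their genome", {
  com <- generateReferenceGenomes(amgSimParams(n_genomes = 10L, seed = 2L))
  genes <- as.data.frame(genomeGenes(com))
  lens <- stats::setNames(Biostrings::width(genomeSequences(com)),
                          names(genomeSequences(com)))
  expect_true(all(genes$start >= 1))
  expect_true(all(genes$end <= lens[genes$genome_id]))
  expect_true(all(genes$start <= genes$end))
})

test_that("survey generation is seed-deterministic, byte for byte", {
  params <- amgSimParams(n_contigs = 25L, seed = 13L)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  writeSimulatedSurvey(generateSurveyContigs(params), d1)
  writeSimulatedSurvey(generateSurveyContigs(params), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("prophage probability zero means no cellular flanks in truth", {
  sim <- generateSurveyContigs(amgSimParams(n_contigs = 40L,
                                            p_prophage_contig = 0,
                                            seed = 4L))
  expect_false(any(sim$truth$genes$label == "cellular_flank"))
  expect_false(any(sim$truth$contigs$kind == "prophage"))
})

test_that("planted flank AMGs and boundary marks appear when prophages do", {
  sim <- generateSurveyContigs(amgSimParams(n_contigs = 60L,
                                            p_prophage_contig = 0.3,
                                            seed = 5L))
  tc <- sim$truth$contigs
  pro <- tc[tc$kind == "prophage", ]
  expect_gt(nrow(pro), 0)
  expect_true(all(pro$contig_id %in% sim$trna$contig_id))
  expect_gt(sum(sim$truth$genes$label == "cellular_flank"), 0)
  # the planted repeat arms are exact copies at the region boundaries
  seqs <- contigSequences(sim$contigs)
  for (r in seq_len(nrow(pro))) {
    s <- as.character(seqs[[pro$contig_id[r]]])
    arm <- 25L
    left <- substr(s, pro$region_start[r], pro$region_start[r] + arm - 1L)
    right <- substr(s, pro$region_end[r] - arm + 1L, pro$region_end[r])
    expect_true(right == left || right == revcompChr(left),
                label = pro$contig_id[r])
  }
})

test_that("depth profiles honor breadth, zero depth and noiseless modes", {
  lens <- c(cA = 10000L)
  dp <- generateDepthProfiles(lens, "s1", depth_mean = 8, breadth = 0.5,
                              seed = 3L)
  v <- as.numeric(depthProfiles(dp)[["cA|s1"]])
  expect_lt(abs(mean(v > 0) - 0.5), 0.02)

  dp0 <- generateDepthProfiles(lens, "s1", depth_mean = 0, seed = 3L)
  expect_true(all(as.numeric(depthProfiles(dp0)[["cA|s1"]]) == 0))

  dpc <- generateDepthProfiles(lens, "s1", depth_mean = 6, breadth = 1,
                               noise = "none", seed = 3L)
  expect_true(all(as.numeric(depthProfiles(dpc)[["cA|s1"]]) == 6))
})
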