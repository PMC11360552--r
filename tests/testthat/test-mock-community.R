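test_that("a genome exactly at the lower bound stays as one kept fragment", {
  com <- makeCommunity(
    lengths = 10000L,
    amg_coords = list(data.frame(start = 2000L, end = 2900L)))
  survey <- rep(c(10000, 12000, 15000), each = 10)  # p10 = 10000 exactly
  fs <- fragmentGenomes(com, survey, seed = 1L)
  expect_equal(fragmentBounds(fs)[["p10"]], 10000)
  ft <- as.data.frame(fragmentTable(fs))
  expect_equal(nrow(ft), 1)
  expect_equal(ft$n_amgs, 1L)
  expect_length(excludedPopulations(fs), 0)
})

test_that("tiling conserves genome length and is reproducible", {
  com <- generateReferenceGenomes(amgSimParams(n_genomes = 15L, seed = 8L))
  set.seed(1); survey <- round(rlnorm(200, log(12608), 0.45))
  fs1 <- fragmentGenomes(com, survey, seed = 5L)
  fs2 <- fragmentGenomes(com, survey, seed = 5L)
  expect_identical(as.data.frame(fragmentTable(fs1)),
                   as.data.frame(fragmentTable(fs2)))
  ft <- as.data.frame(fragmentTable(fs1))
  lens <- stats::setNames(Biostrings::width(genomeSequences(com)),
                          names(genomeSequences(com)))
  for (g in unique(ft$genome_id)) {
    expect_equal(sum(ft$length[ft$genome_id == g]), unname(lens[g]))
    expect_true(all(diff(ft$start[ft$genome_id == g]) > 0))
  }
  # AMG containment never exceeds the genome's AMG count
  genes <- as.data.frame(genomeGenes(com))
  for (g in unique(ft$genome_id)) {
    expect_lte(sum(ft$n_amgs[ft$genome_id == g]),
               sum(genes$is_amg[genes$genome_id == g]))
  }
})

test_that("an AMG straddling a fragment boundary counts in neither", {
  com <- makeCommunity(
    lengths = 20000L,
    amg_coords = list(data.frame(start = 9950L, end = 10850L)))
  survey <- rep(10000, 50)                 # forces cuts at 10000
  fs <- fragmentGenomes(com, survey, seed = 1L)
  ft <- as.data.frame(fragmentTable(fs))
  expect_equal(nrow(ft), 2)
  expect_equal(sum(ft$n_amgs), 0L)
})

test_that("genomes below the lower bound exclude their population", {
  com <- makeCommunity(
    lengths = c(3000L, 20000L),
    amg_coords = list(NULL, data.frame(start = 100L, end = 1000L)))
  survey <- rep(c(8000, 10000, 12000), each = 10)
  expect_message(fs <- fragmentGenomes(com, survey, seed = 2L), "excluded")
  expect_equal(excludedPopulations(fs), "pop01")
  expect_false("g01" %in% fragmentTable(fs)$genome_id)
})

test_that("self-matching resampling keeps the source distribution", {
  com <- generateReferenceGenomes(amgSimParams(n_genomes = 20L, seed = 4L))
  set.seed(2); survey <- round(rlnorm(200, log(12608), 0.45))
  fs <- fragmentGenomes(com, survey, seed = 3L)
  ft <- as.data.frame(fragmentTable(fs))
  rs <- resampleFragments(fs, target_lengths = ft$length, n = 5000L,
                          seed = 9L)
  # uniform weights: each fragment's share close to 1/n_fragments
  counts <- table(factor(rs$fragment_id, levels = ft$fragment_id))
  expect_lt(max(abs(counts / 5000 - 1 / nrow(ft))),
            4 * sqrt(1 / nrow(ft) / 5000) + 1 / nrow(ft) * 0.5)
})

test_that("a two-bin toy resample hits the 80/20 target within 3 sigma", {
  com <- makeCommunity(
    lengths = c(11000L, 11000L),   # not used by the resampler directly
    amg_coords = list(NULL, NULL))
  frags <- S4Vectors::DataFrame(
    fragment_id = sprintf("f%02d", 1:20),
    genome_id = "g01", population_id = "pop01",
    start = 1L, end = 1L,
    length = rep(c(5500L, 8500L), each = 10),  # bins 5 and 8, 50/50
    n_amgs = 0L)
  fs <- new("FragmentSet", fragments = frags, p10 = 5000, p90 = 9000,
            excluded = character(0))
  target <- c(rep(5500, 800), rep(8500, 200))  # 80/20 target
  rs <- resampleFragments(fs, target, n = 10000L, seed = 13L)
  p_hat <- mean(rs$length == 5500)
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
})

test_that("disjoint source and target length distributions error out", {
  frags <- S4Vectors::DataFrame(
    fragment_id = "f1", genome_id = "g01", population_id = "pop01",
    start = 1L, end = 1L, length = 5500L, n_amgs = 0L)
  fs <- new("FragmentSet", fragments = frags, p10 = 5000, p90 = 9000,
            excluded = character(0))
  expect_error(resampleFragments(fs, rep(20000, 10), n = 100L, seed = 1L),
               "disjoint")
})

test_that("saturated AMG coverage gives a conversion factor of one", {
  amg_everywhere <- data.frame(start = seq(500L, 19000L, by = 1500L))
  amg_everywhere$end <- amg_everywhere$start + 400L
  com <- makeCommunity(lengths = rep(20000L, 3),
                       amg_coords = rep(list(amg_everywhere), 3))
  survey <- rep(c(9000, 10000, 11000), each = 20)
  fs <- fragmentGenomes(com, survey, seed = 2L)
  rs <- resampleFragments(fs, survey, n = 500L, seed = 3L)
  ce <- estimateConversionFactor(com, fs, rs)
  expect_equal(trueFraction(ce), 1)
  expect_equal(observedFraction(ce), 1)
  expect_equal(conversionFactor(ce), 1)
})

test_that("fragmentation can only hide AMGs, never invent them", {
  for (seed in c(2L, 9L, 31L)) {
    com <- generateReferenceGenomes(amgSimParams(n_genomes = 25L,
                                                 seed = seed))
    set.seed(seed); survey <- round(rlnorm(200, log(12608), 0.45))
    fs <- fragmentGenomes(com, survey, seed = seed)
    rs <- resampleFragments(fs, survey, n = 1000L, seed = seed + 1L)
    ce <- estimateConversionFactor(com, fs, rs)
    expect_lte(observedFraction(ce), trueFraction(ce) + 1e-12)
    expect_gte(conversionFactor(ce), 1)
  }
})

test_that("the survey correction chain reproduces the printed fractions", {
  expect_equal(applyConversion(1, 1.5), 1)       # capped at one
  expect_equal(applyConversion(0.3, 1), 0.3)     # identity factor
  expect_equal(round(100 * applyConversion(51666 / 579904, 2.1), 1), 18.7)
  expect_equal(round(100 * applyConversion(0.18, 2.1), 1), 37.8)
  expect_error(applyConversion(1.2, 2), "probability")
})
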