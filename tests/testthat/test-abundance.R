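test_that("read filters drop low-identity and low-coverage alignments", {
  aln <- data.frame(
    contig_id = "c1", sample_id = "s1",
    tstart = c(1, 101, 201), tend = c(100, 200, 300),
    identity = c(0.94, 0.95, 0.99),
    read_cov = c(0.9, 0.74, 0.8))
  dp <- filterAlignments(aln, c(c1 = 300L), c(s1 = 1e9))
  v <- as.numeric(depthProfiles(dp)[["c1|s1"]])
  expect_equal(sum(v[1:100]), 0)      # identity 0.94 dropped
  expect_equal(sum(v[101:200]), 0)    # read coverage 0.74 dropped
  expect_true(all(v[201:300] == 1))
})

test_that("perfect full-length reads reproduce the interval-stacking oracle", {
  set.seed(4)
  L <- 500L
  n <- 60
  starts <- sample(1:(L - 80), n, replace = TRUE)
  aln <- data.frame(contig_id = "c1", sample_id = "s1",
                    tstart = starts, tend = starts + 79L,
                    identity = 1, read_cov = 1)
  dp <- filterAlignments(aln, c(c1 = L), c(s1 = 1e9))
  v <- as.numeric(depthProfiles(dp)[["c1|s1"]])
  oracle <- integer(L)
  for (i in seq_len(n)) {
    idx <- starts[i]:(starts[i] + 79L)
    oracle[idx] <- oracle[idx] + 1L
  }
  expect_equal(v, as.numeric(oracle))
})

test_that("invalid identities are rejected", {
  aln <- data.frame(contig_id = "c1", sample_id = "s1", tstart = 1,
                    tend = 10, identity = 1.2, read_cov = 1)
  expect_error(filterAlignments(aln, c(c1 = 100L), c(s1 = 1e9)),
               "identity")
})

test_that("trimmed mean honors breadth gate, trimming and scaling", {
  expect_equal(trimmedMeanAbundance(rep(10, 100), 1e9), 10)
  v69 <- c(rep(0, 31), rep(8, 69))
  expect_equal(trimmedMeanAbundance(v69, 1e9), 0)   # breadth 0.69 < 0.70
  v70 <- c(rep(0, 30), rep(8, 70))
  expect_gt(trimmedMeanAbundance(v70, 1e9), 0)

  set.seed(2)
  v <- c(rpois(90, 20), rep(0, 2), rep(500, 8))   # planted extreme tails
  expect_equal(trimmedMeanAbundance(v, 1e9),
               oracleTrimmedMean(v, 1e9))
  expect_error(trimmedMeanAbundance(numeric(0), 1e9), "empty")
})

test_that("trimmed mean is scale-equivariant and bounded", {
  set.seed(6)
  for (r in 1:10) {
    v <- rpois(200, sample(3:30, 1))
    a1 <- trimmedMeanAbundance(v, 1e9)
    a2 <- trimmedMeanAbundance(v * 7, 7e9)
    expect_equal(a1, a2)
    raw <- trimmedMeanAbundance(v, 1e9) / 1e9 * 1e9
    if (mean(v > 0) >= 0.7) {
      expect_gte(raw, min(v))
      expect_lte(raw, max(v))
    }
  }
  # short vectors are not trimmed at all
  expect_equal(trimmedMeanAbundance(c(1, 100, rep(10, 13)), 1e9),
               mean(c(1, 100, rep(10, 13))))
})

makeAbundanceFixture <- function(depths_by_sample, L = 1000L) {
  pops <- new("VirusPopulations", membership = S4Vectors::DataFrame(
    population_id = "vOTU_00001", representative = "c1",
    member = "c1", rep_length = L))
  profs <- lapply(depths_by_sample, function(d) S4Vectors::Rle(d, L))
  dl <- methods::as(S4Vectors::SimpleList(profs), "RleList")
  names(dl) <- paste("c1", names(depths_by_sample), sep = "|")
  dp <- new("DepthProfileSet", depths = dl, info = S4Vectors::DataFrame(
    contig_id = "c1", sample_id = names(depths_by_sample),
    total_reads = 1e9))
  list(pops = pops, dp = dp)
}

test_that("paired-sample abundances add the two fractions", {
  fx <- makeAbundanceFixture(list(sv = 6, sp = 0))   # virus fraction only
  pairing <- data.frame(sample_id = c("sv", "sp"), pair_id = "st1")
  m <- populationAbundance(fx$pops, fx$dp, pairing)
  expect_equal(unname(m["vOTU_00001", "st1"]), 6)

  fx2 <- makeAbundanceFixture(list(sv = 6, sp = 4))
  m2 <- populationAbundance(fx2$pops, fx2$dp, pairing)
  expect_equal(unname(m2["vOTU_00001", "st1"]), 10)
})

test_that("breadth failure in both fractions zeroes the paired abundance", {
  thin <- c(rep(0, 500), rep(5, 500))   # breadth 0.5
  fx <- makeAbundanceFixture(list(sv = 5, sp = 5))
  fx$dp@depths[[1]] <- S4Vectors::Rle(thin)
  fx$dp@depths[[2]] <- S4Vectors::Rle(thin)
  pairing <- data.frame(sample_id = c("sv", "sp"), pair_id = "st1")
  m <- populationAbundance(fx$pops, fx$dp, pairing)
  expect_equal(unname(m["vOTU_00001", "st1"]), 0)
})

test_that("ko enrichment folds, statuses and omissions behave", {
  pops <- new("VirusPopulations", membership = S4Vectors::DataFrame(
    population_id = c("p1", "p2"), representative = c("c1", "c2"),
    member = c("c1", "c2"), rep_length = c(1000L, 1000L)))
  cand <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2"), contig_id = c("c1", "c2"),
    start = 1L, end = 300L, strand = "+", bit_score = 100,
    auxiliary_score = 1L, ko = c("K10011", "K99999"),
    module_ids = NA_character_, known_amg = FALSE,
    tier = c("conservative", "conservative"))
  cat <- new("AmgCatalog", candidates = cand,
             decisions = S4Vectors::DataFrame(gene_id = character(0),
                                              rule_id = character(0),
                                              outcome = character(0),
                                              reason = character(0)))
  pa <- matrix(c(2.2, 3.0), nrow = 2,
               dimnames = list(c("p1", "p2"), "st1"))
  mk <- c(K10011 = 1.0, K00000 = 0)
  expect_message(enr <- koEnrichment(cat, pops, pa, mk), "omitted")
  r1 <- enr[enr$ko == "K10011", ]
  expect_equal(r1$fold, 2.2)
  expect_true(r1$enriched)
  r2 <- enr[enr$ko == "K99999", ]
  expect_equal(r2$status, "microbe-absent")
  expect_true(is.na(r2$fold))
  expect_false("K00000" %in% enr$ko)

  # a KO with no viral signal has fold 0 and is not enriched
  mk2 <- c(K10011 = 1.0, K55555 = 3.0)
  enr2 <- koEnrichment(cat, pops, pa, mk2)
  r3 <- enr2[enr2$ko == "K55555", ]
  expect_equal(r3$fold, 0)
  expect_false(r3$enriched)
})
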