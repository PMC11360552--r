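test_that("identical contigs form one population, near-misses stay apart", {
  tab <- data.frame(contig_id = c("a", "b"), length = c(9000, 9000))
  one <- clusterPopulations(tab, data.frame(a = "a", b = "b",
                                            ani = 100, af = 1))
  expect_equal(nPopulations(one), 1)
  expect_equal(sort(populationMembership(one)$member), c("a", "b"))

  two <- clusterPopulations(tab, data.frame(a = "a", b = "b",
                                            ani = 94.9, af = 0.85))
  expect_equal(nPopulations(two), 2)
})

test_that("representative is the longest member, ties by smallest id", {
  tab <- data.frame(contig_id = c("zzz", "aaa", "mmm"),
                    length = c(8000, 8000, 7000))
  sims <- data.frame(a = c("zzz", "aaa"), b = c("aaa", "mmm"),
                     ani = c(99, 99), af = c(0.9, 0.9))
  pops <- clusterPopulations(tab, sims)
  m <- as.data.frame(populationMembership(pops))
  expect_true(all(m$representative == "aaa"))
  expect_equal(unique(m$rep_length), 8000)
})

test_that("contradictory duplicate similarity rows raise an error", {
  tab <- data.frame(contig_id = c("a", "b"), length = c(9000, 8000))
  sims <- data.frame(a = c("a", "b"), b = c("b", "a"),
                     ani = c(99, 96), af = c(0.9, 0.9))
  expect_error(clusterPopulations(tab, sims), "contradictory")
})

test_that("a 12-contig partition matches the greedy brute-force oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    tab <- data.frame(contig_id = sprintf("c%02d", 1:n),
                      length = sample(5000:20000, n))
    pr <- t(combn(tab$contig_id, 2))
    sims <- data.frame(a = pr[, 1], b = pr[, 2],
                       ani = round(runif(nrow(pr), 85, 100), 2),
                       af = round(runif(nrow(pr), 0.5, 1), 3))
    got <- as.data.frame(populationMembership(
      clusterPopulations(tab, sims)))
    want <- oraclePopulationPartition(tab, sims, 95, 0.80)
    expect_equal(stats::setNames(got$representative, got$member)[names(want)],
                 want)
  }
})

test_that("the partition covers all contigs and ignores input order", {
  set.seed(8)
  n <- 15
  tab <- data.frame(contig_id = sprintf("c%02d", 1:n),
                    length = sample(5000:20000, n))
  pr <- t(combn(tab$contig_id, 2))
  sims <- data.frame(a = pr[, 1], b = pr[, 2],
                     ani = round(runif(nrow(pr), 90, 100), 2),
                     af = round(runif(nrow(pr), 0.7, 1), 3))
  p1 <- as.data.frame(populationMembership(clusterPopulations(tab, sims)))
  shuffle <- sample(n)
  p2 <- as.data.frame(populationMembership(
    clusterPopulations(tab[shuffle, ], sims[sample(nrow(sims)), ])))
  expect_setequal(p1$member, tab$contig_id)
  expect_equal(anyDuplicated(p1$member), 0)
  m1 <- stats::setNames(p1$representative, p1$member)
  m2 <- stats::setNames(p2$representative, p2$member)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("raising thresholds never decreases the population count", {
  set.seed(77)
  n <- 14
  tab <- data.frame(contig_id = sprintf("c%02d", 1:n),
                    length = sample(5000:20000, n))
  pr <- t(combn(tab$contig_id, 2))
  sims <- data.frame(a = pr[, 1], b = pr[, 2],
                     ani = round(runif(nrow(pr), 85, 100), 2),
                     af = round(runif(nrow(pr), 0.5, 1), 3))
  counts_ani <- vapply(c(90, 93, 95, 97, 99), function(th) {
    nPopulations(clusterPopulations(tab, sims, min_ani = th))
  }, numeric(1))
  expect_true(all(diff(counts_ani) >= 0))
  counts_af <- vapply(c(0.6, 0.7, 0.8, 0.9), function(th) {
    nPopulations(clusterPopulations(tab, sims, min_af = th))
  }, numeric(1))
  expect_true(all(diff(counts_af) >= 0))
})
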