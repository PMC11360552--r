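test_that("identical sequences share a cluster; unrelated ones do not", {
  base <- randDna(600, seed = 3)
  s <- c(a = base, b = base, c = randDna(500))
  m <- as.data.frame(clusterMembership(greedyCluster(s, 0.9, 0.8)))
  expect_equal(m$cluster_id[m$member == "a"], m$cluster_id[m$member == "b"])
  expect_false(m$cluster_id[m$member == "c"] == m$cluster_id[m$member == "a"])
})

test_that("mixed alphabets are rejected", {
  expect_error(greedyCluster(c(x = "ACGTACGTACGT", y = "MKTAYIAKQRQISF"),
                             0.9, 0.8),
               "mixed")
})

test_that("dissimilar proteins below the identity floor stay apart", {
  set.seed(9)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  p1 <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  p2 <- paste(sample(aa, 120, replace = TRUE), collapse = "")
  m <- as.data.frame(clusterMembership(
    greedyCluster(c(a = p1, b = p2), 0.30, 0.60)))
  expect_equal(length(unique(m$cluster_id)), 2)
})

test_that("15 planted nucleotide sequences match the brute-force oracle", {
  set.seed(41)
  fams <- lapply(1:5, function(i) randDna(sample(150:260, 1)))
  seqs <- character(0)
  for (i in seq_along(fams)) {
    k <- sample(2:4, 1)
    for (j in seq_len(k)) {
      s <- fams[[i]]
      chars <- strsplit(s, "")[[1]]
      hit <- which(runif(length(chars)) < 0.03)
      chars[hit] <- sample(c("A", "C", "G", "T"), length(hit),
                           replace = TRUE)
      seqs[sprintf("f%d_%d", i, j)] <- paste(chars, collapse = "")
    }
  }
  seqs <- seqs[1:min(15, length(seqs))]
  got <- as.data.frame(clusterMembership(greedyCluster(seqs, 0.9, 0.8)))
  want <- oracleGreedyCluster(seqs, 0.9, 0.8)
  got_map <- stats::setNames(got$representative, got$member)
  expect_equal(got_map[names(want)], want)
})

test_that("protein co-clustering at the novelty thresholds matches the oracle", {
  set.seed(55)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  fams <- lapply(1:4, function(i)
    paste(sample(aa, sample(80:140, 1), replace = TRUE), collapse = ""))
  seqs <- character(0)
  for (i in seq_along(fams)) {
    for (j in 1:3) {
      ch <- strsplit(fams[[i]], "")[[1]]
      hit <- which(runif(length(ch)) < 0.25)
      ch[hit] <- sample(aa, length(hit), replace = TRUE)
      seqs[sprintf("p%d_%d", i, j)] <- paste(ch, collapse = "")
    }
  }
  got <- as.data.frame(clusterMembership(greedyCluster(seqs, 0.30, 0.60)))
  want <- oracleGreedyCluster(seqs, 0.30, 0.60)
  got_map <- stats::setNames(got$representative, got$member)
  expect_equal(got_map[names(want)], want)
})

test_that("raising the identity floor never merges separate clusters", {
  set.seed(12)
  seqs <- stats::setNames(
    vapply(1:10, function(i) randDna(sample(150:250, 1)), character(1)),
    sprintf("s%02d", 1:10))
  # add related copies so some thresholds actually merge
  seqs["s01b"] <- chartr("A", "C", seqs[["s01"]])
  seqs["s02b"] <- seqs[["s02"]]
  counts <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th) {
    length(unique(clusterMembership(
      greedyCluster(seqs, th, 0.6))$cluster_id))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("novelty calls follow reference membership exactly", {
  base <- c(cat1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA",
            cat2 = "MLLLWWRRKKAAYYTTPPQQGGHHSSVVNNDDEE",
            cat3 = "MPPPFFFNNNCCCQQQEEEHHHIIIKKKLLLMMM")
  refs <- c(ref1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA")
  nv <- assessNovelty(base, refs)
  tab <- nv$clusters
  expect_false(tab$novel[tab$representative == "cat1"])
  expect_equal(nv$n_novel, 2)
  expect_equal(nv$n_total, 3)

  expect_warning(nv2 <- assessNovelty(base, character(0)), "novel")
  expect_equal(nv2$n_novel, nv2$n_total)

  expect_error(assessNovelty(base, c(cat1 = "MKT")), "overlap")
})

test_that("k planted reference-free families give exactly k novel clusters", {
  set.seed(66)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  mkfam <- function() paste(sample(aa, 100, replace = TRUE), collapse = "")
  shared <- replicate(3, mkfam())
  free <- replicate(2, mkfam())      # k = 2 reference-free families
  cat_seqs <- stats::setNames(c(shared, free), sprintf("c%d", 1:5))
  ref_seqs <- stats::setNames(shared, sprintf("r%d", 1:3))
  nv <- assessNovelty(cat_seqs, ref_seqs)
  expect_equal(nv$n_novel, 2)
  expect_equal(nv$n_total, 5)
})
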