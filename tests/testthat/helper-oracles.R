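# Independent oracles: hand-rolled dynamic-programming alignment, O(n^2)
# repeat scans, truth-table module evaluators, and sort-and-slice trimmed
# means. These deliberately share no code with the package internals.

# Smith-Waterman local alignment (match 1, mismatch -1, gap -2), traceback
# for identity (matches / alignment columns) and member coverage.
oracleLocalAlign <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (x[i] == y[j]) 1 else -1
      H[i + 1L, j + 1L] <- max(0, H[i, j] + sc,
                               H[i, j + 1L] - 2, H[i + 1L, j] - 2)
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1L, ]
  i <- best[1] - 1L; j <- best[2] - 1L
  if (max(H) == 0)
    return(list(identity = 0, cov_member = 0, cov_rep = 0))
  matches <- 0L; cols <- 0L
  i_end <- i; j_end <- j
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    sc <- if (x[i] == y[j]) 1 else -1
    if (H[i + 1L, j + 1L] == H[i, j] + sc) {
      matches <- matches + (x[i] == y[j])
      cols <- cols + 1L
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L] - 2) {
      cols <- cols + 1L
      i <- i - 1L
    } else {
      cols <- cols + 1L
      j <- j - 1L
    }
  }
  list(identity = matches / cols,
       cov_member = (i_end - i) / n,
       cov_rep = (j_end - j) / m)
}

# greedy longest-first clustering driven by the oracle aligner
oracleGreedyCluster <- function(seqs, min_id, min_cov) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  assign <- stats::setNames(character(length(seqs)), ids)
  for (i in ord) {
    joined <- NA_character_
    for (r in reps) {
      st <- oracleLocalAlign(seqs[[i]], seqs[[r]])
      if (st$identity >= min_id && st$cov_member >= min_cov) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, ids[i])
      assign[ids[i]] <- ids[i]
    } else assign[ids[i]] <- joined
  }
  assign
}

# greedy longest-first population assignment from a similarity lookup
oraclePopulationPartition <- function(tab, sims, min_ani, min_af) {
  lookup <- function(x, y) {
    hit <- (sims$a == x & sims$b == y) | (sims$a == y & sims$b == x)
    if (!any(hit)) return(NULL)
    c(sims$ani[which(hit)[1]], sims$af[which(hit)[1]])
  }
  ord <- order(-tab$length, tab$contig_id)
  reps <- character(0)
  assign <- stats::setNames(character(nrow(tab)), tab$contig_id[ord])
  for (id in tab$contig_id[ord]) {
    joined <- NA_character_
    for (r in reps) {
      v <- lookup(id, r)
      if (!is.null(v) && v[1] >= min_ani && v[2] >= min_af) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, id)
      assign[id] <- id
    } else assign[id] <- joined
  }
  assign
}

# O(n^2) exact repeat scan: runs of character equality at every offset
# (direct: s vs s; inverted: s vs reverse complement), maximal runs of
# length >= min_arm, overlapping-arm candidates dropped.
oracleExactRepeats <- function(s, min_arm) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  out <- list()
  runsAt <- function(eq) {
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_arm
    cbind(start = starts[keep], len = r$lengths[keep])
  }
  for (d in seq_len(L - min_arm)) {
    eq <- chars[seq_len(L - d)] == chars[seq_len(L - d) + d]
    runs <- runsAt(eq)
    if (nrow(runs)) {
      for (r in seq_len(nrow(runs))) {
        s1 <- runs[r, "start"]; len <- runs[r, "len"]
        s2 <- s1 + d
        if (s1 + len - 1L >= s2) next  # overlapping arms
        out[[length(out) + 1L]] <- data.frame(
          kind = "direct_repeat", s1 = s1, e1 = s1 + len - 1L,
          s2 = s2, e2 = s2 + len - 1L)
      }
    }
  }
  rcc <- strsplit(revcompChr(s), "")[[1]]
  for (c0 in (-(L - min_arm)):(L - min_arm)) {
    if (c0 >= 0) {
      i_idx <- (1L + c0):L
      j_idx <- seq_along(i_idx)
    } else {
      j_idx <- (1L - c0):L
      i_idx <- seq_along(j_idx)
    }
    if (length(i_idx) < min_arm) next
    eq <- chars[i_idx] == rcc[j_idx]
    runs <- runsAt(eq)
    if (nrow(runs)) {
      for (r in seq_len(nrow(runs))) {
        i0 <- i_idx[runs[r, "start"]]
        j0 <- j_idx[runs[r, "start"]]
        len <- runs[r, "len"]
        a1 <- c(i0, i0 + len - 1L)
        a2 <- c(L - (j0 + len - 1L) + 1L, L - j0 + 1L)
        if (a1[1] > a2[1]) next       # mirrored duplicate
        if (a1[2] >= a2[1]) next      # self-overlap
        out[[length(out) + 1L]] <- data.frame(
          kind = "inverted_repeat", s1 = a1[1], e1 = a1[2],
          s2 = a2[1], e2 = a2[2])
      }
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), s1 = integer(0),
                      e1 = integer(0), s2 = integer(0), e2 = integer(0)))
  res <- unique(do.call(rbind, out))
  res[order(res$kind, res$s1, res$s2), , drop = FALSE]
}

# sort-and-slice trimmed-mean abundance
oracleTrimmedMean <- function(v, total_reads, trim = 0.05,
                              min_breadth = 0.70) {
  if (mean(v > 0) < min_breadth) return(0)
  k <- floor(trim * length(v))
  vs <- sort(v)
  if (k > 0) vs <- vs[(k + 1):(length(v) - k)]
  mean(vs) / total_reads * 1e9
}

# hand-written truth-table evaluators for the toy module set: per module,
# the vector of step satisfactions for a KO set
toyModuleOracle <- list(
  M0001 = function(k) c("K00001" %in% k, "K00002" %in% k,
                        "K00003" %in% k, "K00004" %in% k),
  M0002 = function(k) c(("K00005" %in% k) || ("K00006" %in% k),
                        ("K00007" %in% k) && ("K00008" %in% k)),
  M0003 = function(k) c("K00010" %in% k, "K00012" %in% k),
  M0004 = function(k) c("K00013" %in% k, "K00014" %in% k, FALSE,
                        "K00015" %in% k),
  M0005 = function(k) all(c("K00016", "K00017", "K00018") %in% k),
  M0006 = function(k) c((("K00020" %in% k) && ("K00021" %in% k)) ||
                          ("K00022" %in% k),
                        "K00023" %in% k),
  M0007 = function(k) c("K00024" %in% k,
                        any(c("K00025", "K00026", "K00027") %in% k)),
  M0008 = function(k) sprintf("K%05d", 30:35) %in% k,
  M0009 = function(k) any(c("K00040", "K00041") %in% k),
  M0010 = function(k) c("K00042" %in% k,
                        (("K00043" %in% k) && ("K00044" %in% k)) ||
                          ("K00045" %in% k))
)

toyModuleKos <- list(
  M0001 = sprintf("K%05d", 1:4),
  M0002 = sprintf("K%05d", 5:8),
  M0003 = sprintf("K%05d", 10:12),
  M0004 = sprintf("K%05d", 13:15),
  M0005 = sprintf("K%05d", 16:18),
  M0006 = sprintf("K%05d", 20:23),
  M0007 = sprintf("K%05d", 24:27),
  M0008 = sprintf("K%05d", 30:35),
  M0009 = sprintf("K%05d", 40:41),
  M0010 = sprintf("K%05d", 42:45)
)
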