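# Built-in whole-contig similarity estimator: exact k-mer anchors grouped
# into diagonal blocks, chained colinearly, with identity computed
# position-wise over the chained blocks. Intended for synthetic and
# desk-scale data; callers may instead supply a precomputed similarity
# table from an external aligner.

.kmerPositions <- function(seq, k, max_occ) {
  l <- nchar(seq)
  if (l < k) return(list())
  pos <- seq_len(l - k + 1L)
  km <- substring(seq, pos, pos + k - 1L)
  tab <- split(pos, km)
  tab[lengths(tab) <= max_occ]
}

# count matching characters between two equal-length strings
.charMatches <- function(x, y) sum(utf8ToInt(x) == utf8ToInt(y))

#' Estimate ANI and aligned fraction between two sequences
#'
#' Anchors exact `k`-mers shared between the sequences, merges anchors on a
#' common diagonal into gap-free blocks, chains blocks colinearly
#' (maximizing matched columns), and reports the average nucleotide identity
#' over the chained blocks together with the aligned fraction of the
#' shorter sequence.
#'
#' @param seq_a,seq_b nucleotide strings (or XString objects), non-empty.
#' @param k anchor k-mer size (default 15).
#' @param max_occ anchors from k-mers occurring more often than this in
#'   either sequence are ignored (repeat masking).
#' @return a list with `ani` (percent, 0-100), `af` (aligned fraction of the
#'   shorter sequence, 0-1), and `n_blocks`.
#' @examples
#' a <- paste(rep("ACGTTGCA", 40), collapse = "")
#' estimateSimilarity(a, a)$ani
#' @export
estimateSimilarity <- function(seq_a, seq_b, k = 15L, max_occ = 4L) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  la <- nchar(a); lb <- nchar(b)
  if (la < 1L || lb < 1L) stop("sequences must be non-empty")
  k <- min(k, la, lb)
  ta <- .kmerPositions(a, k, max_occ)
  tb <- .kmerPositions(b, k, max_occ)
  shared <- intersect(names(ta), names(tb))
  if (!length(shared)) return(list(ani = 0, af = 0, n_blocks = 0L))
  pa <- ta[shared]; pb <- tb[shared]
  ii <- unlist(mapply(function(x, y) rep(x, each = length(y)), pa, pb,
                      SIMPLIFY = FALSE), use.names = FALSE)
  jj <- unlist(mapply(function(x, y) rep(y, times = length(x)), pa, pb,
                      SIMPLIFY = FALSE), use.names = FALSE)
  d <- ii - jj
  blocks <- lapply(split(jj, d), function(js) {
    c(jmin = min(js), jmax = max(js) + k - 1L)
  })
  ds <- as.integer(names(blocks))
  bl <- data.frame(
    d = ds,
    j_start = vapply(blocks, `[[`, integer(1), "jmin"),
    j_end = vapply(blocks, `[[`, integer(1), "jmax"))
  bl$i_start <- bl$j_start + bl$d
  bl$i_end <- bl$j_end + bl$d
  bl$cols <- bl$j_end - bl$j_start + 1L
  bl$matches <- vapply(seq_len(nrow(bl)), function(r) {
    .charMatches(substr(a, bl$i_start[r], bl$i_end[r]),
                 substr(b, bl$j_start[r], bl$j_end[r]))
  }, numeric(1))
  # colinear chaining over blocks, maximizing matched columns
  bl <- bl[order(bl$j_start, bl$j_end), , drop = FALSE]
  nb <- nrow(bl)
  dp <- bl$matches
  cols <- bl$cols
  prev <- rep(NA_integer_, nb)
  if (nb > 1L) {
    for (r in 2:nb) {
      for (q in seq_len(r - 1L)) {
        if (bl$j_end[q] < bl$j_start[r] && bl$i_end[q] < bl$i_start[r] &&
            dp[q] + bl$matches[r] > dp[r]) {
          dp[r] <- dp[q] + bl$matches[r]
          cols[r] <- cols[q] + bl$cols[r]
          prev[r] <- q
        }
      }
    }
  }
  best <- which.max(dp)
  tot_matches <- dp[best]
  tot_cols <- cols[best]
  n_blocks <- 0L
  r <- best
  while (!is.na(r)) { n_blocks <- n_blocks + 1L; r <- prev[r] }
  list(ani = 100 * tot_matches / tot_cols,
       af = min(1, tot_cols / min(la, lb)),
       n_blocks = n_blocks)
}

#' All-versus-all similarity table with a k-mer prefilter
#'
#' Builds candidate pairs by hashing k-mers sampled every `stride` positions
#' across all sequences, then runs [estimateSimilarity()] on pairs sharing at
#' least `min_hits` sampled k-mers. Unrelated random sequences share
#' essentially none, so the quadratic all-pairs cost is avoided.
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param pairs optional two-column matrix/data.frame of id pairs to score
#'   (bypasses the prefilter).
#' @param k anchor size (default 15).
#' @param stride sampling stride for the prefilter hash.
#' @param min_hits minimum shared sampled k-mers to promote a pair.
#' @return a data.frame with columns `a`, `b`, `ani`, `af`.
#' @export
similarityTable <- function(seqs, pairs = NULL, k = 15L, stride = 5L,
                            min_hits = 3L) {
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named")
  sq <- stats::setNames(as.character(seqs), ids)
  if (is.null(pairs)) {
    hits <- new.env(parent = emptyenv())
    tabs <- lapply(seq_along(sq), function(i) {
      l <- nchar(sq[i])
      if (l < k) return(character(0))
      pos <- seq(1L, l - k + 1L, by = stride)
      unique(substring(sq[i], pos, pos + k - 1L))
    })
    km_all <- unlist(tabs, use.names = FALSE)
    owner <- rep(seq_along(sq), lengths(tabs))
    by_km <- split(owner, km_all)
    by_km <- by_km[lengths(by_km) > 1L]
    pair_keys <- unlist(lapply(by_km, function(o) {
      o <- sort(unique(o))
      if (length(o) < 2L) return(character(0))
      cmb <- utils::combn(o, 2L)
      paste(cmb[1L, ], cmb[2L, ], sep = "_")
    }), use.names = FALSE)
    if (!length(pair_keys))
      return(data.frame(a = character(0), b = character(0),
                        ani = numeric(0), af = numeric(0)))
    counts <- table(pair_keys)
    counts <- counts[counts >= min_hits]
    if (!length(counts))
      return(data.frame(a = character(0), b = character(0),
                        ani = numeric(0), af = numeric(0)))
    idx <- do.call(rbind, strsplit(names(counts), "_", fixed = TRUE))
    pairs <- cbind(ids[as.integer(idx[, 1L])], ids[as.integer(idx[, 2L])])
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    s <- estimateSimilarity(sq[[pairs[r, 1L]]], sq[[pairs[r, 2L]]], k = k)
    data.frame(a = pairs[r, 1L], b = pairs[r, 2L],
               ani = s$ani, af = s$af, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
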