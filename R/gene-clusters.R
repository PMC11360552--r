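# Greedy incremental sequence clustering (longest-first, first-fit) of AMG
# sequences, and novelty assessment by co-clustering catalog proteins with
# published reference AMG proteins. Pairwise identity and coverage come
# from local alignment (match 1, mismatch -1, gap 2); identity is
# matches / alignment columns, coverage is the aligned fraction of the
# member sequence (or of both, for cov_of = "both").

.detectAlphabet <- function(seqs) {
  if (is(seqs, "DNAStringSet") || is(seqs, "DNAString")) return("DNA")
  if (is(seqs, "AAStringSet") || is(seqs, "AAString")) return("AA")
  chars <- unique(strsplit(paste(toupper(as.character(seqs)), collapse = ""),
                           "")[[1]])
  per <- vapply(as.character(seqs), function(s) {
    all(strsplit(toupper(s), "")[[1]] %in% c("A", "C", "G", "T", "N", "U"))
  }, logical(1))
  if (all(per)) return("DNA")
  if (!any(per)) return("AA")
  stop("mixed nucleotide and amino-acid sequences in one clustering run")
}

.aaSubMatrix <- function() {
  lets <- c(Biostrings::AA_ALPHABET)
  m <- matrix(-1, length(lets), length(lets), dimnames = list(lets, lets))
  diag(m) <- 1
  m
}

# local alignment identity/coverage between member and representative
.alnStats <- function(member, rep_seq, alphabet) {
  if (alphabet == "DNA") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    p <- Biostrings::DNAString(member)
    s <- Biostrings::DNAString(rep_seq)
  } else {
    mat <- .aaSubMatrix()
    p <- Biostrings::AAString(member)
    s <- Biostrings::AAString(rep_seq)
  }
  aln <- Biostrings::pairwiseAlignment(p, s, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  cols <- Biostrings::nchar(aln)
  if (cols == 0L) return(c(identity = 0, cov_member = 0, cov_rep = 0))
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  c(identity = Biostrings::nmatch(aln) / cols,
    cov_member = (IRanges::end(pr) - IRanges::start(pr) + 1) / length(p),
    cov_rep = (IRanges::end(sr) - IRanges::start(sr) + 1) / length(s))
}

# shared-k-mer prefilter (DNA only); TRUE means "worth aligning"
.kmerShare <- function(a, b, k = 11L, min_hits = 3L) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k) return(TRUE)
  pa <- seq_len(la - k + 1L)
  pb <- seq_len(lb - k + 1L)
  ka <- unique(substring(a, pa, pa + k - 1L))
  kb <- unique(substring(b, pb, pb + k - 1L))
  length(intersect(ka, kb)) >= min_hits
}

#' Greedy incremental sequence clustering
#'
#' Longest-first, first-fit: sequences are sorted by length descending (ties
#' by lexicographically smallest id); each sequence joins the first existing
#' representative it matches at `>= min_id` alignment identity with
#' `>= min_cov` coverage (of the member for `cov_of = "member"`, of both
#' sequences for `"both"`), otherwise it founds a new cluster. Deterministic
#' given the input.
#'
#' @param seqs a named [Biostrings::DNAStringSet], `AAStringSet`, or named
#'   character vector; one alphabet per run (mixed alphabets are an error).
#' @param min_id minimum alignment identity in `[0, 1]`.
#' @param min_cov minimum coverage in `[0, 1]`.
#' @param cov_of coverage mode: `"member"` (default) or `"both"`.
#' @return a [GeneClusters] object.
#' @examples
#' s <- c(a = "ATGGCCAAATTTGGGCCCAAATTTGGG", b = "ATGGCCAAATTTGGGCCCAAATTTGGG")
#' clusterMembership(greedyCluster(s, 0.9, 0.9))
#' @export
greedyCluster <- function(seqs, min_id, min_cov,
                          cov_of = c("member", "both")) {
  cov_of <- match.arg(cov_of)
  .checkFraction(min_id, "min_id")
  .checkFraction(min_cov, "min_cov")
  ids <- names(seqs)
  sq <- stats::setNames(toupper(as.character(seqs)), ids)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
  if (anyDuplicated(ids)) stop("duplicated sequence ids")
  if (!length(sq))
    return(new("GeneClusters", membership = DataFrame(
      cluster_id = character(0), representative = character(0),
      member = character(0), is_reference = logical(0))))
  alphabet <- .detectAlphabet(seqs)
  lens <- nchar(sq)
  ord <- order(-lens, ids)
  reps <- character(0)
  assignment <- character(length(sq))
  for (i in ord) {
    joined <- NA_character_
    for (rep_id in reps) {
      if (alphabet == "DNA" && !.kmerShare(sq[[i]], sq[[rep_id]])) next
      st <- .alnStats(sq[[i]], sq[[rep_id]], alphabet)
      cov_ok <- if (cov_of == "member") st["cov_member"] >= min_cov
                else st["cov_member"] >= min_cov && st["cov_rep"] >= min_cov
      if (st["identity"] >= min_id && cov_ok) {
        joined <- rep_id
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, ids[i])
      assignment[i] <- ids[i]
    } else assignment[i] <- joined
  }
  cl_ids <- stats::setNames(sprintf("GC_%05d", seq_along(reps)), reps)
  ord_out <- order(match(assignment, reps), ids)
  new("GeneClusters", membership = DataFrame(
    cluster_id = unname(cl_ids[assignment[ord_out]]),
    representative = assignment[ord_out],
    member = ids[ord_out],
    is_reference = FALSE))
}

#' Assess AMG novelty against published reference sequences
#'
#' Co-clusters the catalog AMG proteins with the reference AMG proteins
#' (greedy incremental clustering at `min_id` identity and `min_cov`
#' coverage). A catalog cluster is novel iff no member of its co-cluster is
#' a reference sequence.
#'
#' @param catalog_seqs named catalog AMG protein sequences.
#' @param reference_seqs named published reference AMG protein sequences;
#'   an empty reference set makes every cluster novel, with a warning.
#' @param min_id minimum identity (default 0.30).
#' @param min_cov minimum coverage (default 0.60).
#' @return a list with `clusters` (data.frame: `cluster_id`,
#'   `representative`, `n_members`, `contains_reference`, `novel`),
#'   `n_novel`, `n_total`, `percent_novel`.
#' @export
assessNovelty <- function(catalog_seqs, reference_seqs,
                          min_id = 0.30, min_cov = 0.60) {
  cat_ids <- names(catalog_seqs)
  ref_ids <- names(reference_seqs)
  if (length(intersect(cat_ids, ref_ids)))
    stop("catalog and reference sequence ids must not overlap")
  if (!length(reference_seqs))
    warning("empty reference set: every catalog cluster is novel")
  all_seqs <- stats::setNames(
    c(as.character(catalog_seqs), as.character(reference_seqs)),
    c(cat_ids, ref_ids))
  cl <- greedyCluster(all_seqs, min_id = min_id, min_cov = min_cov,
                      cov_of = "member")
  m <- as.data.frame(clusterMembership(cl))
  m$is_reference <- m$member %in% ref_ids
  by_cl <- split(m, m$cluster_id)
  rows <- lapply(by_cl, function(g) {
    has_cat <- any(!g$is_reference)
    if (!has_cat) return(NULL)
    data.frame(cluster_id = g$cluster_id[1],
               representative = g$representative[1],
               n_members = nrow(g),
               contains_reference = any(g$is_reference),
               novel = !any(g$is_reference),
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n_total <- nrow(clusters)
  n_novel <- sum(clusters$novel)
  list(clusters = clusters, n_novel = n_novel, n_total = n_total,
       percent_novel = if (n_total) 100 * n_novel / n_total else NA_real_)
}
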