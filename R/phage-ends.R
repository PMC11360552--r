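# Prophage-end evidence: tRNA features and maximal exact inverted/direct
# repeat pairs near the boundaries of the interval under test. A bracketing
# repeat pair (or flanking tRNAs) defines an inferred phage interval used by
# the conservative curation rules.

# maximal gap-free extension of a seed pair between strings x and y
.extendPair <- function(x, y, i, j, m) {
  lx <- nchar(x); ly <- nchar(y)
  while (i > 1L && j > 1L &&
         substr(x, i - 1L, i - 1L) == substr(y, j - 1L, j - 1L)) {
    i <- i - 1L; j <- j - 1L; m <- m + 1L
  }
  while (i + m <= lx && j + m <= ly &&
         substr(x, i + m, i + m) == substr(y, j + m, j + m)) {
    m <- m + 1L
  }
  c(i = i, j = j, len = m)
}

# all maximal exact repeat pairs (direct and inverted) with arm >= min_arm
.findExactRepeats <- function(s, min_arm = 20L, max_occ = 8L) {
  L <- nchar(s)
  out <- list()
  if (L < 2L * min_arm) {
    return(data.frame(kind = character(0), s1 = integer(0), e1 = integer(0),
                      s2 = integer(0), e2 = integer(0)))
  }
  tab_s <- .kmerPositions(s, min_arm, max_occ)
  # direct repeats: same k-mer at two positions of s
  dup <- tab_s[lengths(tab_s) >= 2L]
  seen <- new.env(parent = emptyenv())
  for (posv in dup) {
    cmb <- utils::combn(posv, 2L)
    for (c_i in seq_len(ncol(cmb))) {
      p <- cmb[1L, c_i]; q <- cmb[2L, c_i]
      ext <- .extendPair(s, s, p, q, min_arm)
      s1 <- ext["i"]; s2 <- ext["j"]; len <- ext["len"]
      if (s1 + len - 1L >= s2) {  # overlapping arms: trim to abut
        len <- s2 - s1
        if (len < min_arm) next
      }
      key <- paste("D", s1, s2, len)
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- data.frame(
          kind = "direct_repeat", s1 = s1, e1 = s1 + len - 1L,
          s2 = s2, e2 = s2 + len - 1L)
      }
    }
  }
  # inverted repeats: k-mer of s matching the reverse complement
  rc <- .revcomp(s)
  tab_rc <- .kmerPositions(rc, min_arm, max_occ)
  shared <- intersect(names(tab_s), names(tab_rc))
  for (km in shared) {
    for (i in tab_s[[km]]) {
      for (j in tab_rc[[km]]) {
        ext <- .extendPair(s, rc, i, j, min_arm)
        i0 <- ext["i"]; j0 <- ext["j"]; len <- ext["len"]
        a1 <- c(i0, i0 + len - 1L)
        a2 <- c(L - (j0 + len - 1L) + 1L, L - j0 + 1L)
        if (a1[1] > a2[1]) next        # mirrored duplicate
        if (a1[2] >= a2[1]) {          # self-overlap (palindrome center)
          trim <- a1[2] - a2[1] + 1L
          shrink <- ceiling(trim / 2)
          len <- len - shrink
          if (len < min_arm) next
          a1 <- c(i0, i0 + len - 1L)
          a2 <- c(a2[1] + shrink, a2[2])
          a2[1] <- a2[2] - len + 1L
          if (a1[2] >= a2[1]) next
        }
        key <- paste("I", a1[1], a2[1], len)
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- data.frame(
            kind = "inverted_repeat", s1 = a1[1], e1 = a1[2],
            s2 = a2[1], e2 = a2[2])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), s1 = integer(0), e1 = integer(0),
                      s2 = integer(0), e2 = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$s1, res$s2), , drop = FALSE]
}

# distance from an interval [s, e] to a position p (0 if covering)
.intervalDist <- function(s, e, p) {
  ifelse(p < s, s - p, ifelse(p > e, p - e, 0L))
}

#' Detect prophage-end evidence on a contig
#'
#' Reports tRNA features and maximal exact inverted/direct repeat pairs
#' whose arms lie within `end_window` bp of the boundaries of the interval
#' under test (the contig's first viral region if present, else the whole
#' contig). A repeat pair whose arms bracket the two boundaries, or tRNAs
#' flanking both boundaries, define the inferred phage interval.
#'
#' @param contig_id contig identifier.
#' @param sequence nucleotide string, or `NULL` (repeat search is skipped
#'   with a warning and tRNA evidence alone is used).
#' @param contig_length contig length in bp (required when `sequence` is
#'   `NULL`).
#' @param viral_region optional length-2 numeric `(start, end)` interval
#'   under test; default the whole contig.
#' @param trna optional data.frame of tRNA features with columns `start`,
#'   `end` (already restricted to this contig).
#' @param min_arm minimum repeat arm length (default 20 bp).
#' @param end_window window around each boundary (default 1000 bp).
#' @param circular if `TRUE` the repeat search wraps the origin.
#' @return a list with `contig_id`, `evidence` (data.frame: `kind`,
#'   `left_start`, `left_end`, `right_start`, `right_end`) and
#'   `inferred_interval` (length-2 numeric or `NULL`).
#' @export
detectPhageEnds <- function(contig_id, sequence = NULL, contig_length = NULL,
                            viral_region = NULL, trna = NULL,
                            min_arm = 20L, end_window = 1000L,
                            circular = FALSE) {
  if (is.null(sequence)) {
    if (is.null(contig_length))
      stop("contig_length required when no sequence is available")
    L <- as.integer(contig_length)
    warning("no sequence for contig ", contig_id,
            "; repeat search skipped (tRNA evidence only)")
    reps <- data.frame(kind = character(0), s1 = integer(0), e1 = integer(0),
                       s2 = integer(0), e2 = integer(0))
  } else {
    sequence <- toupper(as.character(sequence))
    L <- nchar(sequence)
    search_seq <- sequence
    if (circular && L > 2L * min_arm) {
      ext <- min(L, 2L * end_window)
      search_seq <- paste0(sequence, substr(sequence, 1L, ext))
    }
    reps <- .findExactRepeats(search_seq, min_arm = min_arm)
    if (circular && nrow(reps)) {
      for (col in c("s1", "e1", "s2", "e2"))
        reps[[col]] <- ((reps[[col]] - 1L) %% L) + 1L
      reps <- reps[!(reps$s1 == reps$s2 & reps$e1 == reps$e2), , drop = FALSE]
      reps <- reps[!duplicated(reps), , drop = FALSE]
    }
  }
  if (is.null(viral_region)) viral_region <- c(1L, L)
  lb <- viral_region[1]; rb <- viral_region[2]

  ev <- list()
  if (nrow(reps)) {
    near <- .intervalDist(reps$s1, reps$e1, lb) <= end_window &
      .intervalDist(reps$s2, reps$e2, rb) <= end_window &
      reps$e1 < reps$s2
    reps <- reps[near, , drop = FALSE]
    if (nrow(reps))
      ev[[length(ev) + 1L]] <- data.frame(
        kind = reps$kind, left_start = reps$s1, left_end = reps$e1,
        right_start = reps$s2, right_end = reps$e2,
        stringsAsFactors = FALSE)
  }
  trna_left <- trna_right <- NULL
  if (!is.null(trna) && nrow(trna)) {
    dl <- .intervalDist(trna$start, trna$end, lb)
    dr <- .intervalDist(trna$start, trna$end, rb)
    is_left <- dl <= end_window & dl <= dr
    is_right <- dr <= end_window & dr < dl
    if (any(is_left)) trna_left <- trna[is_left, , drop = FALSE]
    if (any(is_right)) trna_right <- trna[is_right, , drop = FALSE]
    for (r in which(is_left | is_right)) {
      side_left <- is_left[r]
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "tRNA",
        left_start = if (side_left) trna$start[r] else NA_integer_,
        left_end = if (side_left) trna$end[r] else NA_integer_,
        right_start = if (side_left) NA_integer_ else trna$start[r],
        right_end = if (side_left) NA_integer_ else trna$end[r],
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev)
              else data.frame(kind = character(0), left_start = integer(0),
                              left_end = integer(0), right_start = integer(0),
                              right_end = integer(0))
  inferred <- NULL
  rp <- evidence[evidence$kind != "tRNA", , drop = FALSE]
  if (nrow(rp)) {
    span <- rp$right_end - rp$left_start
    best <- which.max(span)
    inferred <- c(rp$left_start[best], rp$right_end[best])
  } else if (!is.null(trna_left) && !is.null(trna_right)) {
    inferred <- c(max(trna_left$end) + 1L, min(trna_right$start) - 1L)
  }
  list(contig_id = contig_id, evidence = evidence,
       inferred_interval = inferred)
}

#' Detect prophage ends across a contig set
#'
#' Applies [detectPhageEnds()] to every contig of a [ContigSet], using each
#' contig's first viral region (when it does not span the whole contig) as
#' the interval under test.
#'
#' @param contigs a [ContigSet].
#' @param trna data.frame of tRNA features (`contig_id`, `start`, `end`).
#' @param ... passed to [detectPhageEnds()].
#' @return a named list of [detectPhageEnds()] results, one per contig.
#' @export
detectPhageEndsSet <- function(contigs, trna = NULL, ...) {
  stopifnot(is(contigs, "ContigSet"))
  ids <- contigIds(contigs)
  lens <- contigLengths(contigs)
  regs <- viralRegions(contigs)
  seqs <- contigSequences(contigs)
  has_seq <- length(seqs) > 0L
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    reg <- regs[[i]]
    vr <- if (length(reg) &&
              !(IRanges::start(reg)[1] == 1L &&
                  IRanges::end(reg)[1] == lens[i]))
      c(IRanges::start(reg)[1], IRanges::end(reg)[1]) else NULL
    tr <- if (!is.null(trna) && nrow(trna))
      trna[trna$contig_id == ids[i], , drop = FALSE] else NULL
    out[[i]] <- detectPhageEnds(
      ids[i],
      sequence = if (has_seq) as.character(seqs[[i]]) else NULL,
      contig_length = lens[i],
      viral_region = vr, trna = tr, ...)
  }
  out
}
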