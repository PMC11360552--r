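# Population abundance from depth profiles: read filters, breadth gate,
# trimmed-mean depth normalized per giga-read, paired-sample summation, and
# KO-level virus-versus-microbe enrichment.

#' Filter read alignments and build depth profiles
#'
#' Keeps alignment rows with identity `>= min_identity` and aligned
#' read fraction `>= min_read_cov`, then stacks the retained aligned
#' intervals into per-contig, per-sample depth vectors.
#'
#' @param alignments data.frame with columns `contig_id`, `sample_id`,
#'   `tstart`, `tend` (1-based inclusive alignment interval on the contig),
#'   `identity` (0-1), `read_cov` (aligned fraction of the read, 0-1).
#' @param contig_lengths named integer vector of contig lengths.
#' @param total_reads named numeric vector of total reads per sample.
#' @param min_identity minimum read identity (default 0.95).
#' @param min_read_cov minimum aligned read fraction (default 0.75).
#' @return a [DepthProfileSet] covering every contig x sample combination.
#' @export
filterAlignments <- function(alignments, contig_lengths, total_reads,
                             min_identity = 0.95, min_read_cov = 0.75) {
  alignments <- as.data.frame(alignments)
  if (any(alignments$identity < 0 | alignments$identity > 1))
    stop("alignment identity outside [0, 1]")
  if (any(alignments$read_cov < 0 | alignments$read_cov > 1))
    stop("read coverage outside [0, 1]")
  keep <- alignments$identity >= min_identity &
    alignments$read_cov >= min_read_cov
  kept <- alignments[keep, , drop = FALSE]
  samples <- names(total_reads)
  profs <- list()
  info <- list()
  for (sid in samples) {
    for (cid in names(contig_lengths)) {
      L <- as.integer(contig_lengths[[cid]])
      rows <- kept[kept$contig_id == cid & kept$sample_id == sid, ,
                   drop = FALSE]
      cov <- if (nrow(rows)) {
        IRanges::coverage(IRanges::IRanges(pmax(1L, rows$tstart),
                                           pmin(L, rows$tend)),
                          width = L)
      } else Rle(0L, L)
      key <- paste(cid, sid, sep = "|")
      profs[[key]] <- cov
      info[[key]] <- data.frame(contig_id = cid, sample_id = sid,
                                total_reads = unname(total_reads[[sid]]),
                                stringsAsFactors = FALSE)
    }
  }
  dl <- as(S4Vectors::SimpleList(profs), "RleList")
  new("DepthProfileSet", depths = dl,
      info = DataFrame(do.call(rbind, info)))
}

#' Trimmed-mean abundance of one depth profile
#'
#' Breadth is the fraction of positions with depth above zero; a profile
#' below `min_breadth` gets abundance exactly 0. Otherwise the top and
#' bottom `floor(trim * L)` positions by depth are discarded and the mean of
#' the rest is normalized by the sample's total reads and scaled per 10^9
#' reads. With fewer than `1/trim` positions no trimming occurs.
#'
#' @param depths per-position depth vector ([S4Vectors::Rle] or numeric),
#'   non-empty.
#' @param total_reads total reads in the sample.
#' @param trim fraction trimmed at each tail (default 0.05).
#' @param min_breadth breadth cut-off (default 0.70).
#' @return a single abundance value (trimmed-mean depth per giga-read).
#' @examples
#' trimmedMeanAbundance(rep(10, 100), total_reads = 1e9)  # 10
#' @export
trimmedMeanAbundance <- function(depths, total_reads, trim = 0.05,
                                 min_breadth = 0.70) {
  v <- as.numeric(depths)
  if (!length(v)) stop("empty depth vector")
  if (total_reads <= 0) stop("total_reads must be positive")
  breadth <- mean(v > 0)
  if (breadth < min_breadth) return(0)
  L <- length(v)
  k <- floor(trim * L)
  if (k > 0L) {
    v <- sort(v)[(k + 1L):(L - k)]
  }
  mean(v) / total_reads * 1e9
}

#' Population abundance matrix over paired samples
#'
#' The abundance of a population in a paired sample is the sum of its
#' representative contig's normalized trimmed-mean abundances over the
#' pair's member samples (virus-enriched plus prokaryote-enriched).
#' Profiles failing the breadth gate contribute exactly 0.
#'
#' @param populations a [VirusPopulations].
#' @param profiles a [DepthProfileSet] covering the representative contigs.
#' @param pairing data.frame with columns `sample_id` and `pair_id`.
#' @param trim,min_breadth passed to [trimmedMeanAbundance()].
#' @return a numeric matrix, populations x paired samples.
#' @export
populationAbundance <- function(populations, profiles, pairing,
                                trim = 0.05, min_breadth = 0.70) {
  stopifnot(is(populations, "VirusPopulations"),
            is(profiles, "DepthProfileSet"))
  reps <- representatives(populations)
  info <- as.data.frame(profileInfo(profiles))
  dl <- depthProfiles(profiles)
  pairs <- unique(pairing$pair_id)
  out <- matrix(0, nrow = length(reps), ncol = length(pairs),
                dimnames = list(names(reps), pairs))
  for (p in pairs) {
    sids <- pairing$sample_id[pairing$pair_id == p]
    for (pop in names(reps)) {
      cid <- reps[[pop]]
      tot <- 0
      for (sid in sids) {
        key <- paste(cid, sid, sep = "|")
        ri <- match(key, paste(info$contig_id, info$sample_id, sep = "|"))
        if (is.na(ri)) next
        tot <- tot + trimmedMeanAbundance(dl[[key]], info$total_reads[ri],
                                          trim = trim,
                                          min_breadth = min_breadth)
      }
      out[pop, p] <- tot
    }
  }
  out
}

#' KO-level virus-versus-microbe abundance enrichment
#'
#' For each KO carried by a conservative AMG: the viral abundance is the
#' arithmetic mean, over AMG-carrying populations encoding that KO, of
#' their total abundance summed across paired samples; the microbial
#' abundance is the summed microbial KO abundance. The fold ratio
#' (viral / microbial) flags a KO as virus-enriched when above 1. A KO with
#' microbial abundance 0 but viral signal is reported with status
#' `"microbe-absent"` (fold `NA`), never as an infinite fold; KOs absent
#' from both sides are omitted with a message.
#'
#' @param catalog an [AmgCatalog]; its conservative tier is used.
#' @param populations a [VirusPopulations].
#' @param population_abundances matrix from [populationAbundance()].
#' @param microbial_ko_abundances named numeric vector (KO -> summed
#'   abundance) or matrix (KOs x paired samples, summed internally).
#' @return a data.frame with `ko`, `n_populations`, `viral_abundance`,
#'   `microbial_abundance`, `fold`, `enriched`, `status`.
#' @export
koEnrichment <- function(catalog, populations, population_abundances,
                         microbial_ko_abundances) {
  stopifnot(is(catalog, "AmgCatalog"), is(populations, "VirusPopulations"))
  cons <- as.data.frame(conservativeSet(catalog))
  cons <- cons[!is.na(cons$ko), , drop = FALSE]
  m <- as.data.frame(populationMembership(populations))
  pop_of <- stats::setNames(m$population_id, m$member)
  if (is.matrix(microbial_ko_abundances))
    microbial_ko_abundances <- rowSums(microbial_ko_abundances)
  pop_tot <- rowSums(population_abundances)
  kos <- sort(unique(c(cons$ko, names(microbial_ko_abundances))))
  rows <- list()
  omitted <- character(0)
  for (ko in kos) {
    carrier_pops <- unique(pop_of[cons$contig_id[cons$ko == ko]])
    carrier_pops <- carrier_pops[!is.na(carrier_pops)]
    viral <- if (length(carrier_pops))
      mean(pop_tot[carrier_pops]) else 0
    microbial <- if (ko %in% names(microbial_ko_abundances))
      unname(microbial_ko_abundances[[ko]]) else 0
    if (viral == 0 && microbial == 0) {
      omitted <- c(omitted, ko)
      next
    }
    if (microbial > 0) {
      fold <- viral / microbial
      status <- "ok"
    } else {
      fold <- NA_real_
      status <- "microbe-absent"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      ko = ko, n_populations = length(carrier_pops),
      viral_abundance = viral, microbial_abundance = microbial,
      fold = fold,
      enriched = (!is.na(fold) && fold > 1) || status == "microbe-absent",
      status = status, stringsAsFactors = FALSE)
  }
  if (length(omitted))
    message(length(omitted), " KO(s) absent from both sides omitted")
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(ko = character(0), n_populations = integer(0),
                         viral_abundance = numeric(0),
                         microbial_abundance = numeric(0),
                         fold = numeric(0), enriched = logical(0),
                         status = character(0))
  rownames(out) <- NULL
  out
}
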