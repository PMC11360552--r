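# Contig screening: length, virus-identification score, and the
# "dsDNA phage"-maximal classifier rule.

#' Screen contigs for downstream virus analysis
#'
#' Keeps contigs that are at least `min_len` bp long, have a virus
#' identification score of at least `min_score`, and whose classifier score
#' is maximized by the "dsDNA phage" group (a tie with another group counts
#' as dsDNA-maximal; the permissive choice, since stricter curation follows
#' downstream). Contigs with no classifier scores are rejected with a
#' logged reason.
#'
#' @param contigs a [ContigSet].
#' @param min_len minimum contig length in bp (default 5000).
#' @param min_score minimum virus score (default 0.75).
#' @return the screened [ContigSet]; rejected contig ids and reasons are
#'   recorded in `metadata(x)$screening`.
#' @examples
#' sim <- generateSurveyContigs(amgSimParams(n_contigs = 20L, seed = 2L))
#' sc <- screenContigs(sim$contigs)
#' metadata(sc)$screening
#' @export
screenContigs <- function(contigs, min_len = 5000, min_score = 0.75) {
  stopifnot(is(contigs, "ContigSet"))
  info <- contigInfo(contigs)
  cls <- classifierScores(contigs)
  n <- nrow(info)
  reason <- rep(NA_character_, n)

  len_ok <- info$length >= min_len
  reason[!len_ok] <- "below minimum length"

  score <- info$virsorter_score
  score_ok <- !is.na(score) & score >= min_score
  reason[is.na(reason) & !score_ok] <- "below minimum score"

  ds <- cls[, "dsDNA phage"]
  others <- cls[, setdiff(colnames(cls), "dsDNA phage"), drop = FALSE]
  has_cls <- !is.na(ds) & rowSums(!is.na(others)) > 0L
  max_other <- suppressWarnings(apply(others, 1L, max, na.rm = TRUE))
  ds_max <- has_cls & ds >= max_other
  reason[is.na(reason) & !has_cls] <- "missing classifier scores"
  reason[is.na(reason) & has_cls & !ds_max] <- "dsDNA phage not top classifier"

  keep <- is.na(reason)
  out <- contigs[which(keep)]
  metadata(out)$screening <- DataFrame(
    contig_id = info$contig_id[!keep],
    reason = reason[!keep])
  out
}
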