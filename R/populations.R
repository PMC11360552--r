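# Greedy longest-first clustering of screened contigs into species-rank
# virus populations (vOTUs) at >=95% ANI over >=80% aligned fraction of the
# shorter sequence.

#' Cluster contigs into virus populations
#'
#' Greedy longest-first clustering: contigs are sorted by length descending
#' (ties by lexicographically smallest id); each contig joins the first
#' existing representative it matches at `>= min_ani` ANI and `>= min_af`
#' aligned fraction, otherwise it founds a new population. Pairs absent from
#' `similarities` are treated as below threshold. The aligned fraction is
#' taken over the shorter sequence, following standard vOTU practice.
#'
#' @param contigs a [ContigSet], or a data.frame with columns `contig_id`
#'   and `length`.
#' @param similarities data.frame with columns `a`, `b`, `ani` (0-100), `af`
#'   (0-1); symmetric pairs are normalized, and contradictory duplicate rows
#'   for the same pair raise an error.
#' @param min_ani minimum average nucleotide identity (percent, default 95).
#' @param min_af minimum aligned fraction (default 0.80).
#' @return a [VirusPopulations] object.
#' @examples
#' ctg <- data.frame(contig_id = c("a", "b"), length = c(9000, 8000))
#' sim <- data.frame(a = "a", b = "b", ani = 99, af = 0.95)
#' clusterPopulations(ctg, sim)
#' @export
clusterPopulations <- function(contigs, similarities, min_ani = 95,
                               min_af = 0.80) {
  if (is(contigs, "ContigSet")) {
    tab <- data.frame(contig_id = contigIds(contigs),
                      length = unname(contigLengths(contigs)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(contigs)[, c("contig_id", "length")]
  }
  if (anyDuplicated(tab$contig_id)) stop("duplicated contig ids")
  sim_env <- new.env(parent = emptyenv())
  if (!is.null(similarities) && nrow(similarities)) {
    key <- ifelse(similarities$a < similarities$b,
                  paste(similarities$a, similarities$b, sep = "\r"),
                  paste(similarities$b, similarities$a, sep = "\r"))
    for (r in seq_along(key)) {
      old <- sim_env[[key[r]]]
      val <- c(similarities$ani[r], similarities$af[r])
      if (!is.null(old)) {
        if (any(abs(old - val) > 1e-9))
          stop("contradictory duplicate similarity rows for pair ",
               similarities$a[r], " / ", similarities$b[r])
      } else assign(key[r], val, envir = sim_env)
    }
  }
  ord <- order(-tab$length, tab$contig_id)
  tab <- tab[ord, , drop = FALSE]
  reps <- character(0)
  assignment <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$contig_id[i]
    joined <- NA_character_
    for (rep_id in reps) {
      key <- if (id < rep_id) paste(id, rep_id, sep = "\r")
             else paste(rep_id, id, sep = "\r")
      v <- sim_env[[key]]
      if (!is.null(v) && v[1] >= min_ani && v[2] >= min_af) {
        joined <- rep_id
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, id)
      assignment[i] <- id
    } else assignment[i] <- joined
  }
  pop_ids <- stats::setNames(sprintf("vOTU_%05d", seq_along(reps)), reps)
  rep_len <- stats::setNames(tab$length, tab$contig_id)[reps]
  new("VirusPopulations", membership = DataFrame(
    population_id = unname(pop_ids[assignment]),
    representative = assignment,
    member = tab$contig_id,
    rep_length = unname(rep_len[assignment])))
}
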