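# AMG curation: the permissive catalog (metabolic-module or known-AMG genes
# with bit score >= 60 and auxiliary score <= 3) and the conservative
# catalog obtained by the post-annotation rules R1 (viral-region
# containment or confident virus score), R2 (prophage-end containment) and
# R3 (mobile-element blacklist), with a full per-gene decision trail.

.normalizeGenes <- function(genes) {
  genes <- as.data.frame(genes)
  need <- c("gene_id", "contig_id", "start", "end", "bit_score",
            "auxiliary_score")
  miss <- setdiff(need, colnames(genes))
  if (length(miss))
    stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (!"ko" %in% colnames(genes)) genes$ko <- NA_character_
  if (!"module_ids" %in% colnames(genes)) genes$module_ids <- NA_character_
  if (!"known_amg" %in% colnames(genes)) genes$known_amg <- FALSE
  if (!"category_flags" %in% colnames(genes))
    genes$category_flags <- NA_character_
  if (!"strand" %in% colnames(genes)) genes$strand <- "+"
  genes$known_amg[is.na(genes$known_amg)] <- FALSE
  if (any(genes$start > genes$end)) stop("gene start > end")
  if (!all(genes$auxiliary_score %in% 1:5))
    stop("auxiliary scores must be integers in 1..5")
  genes
}

#' Call the permissive AMG catalog
#'
#' A gene is a permissive AMG candidate iff its bit score is at least
#' `min_bitscore`, it is assigned to at least one metabolic module and/or
#' matches a previously described AMG, and its auxiliary score (confidence
#' of being virus-encoded; lower is more confident) is at most `max_aux`.
#'
#' @param genes gene annotation data.frame (`gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `bit_score`, `auxiliary_score`, `ko`, `module_ids`,
#'   `known_amg`, `category_flags`).
#' @param contigs a [ContigSet] holding the screened contigs the genes
#'   belong to; a gene referencing an unknown contig is an error.
#' @param min_bitscore minimum annotation bit score (default 60).
#' @param max_aux maximum auxiliary score (default 3).
#' @return an [AmgCatalog] of permissive-tier candidates.
#' @export
callPermissive <- function(genes, contigs, min_bitscore = 60, max_aux = 3) {
  stopifnot(is(contigs, "ContigSet"))
  genes <- .normalizeGenes(genes)
  unknown <- setdiff(unique(genes$contig_id), contigIds(contigs))
  if (length(unknown))
    stop("genes reference unknown contigs: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  has_module <- !is.na(genes$module_ids) & nzchar(genes$module_ids)
  ok <- genes$bit_score >= min_bitscore &
    (has_module | genes$known_amg) &
    genes$auxiliary_score <= max_aux
  cand <- genes[ok, , drop = FALSE]
  cand$tier <- rep("permissive", nrow(cand))
  dec <- DataFrame(
    gene_id = cand$gene_id,
    rule_id = rep("permissive", nrow(cand)),
    outcome = rep("pass", nrow(cand)),
    reason = rep("bit score, module/known-AMG and auxiliary score gates met",
                 nrow(cand)))
  new("AmgCatalog",
      candidates = DataFrame(cand[, c("gene_id", "contig_id", "start", "end",
                                      "strand", "bit_score",
                                      "auxiliary_score", "ko", "module_ids",
                                      "known_amg", "tier")]),
      decisions = dec)
}

#' Apply the conservative post-annotation curation rules
#'
#' Rules are applied in order. R1 (virus region): a candidate is kept iff
#' its gene interval lies fully inside a viral region of its contig, or the
#' contig's virus score is at least `confident_score`. R2 (phage ends): if
#' an inferred phage interval exists for the contig, the candidate must lie
#' fully inside it. R3 (blacklist): every candidate on a contig carrying at
#' least one gene with a blacklist category flag (transposase, integrase,
#' endonuclease, plasmid stability, glycosyltransferase, nucleotidyl
#' transferase, carbohydrate kinase, nucleotide sugar epimerase) is dropped,
#' regardless of the candidate's own position. Rejections are recorded in
#' the decision trail, never raised as errors; survivors get
#' `tier = "conservative"`.
#'
#' @param catalog a permissive-tier [AmgCatalog] from [callPermissive()].
#' @param contigs the screened [ContigSet].
#' @param genes the full gene annotation table (all genes, not only
#'   candidates; required for the contig-wide blacklist rule).
#' @param ends optional named list of [detectPhageEnds()] results.
#' @param confident_score virus score above which R1 passes regardless of
#'   region containment (default 0.95).
#' @param use_phage_ends set `FALSE` to disable R2.
#' @param blacklist category flags that trigger R3.
#' @return the updated [AmgCatalog] with tiers and the full decision trail.
#' @export
applyConservativeRules <- function(catalog, contigs, genes, ends = NULL,
                                   confident_score = 0.95,
                                   use_phage_ends = TRUE,
                                   blacklist = .BLACKLIST_FLAGS) {
  stopifnot(is(catalog, "AmgCatalog"), is(contigs, "ContigSet"))
  genes <- .normalizeGenes(genes)
  cand <- as.data.frame(amgCandidates(catalog))
  if (!nrow(cand)) return(catalog)
  regs <- viralRegions(contigs)
  scores <- virsorterScores(contigs)
  ids <- contigIds(contigs)

  flags <- .splitFlags(genes$category_flags)
  black_contigs <- unique(genes$contig_id[
    vapply(flags, function(f) any(f %in% blacklist), logical(1))])

  n <- nrow(cand)
  r1 <- r2 <- r3 <- logical(n)
  reason1 <- reason2 <- reason3 <- character(n)
  for (i in seq_len(n)) {
    cid <- cand$contig_id[i]
    ci <- match(cid, ids)
    reg <- regs[[ci]]
    inside <- length(reg) > 0L &&
      any(cand$start[i] >= IRanges::start(reg) &
            cand$end[i] <= IRanges::end(reg))
    confident <- !is.na(scores[cid]) && scores[cid] >= confident_score
    r1[i] <- inside || confident
    reason1[i] <- if (inside) "gene inside a viral region"
                  else if (confident) "contig virus score confident"
                  else "outside viral regions on a non-confident contig"
    if (use_phage_ends && !is.null(ends) && !is.null(ends[[cid]]) &&
        !is.null(ends[[cid]]$inferred_interval)) {
      iv <- ends[[cid]]$inferred_interval
      r2[i] <- cand$start[i] >= iv[1] && cand$end[i] <= iv[2]
      reason2[i] <- if (r2[i]) "gene inside the inferred phage interval"
                    else "gene outside the inferred phage interval"
    } else {
      r2[i] <- TRUE
      reason2[i] <- "no phage-end evidence"
    }
    r3[i] <- !(cid %in% black_contigs)
    reason3[i] <- if (r3[i]) "no blacklist gene on contig"
                  else "contig carries a blacklist-category gene"
  }
  keep <- r1 & r2 & r3
  cand$tier <- ifelse(keep, "conservative", "permissive")

  trail <- rbind(
    data.frame(gene_id = cand$gene_id, rule_id = "R1_virus_region",
               outcome = ifelse(r1, "pass", "fail"), reason = reason1,
               stringsAsFactors = FALSE),
    data.frame(gene_id = cand$gene_id, rule_id = "R2_phage_ends",
               outcome = ifelse(r2, "pass", "fail"), reason = reason2,
               stringsAsFactors = FALSE),
    data.frame(gene_id = cand$gene_id, rule_id = "R3_blacklist",
               outcome = ifelse(r3, "pass", "fail"), reason = reason3,
               stringsAsFactors = FALSE))
  new("AmgCatalog",
      candidates = DataFrame(cand),
      decisions = rbind(amgDecisions(catalog), DataFrame(trail)))
}

#' Summarize an AMG catalog over virus populations
#'
#' Maps conservative candidates to populations through their contigs and
#' reports catalog bookkeeping: the number of AMGs, the number and fraction
#' of AMG-carrying populations, and AMGs-per-carrier statistics.
#'
#' @param catalog an [AmgCatalog] (its conservative tier is summarized
#'   unless `tier = "permissive"`).
#' @param populations a [VirusPopulations].
#' @param tier which tier to summarize.
#' @return a list with `n_amgs`, `n_carrier_populations`,
#'   `n_total_populations`, `mean_per_carrier`, `min_per_carrier`,
#'   `max_per_carrier`, `observed_fraction`.
#' @export
catalogSummary <- function(catalog, populations,
                           tier = c("conservative", "permissive")) {
  tier <- match.arg(tier)
  stopifnot(is(catalog, "AmgCatalog"), is(populations, "VirusPopulations"))
  cand <- as.data.frame(amgCandidates(catalog))
  if (tier == "conservative")
    cand <- cand[cand$tier == "conservative", , drop = FALSE]
  m <- as.data.frame(populationMembership(populations))
  pop_of <- stats::setNames(m$population_id, m$member)
  n_total <- length(unique(m$population_id))
  if (!nrow(cand)) {
    return(list(n_amgs = 0L, n_carrier_populations = 0L,
                n_total_populations = n_total, mean_per_carrier = 0,
                min_per_carrier = 0L, max_per_carrier = 0L,
                observed_fraction = 0))
  }
  pops <- pop_of[cand$contig_id]
  if (anyNA(pops))
    stop("candidate contigs missing from the population partition: ",
         paste(utils::head(unique(cand$contig_id[is.na(pops)]), 3),
               collapse = ", "))
  per <- table(pops)
  list(n_amgs = nrow(cand),
       n_carrier_populations = length(per),
       n_total_populations = n_total,
       mean_per_carrier = as.numeric(nrow(cand) / length(per)),
       min_per_carrier = as.integer(min(per)),
       max_per_carrier = as.integer(max(per)),
       observed_fraction = length(per) / n_total)
}

#' Catalog bookkeeping from summary counts
#'
#' The survey arithmetic on plain counts: mean AMGs per carrier population,
#' observed AMG-carrying fraction, the conversion-corrected fraction, and
#' (optionally) the growth of the population catalog over a previous one.
#'
#' @param n_amgs number of catalog AMG sequences.
#' @param n_carriers number of AMG-carrying populations.
#' @param n_total total number of populations.
#' @param factor observed-to-true conversion factor (default 1, i.e. no
#'   correction).
#' @param n_previous optional previous catalog size for the growth fraction.
#' @return a list with `mean_per_carrier`, `observed_fraction`,
#'   `corrected_fraction`, and `growth_fraction` (NA when `n_previous` is
#'   not given).
#' @examples
#' bookkeepingChain(86913, 51666, 579904, factor = 2.1)
#' @export
bookkeepingChain <- function(n_amgs, n_carriers, n_total, factor = 1,
                             n_previous = NULL) {
  stopifnot(n_carriers <= n_total, n_amgs >= n_carriers)
  observed <- n_carriers / n_total
  list(mean_per_carrier = if (n_carriers > 0) n_amgs / n_carriers else 0,
       observed_fraction = observed,
       corrected_fraction = applyConversion(observed, factor),
       growth_fraction = if (is.null(n_previous)) NA_real_
                         else (n_total - n_previous) / n_total)
}
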