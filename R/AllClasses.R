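#' @import methods
#' @importFrom S4Vectors DataFrame Rle RleList metadata metadata<- runLength runValue
#' @importClassesFrom S4Vectors DataFrame Annotated
#' @importClassesFrom IRanges IRanges IRangesList RleList
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Parameters for the synthetic survey generator
#'
#' Holds every knob of the seeded synthetic-data generator. Defaults mirror
#' the study conditions of the global-ocean survey this package models: 81
#' mock reference populations of which 86\% carry at least one AMG (AMG counts
#' per carrier follow a zero-truncated Poisson fitted to mean 11.1 and
#' truncated at 25), and survey contigs with a median length of 12,608 bp.
#'
#' @slot n_genomes number of complete mock reference genomes.
#' @slot genome_length_range bp range (min, max) for mock genome lengths.
#' @slot p_amg_genome probability a mock genome carries at least one AMG.
#' @slot amg_count_mean,amg_count_max mean and truncation maximum of the
#'   zero-truncated Poisson AMG count for AMG-carrying genomes.
#' @slot n_contigs number of base survey contigs (near-duplicate copies are
#'   generated on top of these).
#' @slot contig_length_median,contig_length_sdlog median (bp) and log-sd of
#'   the lognormal survey contig length distribution (floored at 5 kb).
#' @slot p_amg_contig probability a clean virus contig carries AMGs.
#' @slot p_prophage_contig probability a contig is a prophage with cellular
#'   flanks delimited by a planted tRNA and an exact repeat pair.
#' @slot p_blacklist_contig probability a contig carries blacklist-category
#'   genes (transposase, integrase, ...).
#' @slot p_offtarget_contig probability a contig fails screening by design
#'   (low score or a non-"dsDNA phage" classifier maximum).
#' @slot p_duplicate_contig probability a clean contig spawns a mutated
#'   shorter near-duplicate (same virus population).
#' @slot n_samples number of metagenome samples (paired in twos:
#'   virus-enriched then prokaryote-enriched).
#' @slot depth_mean mean per-position read depth (reads/bp).
#' @slot breadth fraction of positions covered in generated depth profiles.
#' @slot repeat_arm arm length (bp) of planted exact repeats.
#' @slot seed RNG seed; a fixed seed gives byte-identical outputs.
#' @export
setClass("AmgSimParams", representation(
  n_genomes = "integer",
  genome_length_range = "integer",
  p_amg_genome = "numeric",
  amg_count_mean = "numeric",
  amg_count_max = "integer",
  n_contigs = "integer",
  contig_length_median = "numeric",
  contig_length_sdlog = "numeric",
  p_amg_contig = "numeric",
  p_prophage_contig = "numeric",
  p_blacklist_contig = "numeric",
  p_offtarget_contig = "numeric",
  p_duplicate_contig = "numeric",
  n_samples = "integer",
  depth_mean = "numeric",
  breadth = "numeric",
  repeat_arm = "integer",
  seed = "integer"
))

setValidity("AmgSimParams", function(object) {
  msg <- character(0)
  for (p in c("p_amg_genome", "p_amg_contig", "p_prophage_contig",
              "p_blacklist_contig", "p_offtarget_contig",
              "p_duplicate_contig", "breadth")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste0(p, " must be a probability in [0, 1]"))
  }
  r <- object@genome_length_range
  if (length(r) != 2L || any(r <= 0L))
    msg <- c(msg, "genome_length_range must be two positive lengths")
  else if (r[1] > r[2])
    msg <- c(msg, "genome_length_range is degenerate (min > max)")
  if (object@contig_length_median <= 0)
    msg <- c(msg, "contig_length_median must be positive")
  if (object@amg_count_max < 1L)
    msg <- c(msg, "amg_count_max must be >= 1")
  if (object@amg_count_mean < 1 || object@amg_count_mean > object@amg_count_max)
    msg <- c(msg, "amg_count_mean must lie in [1, amg_count_max]")
  p <- object@p_prophage_contig + object@p_blacklist_contig +
    object@p_offtarget_contig
  if (p > 1)
    msg <- c(msg, "contig kind probabilities sum to more than 1")
  if (object@n_samples %% 2L != 0L)
    msg <- c(msg, "n_samples must be even (samples are paired)")
  if (object@depth_mean < 0) msg <- c(msg, "depth_mean must be >= 0")
  if (object@repeat_arm < 10L) msg <- c(msg, "repeat_arm must be >= 10")
  if (length(msg)) msg else TRUE
})

#' A set of survey contigs with virus evidence
#'
#' Couples contig sequences with per-contig virus evidence: the virus
#' identification score, the per-classifier-group score matrix, and
#' CheckV-style viral-region intervals.
#'
#' @slot sequences a [Biostrings::DNAStringSet] (may be length zero when only
#'   evidence tables are available; sequence-dependent steps then degrade
#'   gracefully).
#' @slot info a DataFrame with columns `contig_id`, `length`,
#'   `source_fraction` ("virus-enriched"/"prokaryote-enriched"),
#'   `virsorter_score`, and `circular`.
#' @slot classifierScores numeric matrix, contigs x classifier groups.
#' @slot viralRegions an [IRanges::IRangesList], one element per contig, of
#'   1-based inclusive viral-region intervals.
#' @export
setClass("ContigSet", contains = "Annotated", representation(
  sequences = "DNAStringSet",
  info = "DataFrame",
  classifierScores = "matrix",
  viralRegions = "IRangesList"
))

setValidity("ContigSet", function(object) {
  msg <- character(0)
  need <- c("contig_id", "length", "source_fraction", "virsorter_score")
  if (!all(need %in% colnames(object@info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  n <- nrow(object@info)
  ids <- object@info$contig_id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated contig ids")
  if (any(object@info$length < 1L)) msg <- c(msg, "contig lengths must be >= 1")
  sc <- object@info$virsorter_score
  if (any(!is.na(sc) & (sc < 0 | sc > 1)))
    msg <- c(msg, "virsorter scores must be in [0, 1]")
  if (nrow(object@classifierScores) != n)
    msg <- c(msg, "classifierScores must have one row per contig")
  if (length(object@viralRegions) != n)
    msg <- c(msg, "viralRegions must have one element per contig")
  else {
    hi <- vapply(seq_len(n), function(i) {
      r <- object@viralRegions[[i]]
      length(r) == 0L ||
        (min(IRanges::start(r)) >= 1L &&
           max(IRanges::end(r)) <= object@info$length[i])
    }, logical(1))
    if (!all(hi)) msg <- c(msg, "viral regions outside contig bounds")
  }
  if (length(object@sequences) &&
      (length(object@sequences) != n ||
         !identical(unname(Biostrings::width(object@sequences)),
                    as.integer(object@info$length))))
    msg <- c(msg, "sequences inconsistent with info lengths")
  if (length(msg)) msg else TRUE
})

#' Species-rank virus populations (vOTUs)
#'
#' The result of greedy longest-first clustering of screened contigs at the
#' 95\% ANI / 80\% aligned-fraction species rank. Each population's
#' representative is its longest member (ties broken by lexicographically
#' smallest id).
#'
#' @slot membership DataFrame with columns `population_id`, `representative`,
#'   `member`, `rep_length`.
#' @export
setClass("VirusPopulations", contains = "Annotated", representation(
  membership = "DataFrame"
))

setValidity("VirusPopulations", function(object) {
  m <- object@membership
  need <- c("population_id", "representative", "member", "rep_length")
  if (!all(need %in% colnames(m)))
    return(paste("membership must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$member))
    return("populations must partition the contigs (duplicated member)")
  bad <- !vapply(split(seq_len(nrow(m)), m$population_id), function(i) {
    m$representative[i][1] %in% m$member[i]
  }, logical(1))
  if (any(bad)) return("representative must be a member of its population")
  TRUE
})

#' An AMG catalog with curation decision trail
#'
#' Holds AMG candidates at the permissive tier together with the outcome of
#' every conservative curation rule. Candidates whose `tier` is
#' `"conservative"` passed all rules; the decision trail records each rule's
#' outcome for every candidate.
#'
#' @slot candidates DataFrame of gene-level candidates (`gene_id`,
#'   `contig_id`, `start`, `end`, `strand`, `bit_score`, `auxiliary_score`,
#'   `ko`, `module_ids`, `known_amg`, `tier`).
#' @slot decisions DataFrame decision trail (`gene_id`, `rule_id`, `outcome`,
#'   `reason`).
#' @export
setClass("AmgCatalog", contains = "Annotated", representation(
  candidates = "DataFrame",
  decisions = "DataFrame"
))

setValidity("AmgCatalog", function(object) {
  need <- c("gene_id", "contig_id", "start", "end", "bit_score",
            "auxiliary_score", "tier")
  if (!all(need %in% colnames(object@candidates)))
    return(paste("candidates must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@candidates) &&
      !all(object@candidates$tier %in% c("permissive", "conservative")))
    return("tier must be 'permissive' or 'conservative'")
  TRUE
})

#' A mock community of complete reference genomes
#'
#' Complete virus genomes with gene annotations and a genome-to-population
#' map, used to benchmark how genome fragmentation hides AMG-carrying
#' populations.
#'
#' @slot sequences genome sequences ([Biostrings::DNAStringSet]).
#' @slot genes DataFrame of gene calls with `genome_id`, coordinates, scores,
#'   KO/module assignments and the planted `is_amg` truth flag.
#' @slot populations DataFrame mapping `genome_id` to `population_id`.
#' @export
setClass("MockCommunity", contains = "Annotated", representation(
  sequences = "DNAStringSet",
  genes = "DataFrame",
  populations = "DataFrame"
))

#' Fragments tiled from complete genomes
#'
#' @slot fragments DataFrame (`fragment_id`, `genome_id`, `population_id`,
#'   `start`, `end`, `length`, `n_amgs`) for populations kept within the
#'   percentile length bounds.
#' @slot p10,p90 empirical 10th/90th percentile bounds (bp) of the survey
#'   length distribution.
#' @slot excluded ids of populations dropped because a fragment fell outside
#'   the bounds.
#' @export
setClass("FragmentSet", contains = "Annotated", representation(
  fragments = "DataFrame",
  p10 = "numeric",
  p90 = "numeric",
  excluded = "character"
))

#' Observed-versus-true AMG-carrying fraction conversion estimate
#'
#' @slot f_true fraction of kept populations with >= 1 AMG on the complete
#'   genome.
#' @slot f_obs fraction of resampled fragments with >= 1 observable AMG.
#' @slot factor `f_true / f_obs`, the multiplier that converts observed
#'   survey fractions into estimated true fractions.
#' @slot n_resampled number of resampled fragments used.
#' @slot seed RNG seed used for the bootstrap.
#' @slot ci bootstrap confidence interval for the factor (length 2, or
#'   `NA` when no bootstrap was requested).
#' @export
setClass("ConversionEstimate", representation(
  f_true = "numeric",
  f_obs = "numeric",
  factor = "numeric",
  n_resampled = "integer",
  seed = "integer",
  ci = "numeric"
))

setValidity("ConversionEstimate", function(object) {
  if (object@f_true < 0 || object@f_true > 1) return("f_true outside [0, 1]")
  if (object@f_obs < 0 || object@f_obs > 1) return("f_obs outside [0, 1]")
  TRUE
})

#' A parsed KEGG-style module definition
#'
#' Top-level space-separated tokens (outside parentheses) are pathway steps;
#' within a step `,` is OR, `+` (or a space inside parentheses) is AND, a
#' `-`-prefixed component is optional and ignored for satisfaction, and `--`
#' is a gap step that counts in the denominator but is never satisfied.
#'
#' @slot module_id module identifier.
#' @slot definition the raw definition string.
#' @slot steps list of parsed boolean trees, one per counted step.
#' @slot skipped top-level optional (`-`-prefixed) tokens excluded from the
#'   step count.
#' @export
setClass("ModuleDefinition", representation(
  module_id = "character",
  definition = "character",
  steps = "list",
  skipped = "character"
))

#' Per-sample per-contig depth profiles
#'
#' Run-length encoded per-position depth vectors keyed by
#' `"<contig_id>|<sample_id>"`, with per-profile metadata.
#'
#' @slot depths an [S4Vectors::RleList], one run-length encoded depth vector
#'   per contig x sample combination.
#' @slot info DataFrame with `contig_id`, `sample_id`, `total_reads`.
#' @export
setClass("DepthProfileSet", contains = "Annotated", representation(
  depths = "RleList",
  info = "DataFrame"
))

setValidity("DepthProfileSet", function(object) {
  if (length(object@depths) != nrow(object@info))
    return("one depth vector per info row required")
  if (any(object@info$total_reads <= 0))
    return("total_reads must be positive")
  TRUE
})

#' Gene clusters from greedy incremental clustering
#'
#' @slot membership DataFrame (`cluster_id`, `representative`, `member`,
#'   `is_reference`).
#' @export
setClass("GeneClusters", contains = "Annotated", representation(
  membership = "DataFrame"
))

#' End-to-end run configuration
#'
#' Houses every numeric threshold of the pipeline with the survey defaults:
#' screening (>= 5 kb, score >= 0.75; confident score >= 0.95), permissive
#' calling (bit score >= 60, auxiliary score <= 3), population clustering
#' (ANI >= 95, aligned fraction >= 0.80), gene clustering (identity 0.90,
#' member coverage 0.90), novelty clustering (identity 0.30, coverage 0.60),
#' fragmentation percentiles (10/90) and 4000 resampled fragments, pathway
#' completeness >= 0.75, read filters (identity >= 0.95, read coverage >=
#' 0.75), trimmed mean (5\% both tails) and breadth >= 0.70.
#'
#' @slot sim the [AmgSimParams] used when synthetic generation is enabled.
#' @slot seed master RNG seed for pipeline stages downstream of simulation.
#' @slot outdir optional output directory ("" to keep results in memory).
#' @slot min_len,min_score,confident_score screening thresholds.
#' @slot min_bitscore,max_aux permissive-catalog thresholds.
#' @slot min_ani,min_af population clustering thresholds.
#' @slot gene_cluster_id,gene_cluster_cov,novelty_id,novelty_cov clustering
#'   thresholds.
#' @slot frag_lower_q,frag_upper_q,n_resample mock-community settings.
#' @slot completeness_threshold stepwise-completeness cut-off.
#' @slot read_min_identity,read_min_cov,trim,min_breadth abundance filters.
#' @slot repeat_min_arm,end_window prophage-end detection settings.
#' @export
setClass("AmgRunConfig", representation(
  sim = "AmgSimParams",
  seed = "integer",
  outdir = "character",
  min_len = "numeric",
  min_score = "numeric",
  confident_score = "numeric",
  min_bitscore = "numeric",
  max_aux = "integer",
  min_ani = "numeric",
  min_af = "numeric",
  gene_cluster_id = "numeric",
  gene_cluster_cov = "numeric",
  novelty_id = "numeric",
  novelty_cov = "numeric",
  frag_lower_q = "numeric",
  frag_upper_q = "numeric",
  n_resample = "integer",
  completeness_threshold = "numeric",
  read_min_identity = "numeric",
  read_min_cov = "numeric",
  trim = "numeric",
  min_breadth = "numeric",
  repeat_min_arm = "integer",
  end_window = "integer"
))

setValidity("AmgRunConfig", function(object) {
  msg <- character(0)
  for (p in c("min_score", "confident_score", "min_af", "gene_cluster_id",
              "gene_cluster_cov", "novelty_id", "novelty_cov",
              "completeness_threshold", "read_min_identity", "read_min_cov",
              "min_breadth")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste0(p, " outside [0, 1]"))
  }
  if (object@min_ani < 0 || object@min_ani > 100)
    msg <- c(msg, "min_ani outside [0, 100]")
  if (object@trim < 0 || object@trim >= 0.5)
    msg <- c(msg, "trim outside [0, 0.5)")
  if (object@frag_lower_q >= object@frag_upper_q)
    msg <- c(msg, "frag_lower_q must be below frag_upper_q")
  if (object@max_aux < 1L || object@max_aux > 5L)
    msg <- c(msg, "max_aux outside 1..5")
  if (length(msg)) msg else TRUE
})
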