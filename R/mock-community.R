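# Genome-fragmentation mock community: tile complete genomes into fragments
# whose lengths follow the survey length distribution truncated to its
# 10th-90th percentiles, resample fragments to mimic the survey
# distribution, and estimate the conversion factor relating the observed
# (per-fragment) AMG-carrying fraction to the true per-population fraction.

#' Fragment complete genomes within survey length percentiles
#'
#' Computes the empirical 10th/90th percentile bounds of the survey length
#' distribution (linear interpolation) and tiles each genome left-to-right
#' with fragment lengths drawn from the empirical distribution truncated to
#' those bounds. A terminal remainder shorter than the lower bound (or a
#' genome shorter than it) makes the genome's population fall outside the
#' length cut-off: with `remainder = "exclude"` (default) the whole
#' population is excluded, mirroring the drop of out-of-bounds mock
#' populations; `remainder = "merge"` folds the remainder into the last
#' fragment instead. An AMG is counted in a fragment iff its gene interval
#' is fully contained.
#'
#' @param community a [MockCommunity].
#' @param survey_lengths bp lengths of the observed AMG-carrying survey
#'   populations (non-empty).
#' @param seed RNG seed for the fragment-length draws.
#' @param remainder what to do with sub-bound terminal remainders.
#' @param lower_q,upper_q percentile bounds (defaults 0.10 / 0.90).
#' @return a [FragmentSet].
#' @export
fragmentGenomes <- function(community, survey_lengths, seed = 1L,
                            remainder = c("exclude", "merge"),
                            lower_q = 0.10, upper_q = 0.90) {
  remainder <- match.arg(remainder)
  stopifnot(is(community, "MockCommunity"))
  if (!length(survey_lengths)) stop("survey_lengths must be non-empty")
  q <- stats::quantile(survey_lengths, c(lower_q, upper_q), type = 7,
                       names = FALSE)
  p10 <- q[1]; p90 <- q[2]
  pool <- survey_lengths[survey_lengths >= p10 & survey_lengths <= p90]
  if (!length(pool)) stop("no survey lengths within the percentile bounds")
  set.seed(.checkCount(seed, "seed"))

  pops <- as.data.frame(genomePopulations(community))
  genes <- as.data.frame(genomeGenes(community))
  glens <- Biostrings::width(genomeSequences(community))
  gids <- names(genomeSequences(community))
  frag_rows <- list()
  bad_pops <- character(0)
  fcount <- 0L
  for (gi in seq_along(gids)) {
    gid <- gids[gi]
    L <- glens[gi]
    pop <- pops$population_id[match(gid, pops$genome_id)]
    lens <- integer(0)
    remaining <- L
    while (remaining > p90) {
      lens <- c(lens, as.integer(.sampleVec(pool, 1L)))
      remaining <- L - sum(lens)
    }
    if (remaining >= p10) {
      lens <- c(lens, as.integer(remaining))
    } else if (remainder == "merge" && length(lens)) {
      lens[length(lens)] <- lens[length(lens)] + as.integer(remaining)
    } else {
      bad_pops <- c(bad_pops, pop)
      if (length(lens) || remaining > 0)
        lens <- c(lens, as.integer(remaining))  # recorded, then excluded
    }
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    gg <- genes[genes$genome_id == gid & genes$is_amg, , drop = FALSE]
    n_amgs <- vapply(seq_along(lens), function(f) {
      sum(gg$start >= starts[f] & gg$end <= ends[f])
    }, integer(1))
    frag_rows[[gi]] <- data.frame(
      fragment_id = sprintf("frag_%05d", fcount + seq_along(lens)),
      genome_id = gid, population_id = pop,
      start = starts, end = ends, length = lens, n_amgs = n_amgs,
      stringsAsFactors = FALSE)
    fcount <- fcount + length(lens)
  }
  frags <- do.call(rbind, frag_rows)
  bad_pops <- unique(bad_pops)
  if (length(bad_pops))
    message(length(bad_pops),
            " population(s) excluded (fragment outside length bounds)")
  kept <- frags[!(frags$population_id %in% bad_pops), , drop = FALSE]
  new("FragmentSet", fragments = DataFrame(kept),
      p10 = p10, p90 = p90, excluded = bad_pops)
}

#' Resample fragments to match a target length distribution
#'
#' Draws `n` fragments with replacement, weighting each source fragment by
#' the ratio of target to source length-bin mass (1-kb bins); bins absent
#' from the source get weight zero.
#'
#' @param frag_set a non-empty [FragmentSet].
#' @param target_lengths bp lengths whose distribution the resample should
#'   mimic (typically the survey lengths).
#' @param n number of fragments to draw (default 4000).
#' @param seed RNG seed.
#' @param bin bin width in bp (default 1000).
#' @return a data.frame of resampled fragments (rows repeat with
#'   multiplicity).
#' @export
resampleFragments <- function(frag_set, target_lengths, n = 4000L,
                              seed = 1L, bin = 1000L) {
  stopifnot(is(frag_set, "FragmentSet"))
  frags <- as.data.frame(fragmentTable(frag_set))
  if (!nrow(frags)) stop("empty fragment set")
  set.seed(.checkCount(seed, "seed"))
  src_bin <- floor(frags$length / bin)
  tgt_bin <- floor(target_lengths / bin)
  src_mass <- table(src_bin) / length(src_bin)
  tgt_mass <- table(tgt_bin) / length(tgt_bin)
  w <- vapply(src_bin, function(b) {
    key <- as.character(b)
    t <- tgt_mass[key]
    s <- src_mass[key]
    if (is.na(t)) 0 else as.numeric(t / s)
  }, numeric(1))
  if (all(w == 0))
    stop("source and target length distributions are disjoint")
  idx <- sample.int(nrow(frags), n, replace = TRUE, prob = w)
  out <- frags[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the observed-versus-true conversion factor
#'
#' `f_true` is the fraction of kept populations with at least one AMG on
#' the complete genome; `f_obs` is the fraction of resampled fragments with
#' at least one observable AMG (`f_obs_mode = "fragment"`, the default) or
#' the fraction of kept populations with at least one AMG-positive
#' resampled fragment (`"population"`). The conversion factor is
#' `f_true / f_obs`; an optional bootstrap over the resample gives a
#' confidence interval.
#'
#' @param community the [MockCommunity] providing population-level truth.
#' @param frag_set the [FragmentSet] (for the kept/excluded partition).
#' @param resampled resampled fragment data.frame from
#'   [resampleFragments()].
#' @param f_obs_mode `"fragment"` or `"population"`.
#' @param bootstrap number of bootstrap replicates (0 = no CI).
#' @param conf confidence level for the bootstrap interval.
#' @param seed RNG seed for the bootstrap.
#' @return a [ConversionEstimate].
#' @export
estimateConversionFactor <- function(community, frag_set, resampled,
                                     f_obs_mode = c("fragment", "population"),
                                     bootstrap = 0L, conf = 0.95,
                                     seed = 1L) {
  f_obs_mode <- match.arg(f_obs_mode)
  stopifnot(is(community, "MockCommunity"), is(frag_set, "FragmentSet"))
  pops <- as.data.frame(genomePopulations(community))
  genes <- as.data.frame(genomeGenes(community))
  amg_genomes <- unique(genes$genome_id[genes$is_amg])
  pop_has_amg <- vapply(split(pops$genome_id, pops$population_id),
                        function(g) any(g %in% amg_genomes), logical(1))
  kept_pops <- setdiff(names(pop_has_amg), excludedPopulations(frag_set))
  if (!length(kept_pops)) stop("no populations kept")
  f_true <- mean(pop_has_amg[kept_pops])

  obs_fun <- function(rs) {
    if (f_obs_mode == "fragment") mean(rs$n_amgs > 0L)
    else mean(vapply(kept_pops, function(p) {
      any(rs$n_amgs[rs$population_id == p] > 0L)
    }, logical(1)))
  }
  f_obs <- obs_fun(resampled)
  if (f_obs == 0) stop("no AMG observed in any resampled fragment")
  ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0L) {
    set.seed(.checkCount(seed, "seed"))
    bs <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(nrow(resampled), nrow(resampled), replace = TRUE)
      fo <- obs_fun(resampled[idx, , drop = FALSE])
      if (fo == 0) NA_real_ else f_true / fo
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  new("ConversionEstimate", f_true = f_true, f_obs = f_obs,
      factor = f_true / f_obs, n_resampled = nrow(resampled),
      seed = as.integer(seed), ci = ci)
}

#' Correct an observed AMG-carrying fraction
#'
#' Multiplies the observed fraction by the conversion factor, capped at 1.
#'
#' @param observed_fraction observed fraction in `[0, 1]`.
#' @param factor conversion factor (>= 0).
#' @return the corrected fraction.
#' @examples
#' applyConversion(51666 / 579904, 2.1)  # ~0.187
#' @export
applyConversion <- function(observed_fraction, factor) {
  .checkFraction(observed_fraction, "observed_fraction")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0)
    stop("factor must be a single non-negative number")
  min(1, observed_fraction * factor)
}
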