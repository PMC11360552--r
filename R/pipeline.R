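# End-to-end orchestration: screen -> cluster populations -> curate ->
# gene clusters / novelty -> mock-community conversion factor -> pathway
# classification -> abundance and KO enrichment, with a machine-readable
# report embedding the configuration snapshot.

#' Construct an end-to-end run configuration
#'
#' All thresholds default to the survey settings; see
#' [AmgRunConfig-class] for the list.
#'
#' @param sim an [AmgSimParams] for synthetic-input generation.
#' @param seed master seed for pipeline stages downstream of simulation.
#' @param outdir output directory, or `""` to keep everything in memory.
#' @param min_len,min_score,confident_score,min_bitscore,max_aux,min_ani,min_af
#'   screening, permissive-call and population thresholds.
#' @param gene_cluster_id,gene_cluster_cov,novelty_id,novelty_cov clustering
#'   thresholds.
#' @param frag_lower_q,frag_upper_q,n_resample mock-community settings.
#' @param completeness_threshold pathway completeness cut-off.
#' @param read_min_identity,read_min_cov,trim,min_breadth abundance filters.
#' @param repeat_min_arm,end_window prophage-end detection settings.
#' @return an [AmgRunConfig].
#' @export
amgRunConfig <- function(sim = amgSimParams(),
                         seed = 1L,
                         outdir = "",
                         min_len = 5000,
                         min_score = 0.75,
                         confident_score = 0.95,
                         min_bitscore = 60,
                         max_aux = 3L,
                         min_ani = 95,
                         min_af = 0.80,
                         gene_cluster_id = 0.90,
                         gene_cluster_cov = 0.90,
                         novelty_id = 0.30,
                         novelty_cov = 0.60,
                         frag_lower_q = 0.10,
                         frag_upper_q = 0.90,
                         n_resample = 4000L,
                         completeness_threshold = 0.75,
                         read_min_identity = 0.95,
                         read_min_cov = 0.75,
                         trim = 0.05,
                         min_breadth = 0.70,
                         repeat_min_arm = 20L,
                         end_window = 1000L) {
  new("AmgRunConfig", sim = sim, seed = .checkCount(seed, "seed"),
      outdir = outdir, min_len = min_len, min_score = min_score,
      confident_score = confident_score, min_bitscore = min_bitscore,
      max_aux = as.integer(max_aux), min_ani = min_ani, min_af = min_af,
      gene_cluster_id = gene_cluster_id, gene_cluster_cov = gene_cluster_cov,
      novelty_id = novelty_id, novelty_cov = novelty_cov,
      frag_lower_q = frag_lower_q, frag_upper_q = frag_upper_q,
      n_resample = .checkCount(n_resample, "n_resample", min = 1),
      completeness_threshold = completeness_threshold,
      read_min_identity = read_min_identity, read_min_cov = read_min_cov,
      trim = trim, min_breadth = min_breadth,
      repeat_min_arm = .checkCount(repeat_min_arm, "repeat_min_arm",
                                   min = 10),
      end_window = .checkCount(end_window, "end_window", min = 1))
}

.configSnapshot <- function(config) {
  slots <- setdiff(slotNames("AmgRunConfig"), "sim")
  vals <- lapply(slots, function(s) slot(config, s))
  names(vals) <- slots
  simv <- lapply(slotNames("AmgSimParams"),
                 function(s) slot(config@sim, s))
  names(simv) <- slotNames("AmgSimParams")
  c(vals, list(sim = simv))
}

# extract AMG nucleotide sequences (reverse-complemented on "-" strand)
.amgSequences <- function(cand, contigs) {
  seqs <- contigSequences(contigs)
  out <- vapply(seq_len(nrow(cand)), function(i) {
    s <- substr(as.character(seqs[[cand$contig_id[i]]]),
                cand$start[i], cand$end[i])
    if (identical(cand$strand[i], "-")) .revcomp(s) else s
  }, character(1))
  names(out) <- cand$gene_id
  out
}

.stageFail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full survey pipeline on synthetic inputs
#'
#' Executes screen, population clustering, permissive and conservative
#' curation, gene clustering and novelty, the mock-community conversion
#' factor, pathway classification, and abundance/enrichment on generator
#' outputs, and assembles a machine-readable report with the configuration
#' snapshot embedded. Deterministic given the configuration (two runs with
#' the same config produce identical reports). When `outdir` is set, all
#' intermediate tables and a JSON report are written there.
#'
#' @param config an [AmgRunConfig].
#' @return the report, an invisible list; see `names()` of the result.
#' @export
runPipeline <- function(config = amgRunConfig()) {
  stopifnot(is(config, "AmgRunConfig"))
  validObject(config)
  out <- list(config = .configSnapshot(config))

  sim <- tryCatch(generateSurveyContigs(config@sim),
                  error = function(e) .stageFail("simulate", e))
  community <- tryCatch(generateReferenceGenomes(config@sim),
                        error = function(e) .stageFail("simulate", e))

  screened <- tryCatch(
    screenContigs(sim$contigs, config@min_len, config@min_score),
    error = function(e) .stageFail("screen", e))
  out$n_contigs_input <- length(sim$contigs)
  out$n_contigs_screened <- length(screened)

  pops <- tryCatch({
    sims <- similarityTable(contigSequences(screened))
    clusterPopulations(screened, sims, config@min_ani, config@min_af)
  }, error = function(e) .stageFail("cluster-populations", e))
  out$n_populations <- nPopulations(pops)

  genes <- sim$genes[sim$genes$contig_id %in% contigIds(screened), ,
                     drop = FALSE]
  catalog <- tryCatch({
    perm <- callPermissive(genes, screened, config@min_bitscore,
                           config@max_aux)
    ends <- detectPhageEndsSet(screened, sim$trna,
                               min_arm = config@repeat_min_arm,
                               end_window = config@end_window)
    applyConservativeRules(perm, screened, genes, ends,
                           confident_score = config@confident_score)
  }, error = function(e) .stageFail("curate", e))
  cons_sum <- catalogSummary(catalog, pops, tier = "conservative")
  perm_sum <- catalogSummary(catalog, pops, tier = "permissive")
  out$n_amgs_permissive <- perm_sum$n_amgs
  out$n_amgs_conservative <- cons_sum$n_amgs
  out$mean_amgs_per_carrier <- cons_sum$mean_per_carrier
  out$observed_fraction_conservative <- cons_sum$observed_fraction
  out$observed_fraction_permissive <- perm_sum$observed_fraction

  cons <- as.data.frame(conservativeSet(catalog))
  novelty <- tryCatch({
    if (nrow(cons) >= 2L) {
      nt <- .amgSequences(cons, screened)
      gc <- greedyCluster(nt, config@gene_cluster_id,
                          config@gene_cluster_cov, cov_of = "member")
      gc_reps <- unique(as.data.frame(clusterMembership(gc))$representative)
      prot <- vapply(nt[gc_reps], function(s) {
        n <- nchar(s) - nchar(s) %% 3L
        as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, 1L, n)),
          if.fuzzy.codon = "X"))
      }, character(1))
      # synthetic published-reference panel: lightly diverged copies of a
      # deterministic subset of the catalog proteins
      set.seed(config@seed)
      n_ref <- floor(0.6 * length(prot))
      ref_idx <- sort(.sampleVec(seq_along(prot), n_ref))
      refs <- vapply(prot[ref_idx], function(p) {
        ch <- strsplit(p, "")[[1]]
        hit <- which(stats::runif(length(ch)) < 0.05)
        ch[hit] <- sample(c("A", "G", "L", "S", "V", "T"), length(hit),
                          replace = TRUE)
        paste(ch, collapse = "")
      }, character(1))
      names(refs) <- paste0("ref_", seq_along(refs))
      nv <- assessNovelty(prot, refs, config@novelty_id, config@novelty_cov)
      list(gene_clusters = gc, novelty = nv)
    } else list(gene_clusters = NULL, novelty = NULL)
  }, error = function(e) .stageFail("cluster-genes/novelty", e))
  if (!is.null(novelty$novelty)) {
    out$n_gene_clusters <- length(unique(
      as.data.frame(clusterMembership(novelty$gene_clusters))$cluster_id))
    out$percent_novel <- novelty$novelty$percent_novel
  }

  conversion <- tryCatch({
    m <- as.data.frame(populationMembership(pops))
    pop_of <- stats::setNames(m$population_id, m$member)
    carrier <- unique(pop_of[cons$contig_id])
    lens <- m$rep_length[!duplicated(m$population_id)]
    names(lens) <- m$population_id[!duplicated(m$population_id)]
    survey_lengths <- as.numeric(lens[carrier])
    if (length(survey_lengths) < 3L)
      survey_lengths <- as.numeric(lens)  # too few carriers at tiny scale
    fs <- fragmentGenomes(community, survey_lengths, seed = config@seed,
                          lower_q = config@frag_lower_q,
                          upper_q = config@frag_upper_q)
    rs <- resampleFragments(fs, survey_lengths, n = config@n_resample,
                            seed = config@seed + 1L)
    ce <- estimateConversionFactor(community, fs, rs, bootstrap = 200L,
                                   seed = config@seed + 2L)
    list(frag_set = fs, resampled = rs, estimate = ce)
  }, error = function(e) .stageFail("mockfactor", e))
  ce <- conversion$estimate
  out$conversion_factor <- conversionFactor(ce)
  out$conversion_f_true <- trueFraction(ce)
  out$conversion_f_obs <- observedFraction(ce)
  out$corrected_fraction_conservative <- applyConversion(
    cons_sum$observed_fraction, conversionFactor(ce))
  out$corrected_fraction_permissive <- applyConversion(
    perm_sum$observed_fraction, conversionFactor(ce))

  pathways <- tryCatch({
    mods <- toyModuleSet()
    all_kos <- unique(unlist(regmatches(
      mods$definition, gregexpr("K[0-9]{5}", mods$definition))))
    set.seed(config@seed + 3L)
    microbial_kos <- sort(.sampleVec(all_kos,
                                     floor(0.85 * length(all_kos))))
    viral_kos <- unique(cons$ko[!is.na(cons$ko)])
    classifyPathways(mods, microbial_kos, viral_kos,
                     threshold = config@completeness_threshold)
  }, error = function(e) .stageFail("pathways", e))
  out$pathway_summary <- as.list(attr(pathways, "summary"))

  abundance <- tryCatch({
    reps <- representatives(pops)
    rep_lens <- contigLengths(screened)[unname(reps)]
    names(rep_lens) <- unname(reps)
    ns <- config@sim@n_samples
    sample_ids <- sprintf("S%02d", seq_len(ns))
    dp <- generateDepthProfiles(rep_lens, sample_ids,
                                depth_mean = config@sim@depth_mean,
                                breadth = config@sim@breadth,
                                seed = config@seed + 4L)
    pairing <- data.frame(
      sample_id = sample_ids,
      pair_id = sprintf("pair%02d", ceiling(seq_len(ns) / 2)))
    pa <- populationAbundance(pops, dp, pairing, trim = config@trim,
                              min_breadth = config@min_breadth)
    set.seed(config@seed + 5L)
    viral_kos <- unique(cons$ko[!is.na(cons$ko)])
    mk <- stats::setNames(stats::rlnorm(length(viral_kos),
                                        log(mean(pa) + 1e-9), 0.5),
                          viral_kos)
    enr <- koEnrichment(catalog, pops, pa, mk)
    list(profiles = dp, matrix = pa, pairing = pairing, enrichment = enr)
  }, error = function(e) .stageFail("abundance/enrich", e))
  out$n_enriched_kos <- sum(abundance$enrichment$enriched)
  out$enrichment <- abundance$enrichment

  if (nzchar(config@outdir)) {
    dir.create(config@outdir, showWarnings = FALSE, recursive = TRUE)
    writeSimulatedSurvey(sim, file.path(config@outdir, "simulated"))
    writePopulations(pops, file.path(config@outdir, "populations.tsv"))
    writeAmgTsv(as.data.frame(amgCandidates(catalog)),
                file.path(config@outdir, "amg_candidates.tsv"))
    writeAmgTsv(as.data.frame(amgDecisions(catalog)),
                file.path(config@outdir, "amg_decisions.tsv"))
    writeAmgTsv(as.data.frame(fragmentTable(conversion$frag_set)),
                file.path(config@outdir, "fragments.tsv"))
    writeAmgTsv(conversion$resampled,
                file.path(config@outdir, "fragments_resampled.tsv"))
    writeAmgTsv(pathways, file.path(config@outdir, "pathways.tsv"))
    writeDepthProfiles(abundance$profiles,
                       file.path(config@outdir, "depth_profiles.tsv"))
    writeAmgTsv(abundance$enrichment,
                file.path(config@outdir, "ko_enrichment.tsv"))
    jsonlite::write_json(
      out[setdiff(names(out), "enrichment")],
      file.path(config@outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$populations <- pops
  out$catalog <- catalog
  out$pathways <- pathways
  invisible(out)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults. Keys under
#' `sim:` configure the synthetic generator.
#'
#' @param path YAML file path.
#' @return an [AmgRunConfig].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  known <- names(formals(amgRunConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(amgSimParams)))
    if (length(bad))
      stop("unknown sim config keys: ", paste(bad, collapse = ", "))
    y$sim <- do.call(amgSimParams, sim_args)
  }
  do.call(amgRunConfig, y)
}
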