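# Accessor and show() methods for the S4 containers.

#' @rdname ContigSet-class
#' @export
setMethod("contigIds", "ContigSet", function(x) x@info$contig_id)
#' @rdname ContigSet-class
#' @export
setMethod("contigLengths", "ContigSet", function(x) {
  stats::setNames(as.integer(x@info$length), x@info$contig_id)
})
#' @rdname ContigSet-class
#' @export
setMethod("contigSequences", "ContigSet", function(x) x@sequences)
#' @rdname ContigSet-class
#' @export
setMethod("virsorterScores", "ContigSet", function(x) {
  stats::setNames(x@info$virsorter_score, x@info$contig_id)
})
#' @rdname ContigSet-class
#' @export
setMethod("classifierScores", "ContigSet", function(x) x@classifierScores)
#' @rdname ContigSet-class
#' @export
setMethod("viralRegions", "ContigSet", function(x) x@viralRegions)
#' @rdname ContigSet-class
#' @export
setMethod("contigInfo", "ContigSet", function(x) x@info)

setMethod("show", "ContigSet", function(object) {
  n <- nrow(object@info)
  cat("ContigSet with", n, "contigs\n")
  if (n) {
    cat("  length range:", min(object@info$length), "-",
        max(object@info$length), "bp\n")
    cat("  sequences attached:", length(object@sequences) > 0L, "\n")
    cat("  fractions:",
        paste(names(table(object@info$source_fraction)), collapse = ", "),
        "\n")
  }
})

# subset a ContigSet by contig id or logical/integer index
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@info$contig_id)
  new("ContigSet",
      sequences = if (length(x@sequences)) x@sequences[i]
                  else x@sequences,
      info = x@info[i, , drop = FALSE],
      classifierScores = x@classifierScores[i, , drop = FALSE],
      viralRegions = x@viralRegions[i],
      metadata = metadata(x))
})

#' @export
setMethod("length", "ContigSet", function(x) nrow(x@info))

#' @rdname VirusPopulations-class
#' @export
setMethod("populationMembership", "VirusPopulations",
          function(x) x@membership)
#' @rdname VirusPopulations-class
#' @export
setMethod("nPopulations", "VirusPopulations", function(x) {
  length(unique(x@membership$population_id))
})
#' @rdname VirusPopulations-class
#' @export
setMethod("representatives", "VirusPopulations", function(x) {
  m <- x@membership
  keep <- !duplicated(m$population_id)
  stats::setNames(m$representative[keep], m$population_id[keep])
})

setMethod("show", "VirusPopulations", function(object) {
  m <- object@membership
  np <- length(unique(m$population_id))
  cat("VirusPopulations:", np, "populations over", nrow(m), "contigs\n")
  if (np) {
    sz <- table(m$population_id)
    cat("  singletons:", sum(sz == 1L), " largest:", max(sz), "\n")
  }
})

#' @rdname AmgCatalog-class
#' @export
setMethod("amgCandidates", "AmgCatalog", function(x) x@candidates)
#' @rdname AmgCatalog-class
#' @export
setMethod("amgDecisions", "AmgCatalog", function(x) x@decisions)
#' @rdname AmgCatalog-class
#' @export
setMethod("conservativeSet", "AmgCatalog", function(x) {
  x@candidates[x@candidates$tier == "conservative", , drop = FALSE]
})
#' @rdname AmgCatalog-class
#' @export
setMethod("permissiveSet", "AmgCatalog", function(x) x@candidates)

setMethod("show", "AmgCatalog", function(object) {
  n <- nrow(object@candidates)
  nc <- sum(object@candidates$tier == "conservative")
  cat("AmgCatalog:", n, "permissive candidates;", nc, "conservative\n")
  if (nrow(object@decisions)) {
    fails <- object@decisions[object@decisions$outcome == "fail", ]
    if (nrow(fails)) {
      tab <- table(fails$rule_id)
      cat("  rejections:",
          paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                collapse = " "), "\n")
    }
  }
})

#' @rdname MockCommunity-class
#' @export
setMethod("genomeSequences", "MockCommunity", function(x) x@sequences)
#' @rdname MockCommunity-class
#' @export
setMethod("genomeGenes", "MockCommunity", function(x) x@genes)
#' @rdname MockCommunity-class
#' @export
setMethod("genomePopulations", "MockCommunity", function(x) x@populations)

setMethod("show", "MockCommunity", function(object) {
  n <- length(object@sequences)
  cat("MockCommunity:", n, "genomes,",
      length(unique(object@populations$population_id)), "populations\n")
  if (nrow(object@genes)) {
    amg <- object@genes$is_amg
    cat("  genes:", nrow(object@genes), " AMGs:", sum(amg), "\n")
  }
})

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentTable", "FragmentSet", function(x) x@fragments)
#' @rdname FragmentSet-class
#' @export
setMethod("excludedPopulations", "FragmentSet", function(x) x@excluded)
#' @rdname FragmentSet-class
#' @export
setMethod("fragmentBounds", "FragmentSet", function(x) {
  c(p10 = x@p10, p90 = x@p90)
})

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet:", nrow(object@fragments), "fragments within [",
      round(object@p10), ",", round(object@p90), "] bp;",
      length(object@excluded), "populations excluded\n")
})

#' @rdname ConversionEstimate-class
#' @export
setMethod("conversionFactor", "ConversionEstimate", function(x) x@factor)
#' @rdname ConversionEstimate-class
#' @export
setMethod("observedFraction", "ConversionEstimate", function(x) x@f_obs)
#' @rdname ConversionEstimate-class
#' @export
setMethod("trueFraction", "ConversionEstimate", function(x) x@f_true)
#' @rdname ConversionEstimate-class
#' @export
setMethod("factorCI", "ConversionEstimate", function(x) x@ci)

setMethod("show", "ConversionEstimate", function(object) {
  cat(sprintf(
    "ConversionEstimate: f_true=%.3f f_obs=%.3f factor=%.2f (n=%d)\n",
    object@f_true, object@f_obs, object@factor, object@n_resampled))
  if (!anyNA(object@ci))
    cat(sprintf("  bootstrap CI: [%.2f, %.2f]\n", object@ci[1], object@ci[2]))
})

#' @rdname ModuleDefinition-class
#' @export
setMethod("moduleSteps", "ModuleDefinition", function(x) x@steps)
#' @rdname ModuleDefinition-class
#' @export
setMethod("nSteps", "ModuleDefinition", function(x) length(x@steps))

setMethod("show", "ModuleDefinition", function(object) {
  cat("ModuleDefinition", object@module_id, "with", length(object@steps),
      "steps\n  ", object@definition, "\n")
})

#' @rdname DepthProfileSet-class
#' @export
setMethod("depthProfiles", "DepthProfileSet", function(x) x@depths)
#' @rdname DepthProfileSet-class
#' @export
setMethod("profileInfo", "DepthProfileSet", function(x) x@info)

setMethod("show", "DepthProfileSet", function(object) {
  cat("DepthProfileSet:", nrow(object@info), "contig x sample profiles,",
      length(unique(object@info$sample_id)), "samples\n")
})

#' @rdname GeneClusters-class
#' @export
setMethod("clusterMembership", "GeneClusters", function(x) x@membership)

setMethod("show", "GeneClusters", function(object) {
  m <- object@membership
  cat("GeneClusters:", length(unique(m$cluster_id)), "clusters over",
      nrow(m), "sequences\n")
})

setMethod("show", "AmgSimParams", function(object) {
  cat("AmgSimParams (seed", object@seed, ")\n")
  cat("  genomes:", object@n_genomes, " P(AMG genome):",
      object@p_amg_genome, " AMG count mean/max:", object@amg_count_mean,
      "/", object@amg_count_max, "\n")
  cat("  contigs:", object@n_contigs, " median length:",
      object@contig_length_median, "bp\n")
  cat("  P(prophage):", object@p_prophage_contig, " P(blacklist):",
      object@p_blacklist_contig, " P(AMG contig):", object@p_amg_contig, "\n")
})

setMethod("show", "AmgRunConfig", function(object) {
  cat("AmgRunConfig (seed", object@seed, ")\n")
  cat("  screen: >=", object@min_len, "bp, score >=", object@min_score,
      "; confident score >=", object@confident_score, "\n")
  cat("  populations: ANI >=", object@min_ani, ", AF >=", object@min_af, "\n")
  cat("  permissive: bit >=", object@min_bitscore, ", aux <=",
      object@max_aux, "\n")
  cat("  resample:", object@n_resample, "fragments; completeness >=",
      object@completeness_threshold, "\n")
})
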