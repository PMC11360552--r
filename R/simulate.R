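# Synthetic-data generator: seeded mock genomes, survey contigs with
# ground-truth labels, depth profiles, and a toy KEGG module set. The
# generator provides the statistical structure the downstream analysis
# assumes (sporadic AMG placement, prophage contigs with tRNA/repeat-marked
# cellular flanks, blacklist contamination, lognormal contig lengths),
# so every stage is testable without downloads.

#' Construct synthetic-survey generator parameters
#'
#' Defaults mirror the modeled study conditions: 81 mock reference
#' populations, 86\% of them AMG-carrying with zero-truncated Poisson AMG
#' counts (mean 11.1, max 25), and survey contigs with median length
#' 12,608 bp. Contig-kind rates (prophage 5\%, blacklist 8\%, off-target
#' 10\%) approximate the survey's curation removal rates while keeping every
#' kind represented at desk scale.
#'
#' @param n_genomes number of complete mock genomes (one population each).
#' @param genome_length_range bp range for mock genome lengths.
#' @param p_amg_genome probability a mock genome carries at least one AMG.
#' @param amg_count_mean,amg_count_max zero-truncated Poisson AMG count
#'   parameters for AMG-carrying genomes.
#' @param n_contigs number of base survey contigs.
#' @param contig_length_median,contig_length_sdlog lognormal contig length
#'   parameters (bp; floored at 5 kb).
#' @param p_amg_contig probability a clean virus contig carries AMGs.
#' @param p_prophage_contig probability of a prophage contig with cellular
#'   flanks.
#' @param p_blacklist_contig probability of a blacklist-gene contig.
#' @param p_offtarget_contig probability of a contig built to fail screening.
#' @param p_duplicate_contig probability a clean contig spawns a mutated
#'   near-duplicate (same population).
#' @param n_samples number of samples (even; paired virus/prokaryote).
#' @param depth_mean mean read depth (reads/bp).
#' @param breadth covered fraction of positions in depth profiles.
#' @param repeat_arm planted repeat arm length (bp).
#' @param seed RNG seed.
#' @return an [AmgSimParams] object.
#' @examples
#' params <- amgSimParams(n_contigs = 20L, seed = 42L)
#' @export
amgSimParams <- function(n_genomes = 81L,
                         genome_length_range = c(30000L, 100000L),
                         p_amg_genome = 0.86,
                         amg_count_mean = 11.1,
                         amg_count_max = 25L,
                         n_contigs = 200L,
                         contig_length_median = 12608,
                         contig_length_sdlog = 0.45,
                         p_amg_contig = 0.25,
                         p_prophage_contig = 0.05,
                         p_blacklist_contig = 0.08,
                         p_offtarget_contig = 0.10,
                         p_duplicate_contig = 0.15,
                         n_samples = 4L,
                         depth_mean = 10,
                         breadth = 0.95,
                         repeat_arm = 25L,
                         seed = 1L) {
  new("AmgSimParams",
      n_genomes = .checkCount(n_genomes, "n_genomes"),
      genome_length_range = as.integer(genome_length_range),
      p_amg_genome = p_amg_genome,
      amg_count_mean = as.numeric(amg_count_mean),
      amg_count_max = .checkCount(amg_count_max, "amg_count_max", min = 1),
      n_contigs = .checkCount(n_contigs, "n_contigs"),
      contig_length_median = as.numeric(contig_length_median),
      contig_length_sdlog = as.numeric(contig_length_sdlog),
      p_amg_contig = p_amg_contig,
      p_prophage_contig = p_prophage_contig,
      p_blacklist_contig = p_blacklist_contig,
      p_offtarget_contig = p_offtarget_contig,
      p_duplicate_contig = p_duplicate_contig,
      n_samples = .checkCount(n_samples, "n_samples"),
      depth_mean = as.numeric(depth_mean),
      breadth = breadth,
      repeat_arm = .checkCount(repeat_arm, "repeat_arm", min = 10),
      seed = .checkCount(seed, "seed"))
}

#' Toy KEGG-style module set
#'
#' Ten small module definitions over a toy KO universe, exercising linear
#' steps, OR branches, AND complexes, optional components, and gap steps.
#'
#' @return a data.frame with columns `module_id` and `definition`.
#' @export
toyModuleSet <- function() {
  data.frame(
    module_id = sprintf("M%04d", 1:10),
    definition = c(
      "K00001 K00002 K00003 K00004",
      "(K00005,K00006) K00007+K00008",
      "K00010 -K00011 K00012",
      "K00013 K00014 -- K00015",
      "K00016+K00017+K00018",
      "(K00020+K00021),K00022 K00023",
      "K00024 (K00025,K00026,K00027)",
      "K00030 K00031 K00032 K00033 K00034 K00035",
      "K00040,K00041",
      "K00042 (K00043+K00044,K00045)"
    ),
    stringsAsFactors = FALSE
  )
}

# KO pools used by the generator; AMG KOs overlap the toy module universe so
# pathway mapping has signal, plus "novel-like" KOs outside any module.
.amgKoPool <- function() {
  c(sprintf("K%05d", c(1:8, 10:18, 20:27, 30:35, 40:45)),
    sprintf("K%05d", 101:112))
}

.houseKoPool <- function() sprintf("K%05d", 200:260)

# map KO -> comma list of toy modules containing it
.koModuleMap <- function() {
  mods <- toyModuleSet()
  kos <- regmatches(mods$definition,
                    gregexpr("K[0-9]{5}", mods$definition))
  map <- list()
  for (i in seq_len(nrow(mods))) {
    for (ko in unique(kos[[i]])) map[[ko]] <- c(map[[ko]], mods$module_id[i])
  }
  map
}

# lambda of a Poisson truncated to [1, M] with target mean m
.ztpoisLambda <- function(m, M) {
  f <- function(l) {
    k <- 1:M
    p <- stats::dpois(k, l)
    sum(k * p) / sum(p) - m
  }
  stats::uniroot(f, c(1e-6, 10 * m + 10))$root
}

.rztpois <- function(n, lambda, M) {
  k <- 1:M
  p <- stats::dpois(k, lambda)
  sample(k, n, replace = TRUE, prob = p)
}

# Tile genes (length a multiple of 3) along [1, L]; returns start/end/strand.
.layoutGenes <- function(L, gene_len = 900L, min_gap = 60L, max_gap = 180L) {
  starts <- integer(0)
  pos <- sample(30:150, 1L)
  while (pos + gene_len - 1L <= L - 30L) {
    starts <- c(starts, pos)
    pos <- pos + gene_len + sample(min_gap:max_gap, 1L)
  }
  if (!length(starts))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  data.frame(start = starts, end = starts + gene_len - 1L,
             strand = sample(c("+", "-"), length(starts), replace = TRUE),
             stringsAsFactors = FALSE)
}

.geneRow <- function(gene_id, contig_id, start, end, strand, is_amg,
                     komap, amg_pool, house_pool) {
  if (is_amg) {
    ko <- sample(amg_pool, 1L)
    mods <- komap[[ko]]
    data.frame(gene_id = gene_id, contig_id = contig_id, start = start,
               end = end, strand = strand,
               bit_score = round(stats::runif(1, 60, 300), 1),
               auxiliary_score = sample(1:3, 1L),
               ko = ko,
               module_ids = if (is.null(mods)) NA_character_
                            else paste(mods, collapse = ","),
               known_amg = stats::runif(1) < 0.5 | is.null(mods),
               category_flags = NA_character_,
               is_amg = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = gene_id, contig_id = contig_id, start = start,
               end = end, strand = strand,
               bit_score = round(stats::runif(1, 30, 300), 1),
               auxiliary_score = sample(1:5, 1L),
               ko = if (stats::runif(1) < 0.5) sample(house_pool, 1L)
                    else NA_character_,
               module_ids = NA_character_,
               known_amg = FALSE,
               category_flags = NA_character_,
               is_amg = FALSE, stringsAsFactors = FALSE)
  }
}

#' Generate complete mock reference genomes
#'
#' Draws `n_genomes` complete genomes (one population each), a fraction
#' `p_amg_genome` of which carry AMGs with zero-truncated Poisson counts
#' fitted to (`amg_count_mean`, `amg_count_max`). Genes carry bit scores,
#' auxiliary scores, and KO/module assignments from the generator's pools;
#' planted AMGs satisfy the permissive-catalog gates by construction.
#' Generator bookkeeping (per-genome AMG counts) is stored in
#' `metadata(x)$amg_counts`.
#'
#' @param params an [AmgSimParams] object.
#' @return a [MockCommunity].
#' @examples
#' com <- generateReferenceGenomes(amgSimParams(n_genomes = 5L, seed = 3L))
#' genomePopulations(com)
#' @export
generateReferenceGenomes <- function(params) {
  stopifnot(is(params, "AmgSimParams"))
  validObject(params)
  set.seed(params@seed)
  n <- params@n_genomes
  if (n == 0L) {
    return(new("MockCommunity",
               sequences = Biostrings::DNAStringSet(),
               genes = DataFrame(genome_id = character(0),
                                 gene_id = character(0)),
               populations = DataFrame(genome_id = character(0),
                                       population_id = character(0))))
  }
  lens <- as.integer(round(stats::runif(
    n, params@genome_length_range[1], params@genome_length_range[2])))
  ids <- sprintf("genome_%03d", seq_len(n))
  carries <- stats::runif(n) < params@p_amg_genome
  lambda <- .ztpoisLambda(params@amg_count_mean, params@amg_count_max)
  counts <- integer(n)
  counts[carries] <- .rztpois(sum(carries), lambda, params@amg_count_max)

  komap <- .koModuleMap()
  amg_pool <- .amgKoPool()
  house_pool <- .houseKoPool()
  seqs <- character(n)
  gene_rows <- vector("list", n)
  for (i in seq_len(n)) {
    seqs[i] <- .randomDna(lens[i])
    lay <- .layoutGenes(lens[i])
    ng <- nrow(lay)
    k <- min(counts[i], ng)
    counts[i] <- k
    amg_idx <- if (k > 0L) sort(sample(ng, k)) else integer(0)
    rows <- lapply(seq_len(ng), function(g) {
      .geneRow(sprintf("%s_g%03d", ids[i], g), ids[i],
               lay$start[g], lay$end[g], lay$strand[g],
               g %in% amg_idx, komap, amg_pool, house_pool)
    })
    gene_rows[[i]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, gene_rows)
  names(genes)[names(genes) == "contig_id"] <- "genome_id"
  sset <- Biostrings::DNAStringSet(seqs)
  names(sset) <- ids
  out <- new("MockCommunity",
             sequences = sset,
             genes = DataFrame(genes),
             populations = DataFrame(
               genome_id = ids,
               population_id = sprintf("mockpop_%03d", seq_len(n))))
  metadata(out)$amg_counts <- stats::setNames(counts, ids)
  out
}

# sample a contig length from the truncated lognormal survey distribution
.contigLength <- function(n, params, floor_bp = 5000) {
  l <- stats::rlnorm(n, meanlog = log(params@contig_length_median),
                     sdlog = params@contig_length_sdlog)
  as.integer(pmin(pmax(round(l), floor_bp), 10 * params@contig_length_median))
}

#' Generate survey contigs with ground-truth labels
#'
#' Emits contigs of several kinds with known truth: clean virus contigs
#' (viral region spanning the whole contig), prophage contigs whose internal
#' viral region is delimited by a planted tRNA feature and an exact
#' inverted or direct repeat pair (AMGs planted both inside the region and in
#' the cellular flanks), contigs carrying blacklist-category genes, contigs
#' designed to fail screening, and mutated near-duplicate contigs that
#' cluster with their parent population.
#'
#' @param params an [AmgSimParams] object.
#' @return a list with elements `contigs` ([ContigSet]), `genes`
#'   (annotation data.frame), `trna` (tRNA feature data.frame), and `truth`
#'   (list of `contigs` and `genes` truth data.frames).
#' @examples
#' sim <- generateSurveyContigs(amgSimParams(n_contigs = 15L, seed = 9L))
#' table(sim$truth$contigs$kind)
#' @export
generateSurveyContigs <- function(params) {
  stopifnot(is(params, "AmgSimParams"))
  validObject(params)
  set.seed(params@seed + 1L)
  n <- params@n_contigs
  komap <- .koModuleMap()
  amg_pool <- .amgKoPool()
  house_pool <- .houseKoPool()

  kinds <- character(n)
  u <- stats::runif(n)
  p1 <- params@p_prophage_contig
  p2 <- p1 + params@p_blacklist_contig
  p3 <- p2 + params@p_offtarget_contig
  kinds[u < p1] <- "prophage"
  kinds[u >= p1 & u < p2] <- "blacklist"
  kinds[u >= p2 & u < p3] <- "offtarget"
  kinds[u >= p3] <- "clean"

  lens <- .contigLength(n, params)
  lens[kinds == "prophage"] <- pmax(lens[kinds == "prophage"], 9000L)
  ids <- sprintf("contig_%04d", seq_len(n))

  seqs <- character(n)
  scores <- numeric(n)
  fractions <- character(n)
  regions <- vector("list", n)
  cls <- matrix(0, nrow = n, ncol = length(.CLASSIFIER_GROUPS),
                dimnames = list(ids, .CLASSIFIER_GROUPS))
  gene_tabs <- vector("list", n)
  trna_tabs <- vector("list", n)
  truth_c <- vector("list", n)
  truth_g <- vector("list", n)

  gcount <- 0L
  for (i in seq_len(n)) {
    L <- lens[i]
    kind <- kinds[i]
    s <- .randomDna(L)
    lay <- .layoutGenes(L)
    ng <- nrow(lay)
    fractions[i] <- if (kind == "prophage") "prokaryote-enriched"
                    else if (stats::runif(1) < 0.7) "virus-enriched"
                    else "prokaryote-enriched"

    dscore <- stats::runif(1, 0.55, 1.0)
    cls[i, ] <- pmax(0, dscore - stats::runif(length(.CLASSIFIER_GROUPS),
                                              0.05, 0.5))
    cls[i, "dsDNA phage"] <- dscore

    region <- IRanges::IRanges(1L, L)
    amg_rows <- integer(0)
    labels <- rep("none", ng)
    trna <- NULL

    if (kind == "offtarget") {
      if (stats::runif(1) < 0.5) {
        scores[i] <- stats::runif(1, 0.30, 0.749)   # fails score gate
      } else {
        scores[i] <- stats::runif(1, 0.75, 1.0)     # fails dsDNA-max gate
        other <- sample(setdiff(.CLASSIFIER_GROUPS, "dsDNA phage"), 1L)
        cls[i, other] <- cls[i, "dsDNA phage"] + 0.05
      }
    } else if (kind == "prophage") {
      scores[i] <- stats::runif(1, 0.75, 0.949)
      # viral region spans an internal run of genes with >=1 gene flanking
      # on both sides; boundaries padded so planted repeat arms sit at the
      # region edges without touching flank genes
      i0 <- max(2L, ceiling(ng * 0.3))
      i1 <- min(ng - 1L, floor(ng * 0.7))
      if (i1 < i0) { i0 <- 2L; i1 <- max(2L, ng - 1L) }
      rs <- max(2L, lay$start[i0] - 25L)
      re <- min(L - 1L, lay$end[i1] + 25L)
      region <- IRanges::IRanges(rs, re)
      # plant exact repeat arms at the region boundaries
      arm <- params@repeat_arm
      left_arm <- substr(s, rs, rs + arm - 1L)
      right_arm <- if (stats::runif(1) < 0.5) left_arm else .revcomp(left_arm)
      substr(s, re - arm + 1L, re) <- right_arm
      # tRNA feature just upstream of the 5' junction
      trna <- data.frame(contig_id = ids[i],
                         start = max(1L, rs - 120L),
                         end = max(1L, rs - 120L) + 74L,
                         stringsAsFactors = FALSE)
      inside <- which(lay$start >= rs & lay$end <= re)
      outside <- setdiff(seq_len(ng), inside)
      n_in <- min(length(inside), 1L + stats::rpois(1, 0.8))
      n_out <- min(length(outside), 1L + stats::rpois(1, 0.5))
      amg_in <- .sampleVec(inside, n_in)
      amg_out <- .sampleVec(outside, n_out)
      amg_rows <- c(amg_in, amg_out)
      labels[amg_in] <- "intra_viral"
      labels[amg_out] <- "cellular_flank"
    } else if (kind == "blacklist") {
      scores[i] <- stats::runif(1, 0.75, 1.0)
      nb <- min(ng, sample(1:2, 1L))
      black <- sample(ng, nb)
      labels[black] <- "blacklist_gene"
      if (stats::runif(1) < max(params@p_amg_contig, 0.5)) {
        cand <- setdiff(seq_len(ng), black)
        k <- min(length(cand), 1L + stats::rpois(1, 1.0))
        amg_rows <- .sampleVec(cand, k)
        labels[amg_rows] <- "blacklist_contig"
      }
    } else { # clean
      scores[i] <- stats::runif(1, 0.75, 1.0)
      if (stats::runif(1) < params@p_amg_contig && ng > 0L) {
        k <- min(ng, 1L + stats::rpois(1, 1.2))
        amg_rows <- sample(ng, k)
        labels[amg_rows] <- "intra_viral"
      }
    }

    seqs[i] <- s
    regions[[i]] <- region
    rows <- lapply(seq_len(ng), function(g) {
      r <- .geneRow(sprintf("gene_%05d", gcount + g), ids[i],
                    lay$start[g], lay$end[g], lay$strand[g],
                    g %in% amg_rows, komap, amg_pool, house_pool)
      if (labels[g] == "blacklist_gene")
        r$category_flags <- sample(.BLACKLIST_FLAGS, 1L)
      r
    })
    gcount <- gcount + ng
    gene_tabs[[i]] <- if (ng) do.call(rbind, rows) else NULL
    trna_tabs[[i]] <- trna
    truth_c[[i]] <- data.frame(
      contig_id = ids[i], kind = kind,
      region_start = IRanges::start(region)[1],
      region_end = IRanges::end(region)[1],
      parent = NA_character_, n_amg = length(amg_rows),
      stringsAsFactors = FALSE)
    if (ng)
      truth_g[[i]] <- data.frame(
        gene_id = sprintf("gene_%05d", (gcount - ng + 1L):gcount),
        contig_id = ids[i], is_amg = seq_len(ng) %in% amg_rows,
        label = labels, stringsAsFactors = FALSE)
  }

  # near-duplicate contigs: mutated 80% prefixes of clean contigs; they
  # carry no annotations but must co-cluster with their parent
  dup_src <- which(kinds == "clean" &
                     stats::runif(n) < params@p_duplicate_contig)
  for (i in dup_src) {
    Ld <- as.integer(round(0.8 * lens[i]))
    if (Ld < 5000L) next
    did <- paste0(ids[i], "d")
    seqs <- c(seqs, .mutateDna(substr(seqs[i], 1L, Ld), 0.02))
    lens <- c(lens, Ld)
    ids <- c(ids, did)
    scores <- c(scores, scores[i])
    fractions <- c(fractions, fractions[i])
    regions <- c(regions, list(IRanges::IRanges(1L, Ld)))
    cls <- rbind(cls, cls[i, , drop = FALSE])
    rownames(cls)[nrow(cls)] <- did
    truth_c <- c(truth_c, list(data.frame(
      contig_id = did, kind = "duplicate",
      region_start = 1L, region_end = Ld,
      parent = ids[i], n_amg = 0L, stringsAsFactors = FALSE)))
  }

  sset <- Biostrings::DNAStringSet(seqs)
  names(sset) <- ids
  contigs <- new("ContigSet",
                 sequences = sset,
                 info = DataFrame(contig_id = ids,
                                  length = lens,
                                  source_fraction = fractions,
                                  virsorter_score = scores,
                                  circular = FALSE),
                 classifierScores = cls,
                 viralRegions = .asRegionList(regions, ids))
  genes <- do.call(rbind, gene_tabs[!vapply(gene_tabs, is.null, logical(1))])
  trna <- do.call(rbind, trna_tabs[!vapply(trna_tabs, is.null, logical(1))])
  if (is.null(trna))
    trna <- data.frame(contig_id = character(0), start = integer(0),
                       end = integer(0))
  list(contigs = contigs,
       genes = genes,
       trna = trna,
       truth = list(contigs = do.call(rbind, truth_c),
                    genes = do.call(rbind, truth_g)))
}

#' Generate per-sample depth profiles
#'
#' Per contig and sample, draws block-wise Poisson depths around a target
#' mean, then masks a contiguous segment so that the covered fraction equals
#' `breadth` (to rounding). Truth (planted mean depth and breadth per
#' profile) is stored in `metadata(x)$truth`.
#'
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param sample_ids character vector of sample ids.
#' @param depth_mean scalar mean depth, or a contigs x samples matrix of
#'   target mean depths.
#' @param breadth covered fraction of positions (scalar).
#' @param noise `"poisson"` (default) or `"none"` for constant depth.
#' @param block run length (bp) of constant-depth blocks.
#' @param total_reads total reads per sample (scalar or named vector) used
#'   later for normalization.
#' @param seed RNG seed.
#' @return a [DepthProfileSet].
#' @examples
#' dp <- generateDepthProfiles(c(c1 = 1000L), "s1", depth_mean = 5,
#'                             seed = 1L)
#' @export
generateDepthProfiles <- function(contig_lengths, sample_ids,
                                  depth_mean = 10, breadth = 0.95,
                                  noise = c("poisson", "none"),
                                  block = 50L, total_reads = 1e9,
                                  seed = 1L) {
  noise <- match.arg(noise)
  .checkProb(breadth, "breadth")
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be named by contig id")
  set.seed(.checkCount(seed, "seed"))
  nc <- length(contig_lengths)
  ns <- length(sample_ids)
  if (is.matrix(depth_mean)) {
    stopifnot(nrow(depth_mean) == nc, ncol(depth_mean) == ns)
    dm <- depth_mean
  } else {
    dm <- matrix(depth_mean, nc, ns)
  }
  if (length(total_reads) == 1L)
    total_reads <- stats::setNames(rep(total_reads, ns), sample_ids)
  profs <- vector("list", nc * ns)
  info <- vector("list", nc * ns)
  truth <- vector("list", nc * ns)
  idx <- 0L
  for (j in seq_len(ns)) {
    for (i in seq_len(nc)) {
      idx <- idx + 1L
      L <- as.integer(contig_lengths[i])
      m <- dm[i, j]
      nb <- ceiling(L / block)
      vals <- if (noise == "none" || m == 0) rep(m, nb)
              else stats::rpois(nb, m)
      v <- rep(vals, each = block)[seq_len(L)]
      ncov <- round(breadth * L)
      u <- L - ncov
      if (u > 0L && L > u) {
        st <- sample.int(L - u + 1L, 1L)
        v[st:(st + u - 1L)] <- 0
      } else if (u >= L) {
        v[] <- 0
      }
      profs[[idx]] <- Rle(v)
      info[[idx]] <- data.frame(
        contig_id = names(contig_lengths)[i],
        sample_id = sample_ids[j],
        total_reads = unname(total_reads[sample_ids[j]]),
        stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(
        contig_id = names(contig_lengths)[i],
        sample_id = sample_ids[j],
        mean_depth = m, breadth = breadth, stringsAsFactors = FALSE)
    }
  }
  info <- do.call(rbind, info)
  dl <- as(S4Vectors::SimpleList(profs), "RleList")
  names(dl) <- paste(info$contig_id, info$sample_id, sep = "|")
  out <- new("DepthProfileSet", depths = dl, info = DataFrame(info))
  metadata(out)$truth <- do.call(rbind, truth)
  out
}

#' Write a simulated survey to disk
#'
#' Writes the generator outputs in the package's external formats: contig
#' FASTA, annotation TSV, virus-evidence TSV, tRNA TSV, and the
#' ground-truth sidecar TSVs. Output is deterministic given the generator
#' seed (byte-identical across runs).
#'
#' @param sim result of [generateSurveyContigs()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulatedSurvey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(contigSequences(sim$contigs),
                              file.path(dir, "contigs.fasta"))
  writeAmgTsv(sim$genes, file.path(dir, "annotations.tsv"))
  writeContigEvidence(sim$contigs, file.path(dir, "virus_evidence.tsv"))
  writeAmgTsv(sim$trna, file.path(dir, "trna.tsv"))
  writeAmgTsv(sim$truth$contigs, file.path(dir, "truth_contigs.tsv"))
  writeAmgTsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
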