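# Small constructors used across test files.

randDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# a ContigSet with explicit scores/regions; classifier defaults to
# dsDNA-phage-maximal unless ds_top = FALSE
makeContigSet <- function(ids, lengths, scores,
                          ds_top = rep(TRUE, length(ids)),
                          regions = NULL, seqs = NULL,
                          source = "virus-enriched") {
  n <- length(ids)
  cls <- matrix(NA_real_, n, 2,
                dimnames = list(ids, c("dsDNA phage", "ssDNA")))
  cls[, "dsDNA phage"] <- 0.9
  cls[, "ssDNA"] <- ifelse(ds_top, 0.5, 0.95)
  if (is.null(regions))
    regions <- lapply(lengths, function(L) IRanges::IRanges(1L, L))
  sset <- if (is.null(seqs)) Biostrings::DNAStringSet()
          else {
            x <- Biostrings::DNAStringSet(seqs)
            names(x) <- ids
            x
          }
  rl <- do.call(IRanges::IRangesList, regions)
  names(rl) <- ids
  new("ContigSet",
      sequences = sset,
      info = S4Vectors::DataFrame(contig_id = ids,
                                  length = as.integer(lengths),
                                  source_fraction = rep(source, n),
                                  virsorter_score = scores,
                                  circular = FALSE),
      classifierScores = cls,
      viralRegions = rl)
}

# minimal gene-annotation row builder
makeGene <- function(gene_id, contig_id, start, end, bit = 100,
                     aux = 1L, ko = NA_character_,
                     modules = NA_character_, known = FALSE,
                     flags = NA_character_, strand = "+") {
  data.frame(gene_id = gene_id, contig_id = contig_id, start = start,
             end = end, strand = strand, bit_score = bit,
             auxiliary_score = aux, ko = ko, module_ids = modules,
             known_amg = known, category_flags = flags,
             stringsAsFactors = FALSE)
}

# a MockCommunity with explicit genomes/genes (one population per genome
# unless pop ids are supplied)
makeCommunity <- function(lengths, amg_coords, pop_ids = NULL,
                          seed = 1L) {
  set.seed(seed)
  n <- length(lengths)
  ids <- sprintf("g%02d", seq_len(n))
  seqs <- Biostrings::DNAStringSet(vapply(lengths, randDna, character(1)))
  names(seqs) <- ids
  rows <- list()
  for (i in seq_len(n)) {
    co <- amg_coords[[i]]
    if (is.null(co) || !nrow(co)) next
    rows[[i]] <- data.frame(
      genome_id = ids[i],
      gene_id = sprintf("%s_a%02d", ids[i], seq_len(nrow(co))),
      start = co$start, end = co$end, strand = "+",
      bit_score = 100, auxiliary_score = 1L,
      ko = "K00001", module_ids = "M0001", known_amg = FALSE,
      category_flags = NA_character_, is_amg = TRUE,
      stringsAsFactors = FALSE)
  }
  genes <- if (length(rows)) do.call(rbind, rows[!vapply(rows, is.null,
                                                         logical(1))])
           else data.frame(genome_id = character(0), gene_id = character(0),
                           start = integer(0), end = integer(0),
                           is_amg = logical(0))
  if (is.null(pop_ids)) pop_ids <- sprintf("pop%02d", seq_len(n))
  new("MockCommunity", sequences = seqs,
      genes = S4Vectors::DataFrame(genes),
      populations = S4Vectors::DataFrame(genome_id = ids,
                                         population_id = pop_ids))
}
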