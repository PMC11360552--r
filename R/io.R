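# Readers/writers for the package's external interfaces: contig FASTA +
# virus-evidence TSV, annotation TSV, similarity TSV, depth-profile TSV,
# module-definition TSV, and population TSV.

# viral regions <-> "start-end;start-end" text
.encodeRegions <- function(rl) {
  vapply(seq_along(rl), function(i) {
    r <- rl[[i]]
    if (!length(r)) return(".")
    paste(paste0(IRanges::start(r), "-", IRanges::end(r)), collapse = ";")
  }, character(1))
}

.decodeRegions <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == ".") return(IRanges::IRanges())
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    IRanges::IRanges(start = vapply(parts, function(p) as.integer(p[1]),
                                    integer(1)),
                     end = vapply(parts, function(p) as.integer(p[2]),
                                  integer(1)))
  })
}

#' Write the virus-evidence table of a contig set
#'
#' @param contigs a [ContigSet].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeContigEvidence <- function(contigs, path) {
  stopifnot(is(contigs, "ContigSet"))
  info <- as.data.frame(contigInfo(contigs))
  cls <- classifierScores(contigs)
  colnames(cls) <- paste0("classifier:", colnames(cls))
  df <- cbind(info, as.data.frame(cls, check.names = FALSE),
              viral_regions = .encodeRegions(viralRegions(contigs)))
  writeAmgTsv(df, path)
}

#' Read a contig set from FASTA and a virus-evidence table
#'
#' @param evidence_path virus-evidence TSV (as written by
#'   [writeContigEvidence()]): `contig_id`, `length`, `source_fraction`,
#'   `virsorter_score`, optional `circular`, `classifier:<group>` columns
#'   and `viral_regions`.
#' @param fasta_path optional contig FASTA; when absent,
#'   sequence-dependent steps are skipped downstream.
#' @return a [ContigSet].
#' @export
readContigSet <- function(evidence_path, fasta_path = NULL) {
  df <- readAmgTsv(evidence_path)
  cls_cols <- grep("^classifier:", colnames(df), value = TRUE)
  cls <- as.matrix(df[, cls_cols, drop = FALSE])
  colnames(cls) <- sub("^classifier:", "", cls_cols)
  rownames(cls) <- df$contig_id
  regions <- .decodeRegions(df$viral_regions)
  seqs <- Biostrings::DNAStringSet()
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs <- seqs[df$contig_id]
  }
  if (!"circular" %in% colnames(df)) df$circular <- FALSE
  new("ContigSet",
      sequences = seqs,
      info = DataFrame(contig_id = df$contig_id,
                       length = as.integer(df$length),
                       source_fraction = df$source_fraction,
                       virsorter_score = as.numeric(df$virsorter_score),
                       circular = as.logical(df$circular)),
      classifierScores = cls,
      viralRegions = .asRegionList(regions, df$contig_id))
}

#' Write a population partition
#'
#' @param populations a [VirusPopulations].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePopulations <- function(populations, path) {
  writeAmgTsv(as.data.frame(populationMembership(populations)), path)
}

#' Write depth profiles with run-length encoded vectors
#'
#' @param profiles a [DepthProfileSet].
#' @param path output TSV path (`contig_id`, `sample_id`, `total_reads`,
#'   `depths` as `"<len>x<value>,..."`).
#' @return `path`, invisibly.
#' @export
writeDepthProfiles <- function(profiles, path) {
  stopifnot(is(profiles, "DepthProfileSet"))
  info <- as.data.frame(profileInfo(profiles))
  dl <- depthProfiles(profiles)
  info$depths <- vapply(seq_along(dl), function(i) .encodeRle(dl[[i]]),
                        character(1))
  writeAmgTsv(info, path)
}

#' Read depth profiles written by [writeDepthProfiles()]
#'
#' @param path input TSV path.
#' @return a [DepthProfileSet].
#' @export
readDepthProfiles <- function(path) {
  df <- readAmgTsv(path)
  profs <- lapply(df$depths, .decodeRle)
  dl <- as(S4Vectors::SimpleList(profs), "RleList")
  names(dl) <- paste(df$contig_id, df$sample_id, sep = "|")
  new("DepthProfileSet", depths = dl,
      info = DataFrame(df[, c("contig_id", "sample_id", "total_reads")]))
}

#' Read a precomputed pairwise similarity table
#'
#' @param path TSV with columns `a`, `b`, `ani`, `af` (e.g. exported from an
#'   external whole-genome aligner).
#' @return a data.frame usable by [clusterPopulations()].
#' @export
readSimilarityTable <- function(path) {
  df <- readAmgTsv(path)
  need <- c("a", "b", "ani", "af")
  if (!all(need %in% colnames(df)))
    stop("similarity table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read module definitions
#'
#' @param path TSV with columns `module_id` and `definition`.
#' @return a data.frame accepted by [classifyPathways()].
#' @export
readModuleDefinitions <- function(path) {
  df <- readAmgTsv(path)
  if (!all(c("module_id", "definition") %in% colnames(df)))
    stop("module table needs columns module_id, definition")
  df
}
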