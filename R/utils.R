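# Internal helpers shared across modules: TSV conventions (tab-delimited,
# header row, "." for missing), run-length depth encoding, random sequence
# generation, and small argument checks.

.checkProb <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single probability in [0, 1]", call. = FALSE)
  invisible(as.numeric(x))
}

.checkCount <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

.checkFraction <- function(x, what) .checkProb(x, what)

# list<character> -> "a,b" with "." for empty
.pasteFlags <- function(lst) {
  vapply(lst, function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x) == 0L) "." else paste(x, collapse = ",")
  }, character(1))
}

# "a,b" / "." -> list<character>
.splitFlags <- function(x) {
  x <- as.character(x)
  out <- strsplit(x, ",", fixed = TRUE)
  out[is.na(x) | x == "."] <- list(character(0))
  out
}

#' Write a tab-delimited table using the package conventions
#'
#' Tab-delimited, header row, UTF-8, LF line endings, `"."` for missing
#' values; list columns are joined with commas.
#'
#' @param df a data.frame or DataFrame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAmgTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.list(col)) col <- .pasteFlags(col)
    col <- as.character(col)
    col[is.na(col)] <- "."
    df[[j]] <- col
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited table using the package conventions
#'
#' @param path input file path.
#' @return a data.frame with `"."` decoded to `NA`.
#' @export
readAmgTsv <- function(path) {
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Rle <-> "lenxval,lenxval" text encoding for depth vectors
.encodeRle <- function(r) {
  r <- S4Vectors::Rle(r)
  paste0(S4Vectors::runLength(r), "x", S4Vectors::runValue(r), collapse = ",")
}

.decodeRle <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "x", fixed = TRUE)
  lens <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  vals <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  S4Vectors::Rle(vals, lens)
}

# sample k elements from a vector, safe for length-1 vectors
.sampleVec <- function(x, k) x[sample.int(length(x), k)]

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-mutate a DNA string at the given per-position rate (no indels).
.mutateDna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    repl <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Category flags a contig may carry; all but tRNA form the mobile-element /
# hypervariable-region blacklist used by conservative curation.
.BLACKLIST_FLAGS <- c("transposase", "integrase", "endonuclease",
                      "plasmid_stability", "glycosyltransferase",
                      "nucleotidyl_transferase", "carbohydrate_kinase",
                      "nucleotide_sugar_epimerase")

.CLASSIFIER_GROUPS <- c("dsDNA phage", "ssDNA", "NCLDV", "RNA", "lavidaviridae")

# plain list of IRanges -> named IRangesList
.asRegionList <- function(regions, ids) {
  rl <- do.call(IRanges::IRangesList, regions)
  names(rl) <- ids
  rl
}
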