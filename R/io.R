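#' Write an annotated genome to FASTA + GFF3
#'
#' Internal coordinates are 0-based half-open; the exported GFF3 is 1-based
#' inclusive with feature types `gene`, `tRNA` and `mobile_genetic_element`,
#' stable `ID` attributes, and IS family labels in a `family` attribute.
#'
#' @param genome an `annotated_genome`.
#' @param fasta,gff3 output paths.
#' @export
write_reference <- function(genome, fasta, gff3) {
  dna <- Biostrings::DNAStringSet(setNames(genome$seq, genome$genome_id))
  Biostrings::writeXStringSet(dna, fasta)
  gr <- features_as_granges(genome)
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(fasta = fasta, gff3 = gff3))
}

features_as_granges <- function(genome) {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$family <- f$is_family
  S4Vectors::mcols(gr)$highly_expressed <- f$highly_expressed
  GenomeInfoDb::seqlengths(gr) <- nchar(genome$seq)
  GenomeInfoDb::isCircular(gr) <- genome$circular
  gr
}

#' Read an annotated genome from FASTA + GFF3
#'
#' @param fasta,gff3 input paths.
#' @param circular logical; bacterial chromosomes default to circular.
#' @return an `annotated_genome`.
#' @export
read_reference <- function(fasta, gff3, circular = TRUE) {
  dna <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff3, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "tRNA", "rRNA", "ncRNA",
                                       "mobile_genetic_element")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  id <- if (!is.null(mc$ID)) as.character(mc$ID) else
    sprintf("feat_%05d", seq_along(gr))
  fam <- if (!is.null(mc$family)) as.character(mc$family) else
    rep(NA_character_, length(gr))
  he <- if (!is.null(mc$highly_expressed))
    as.logical(mc$highly_expressed) else rep(FALSE, length(gr))
  features <- data.frame(
    id = id, type = as.character(mc$type),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_family = fam, highly_expressed = he %in% TRUE,
    stringsAsFactors = FALSE)
  features$strand[!features$strand %in% c("+", "-")] <- "+"
  features <- features[order(features$start), ]
  rownames(features) <- NULL
  L <- Biostrings::width(dna)[1]
  bad <- features$end > L | features$start < 0 | features$end <= features$start
  if (any(bad)) stop("feature(s) outside genome or with end <= start")
  structure(list(genome_id = names(dna)[1],
                 seq = as.character(dna[[1]]),
                 features = features, circular = circular,
                 codon_model = NULL, spec = NULL),
            class = "annotated_genome")
}

#' Write simulated reads as FASTQ (Phred+33, constant quality)
#'
#' @param read_set a `read_set` from [simulate_reads()] (or a DNAStringSet).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(read_set, path) {
  reads <- if (inherits(read_set, "read_set")) read_set$reads else read_set
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Export a truth manifest as TSV
#'
#' One row per structural edit plus one row per fully/partially deleted
#' gene. Coordinates are 1-based inclusive in the export.
#'
#' @param manifest a `truth_manifest`.
#' @param path output TSV path.
#' @export
write_manifest <- function(manifest, path) {
  rows <- list()
  d <- manifest$deletions
  if (nrow(d)) rows[[length(rows) + 1L]] <- data.frame(
    query_id = manifest$query_id, edit_type = "deletion",
    feature_id = NA_character_, ref_start = d$ref_start + 1L,
    ref_end = d$ref_end, length = d$length, flank_style = d$flank_style)
  i <- manifest$insertions
  if (nrow(i)) rows[[length(rows) + 1L]] <- data.frame(
    query_id = manifest$query_id, edit_type = "insertion",
    feature_id = NA_character_, ref_start = i$ref_anchor + 1L,
    ref_end = i$ref_anchor, length = i$length, flank_style = i$flank_style)
  for (g in manifest$deleted_genes_full)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = manifest$query_id, edit_type = "deleted_gene_full",
      feature_id = g, ref_start = NA, ref_end = NA, length = NA,
      flank_style = NA_character_)
  for (g in manifest$deleted_genes_partial)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = manifest$query_id, edit_type = "deleted_gene_partial",
      feature_id = g, ref_start = NA, ref_end = NA, length = NA,
      flank_style = NA_character_)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), edit_type = character(0),
               feature_id = character(0), ref_start = numeric(0),
               ref_end = numeric(0), length = numeric(0),
               flank_style = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal SAM writer for the built-in mapper's ungapped hits.
# All reported hits are primary lines (flag 0/16) so that coverage computed
# from the SAM equals the mapper's own mask even when multi-mapping
# locations are counted.
write_sam <- function(path, genome_id, genome_len, read_names, read_seqs,
                      hits) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome_id, genome_len)), con)
  if (nrow(hits)) {
    seqs <- read_seqs[hits$read]
    minus <- hits$strand == "-"
    if (any(minus)) seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                     read_names[hits$read], ifelse(minus, 16L, 0L), genome_id,
                     hits$pos + 1L, nchar(seqs), seqs,
                     strrep("I", nchar(seqs)), hits$mismatches)
    writeLines(lines, con)
  }
  invisible(path)
}
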