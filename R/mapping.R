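#' Configuration of the built-in exact-seed read mapper
#'
#' The mapper declares a read mapped at a reference position (either strand)
#' when an exact `seed_k`-mer of the read anchors it there and the
#' full-length ungapped comparison shows at most `max_mismatches`
#' mismatches. With `count_multimappers = TRUE` (default) every passing
#' location contributes coverage; otherwise only the best location (fewest
#' mismatches, ties broken leftmost, then forward strand) does. Coverage
#' *breadth* presence/absence is the downstream signal, so counting
#' multi-mapped reads avoids spuriously flagging multicopy genes as absent.
#'
#' @param seed_k exact seed length (default 18).
#' @param max_mismatches mismatch budget over the full read (default 3).
#' @param count_multimappers logical (default TRUE).
#' @export
mapper_config <- function(seed_k = 18L, max_mismatches = 3L,
                          count_multimappers = TRUE) {
  if (seed_k < 1) stop("seed_k must be >= 1")
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  structure(list(seed_k = as.integer(seed_k),
                 max_mismatches = as.integer(max_mismatches),
                 count_multimappers = isTRUE(count_multimappers)),
            class = "mapper_config")
}

new_coverage_mask <- function(genome_id, covered) {
  structure(list(genome_id = genome_id, length = length(covered),
                 covered = as.integer(covered)),
            class = "coverage_mask")
}

#' @export
print.coverage_mask <- function(x, ...) {
  cat(sprintf("<coverage_mask> %s: %s bp, %.1f%% covered\n", x$genome_id,
              format(x$length, big.mark = ","),
              100 * mean(x$covered)))
  invisible(x)
}

#' Map reads onto a reference and return its per-base coverage mask
#'
#' @param reads a `read_set`, [Biostrings::DNAStringSet], character vector,
#'   or FASTQ path.
#' @param reference an `annotated_genome`, DNAString(Set) or sequence string.
#' @param config a [mapper_config()].
#' @param sam_out optional path; when given, every reported hit is written
#'   as a primary SAM line.
#' @return a `coverage_mask`; the hit table (read index, 0-based position,
#'   strand, mismatches) is attached as attribute `"hits"`.
#' @export
map_reads <- function(reads, reference, config = mapper_config(),
                      sam_out = NULL) {
  stopifnot(inherits(config, "mapper_config"))
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  read_chr <- if (inherits(reads, "DNAStringSet")) as.character(reads)
              else toupper(as.character(reads))
  read_names <- names(read_chr) %||% sprintf("read_%07d", seq_along(read_chr))
  genome_id <- if (inherits(reference, "annotated_genome"))
    reference$genome_id else "reference"
  ref_seq <- if (inherits(reference, "annotated_genome")) reference$seq
             else as_dna_string(reference)
  if (any(nchar(read_chr) < config$seed_k))
    stop("reads shorter than seed_k cannot be mapped")

  res <- .map_reads_cpp(ref_seq, unname(read_chr), config$seed_k,
                        config$max_mismatches, !config$count_multimappers)
  hits <- data.frame(read = res$read, pos = res$pos,
                     strand = res$strand, mismatches = res$mismatches,
                     stringsAsFactors = FALSE)
  mask <- new_coverage_mask(genome_id, res$mask)
  if (!is.null(sam_out))
    write_sam(sam_out, genome_id, nchar(ref_seq), read_names,
              unname(read_chr), hits)
  attr(mask, "hits") <- hits
  mask
}

#' Build a coverage mask from standard alignments (SAM/BAM)
#'
#' A base is covered when at least one non-secondary, non-unmapped
#' alignment's reference-consuming blocks overlap it; soft/hard-clipped
#' bases do not cover.
#'
#' @param path SAM or BAM file.
#' @param reference_length expected reference length (validated against the
#'   header).
#' @param genome_id optional expected reference name.
#' @return a `coverage_mask`.
#' @export
load_alignments <- function(path, reference_length, genome_id = NULL) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) == 0L) stop("alignment file has no reference sequences")
  tgt <- if (!is.null(genome_id)) {
    if (!genome_id %in% names(hdr)) stop("reference name mismatch")
    genome_id
  } else names(hdr)[1]
  if (hdr[[tgt]] != reference_length)
    stop(sprintf("reference length mismatch: header %d vs expected %d",
                 hdr[[tgt]], reference_length))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags))
  aln <- aln[as.character(GenomicAlignments::seqnames(aln)) == tgt]
  covered <- integer(reference_length)
  if (length(aln)) {
    cov <- GenomicAlignments::coverage(aln)[[tgt]]
    covered <- as.integer(as.integer(cov) > 0L)
    length(covered) <- reference_length
    covered[is.na(covered)] <- 0L
  }
  new_coverage_mask(tgt, covered)
}
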