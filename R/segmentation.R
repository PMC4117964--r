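GENE_KIND_TYPES <- c("gene", "tRNA", "rRNA", "ncRNA")

#' Dissect a reference genome into gene and IGR segments
#'
#' One gene segment per annotated gene/RNA feature (feature extents exactly,
#' in genome order) and one intergenic-region (IGR) segment per positive gap
#' between consecutive gene ends and starts. On a linear genome the leading
#' and trailing gaps become IGRs of their own; on a circular genome they are
#' merged into a single wrap-around IGR (represented with `end` past the
#' genome length). Overlapping genes are both kept in full and yield no IGR
#' between them. IGR ids follow the `IGR_<leftGene>-<rightGene>` convention.
#'
#' @param genome an `annotated_genome`, or a feature data frame with columns
#'   `id`, `type`, `start`, `end` (0-based half-open).
#' @param genome_length required when `genome` is a plain feature table.
#' @param circular logical; taken from the genome object when available.
#' @return a `segment_table` data frame: `segment_id`, `kind` (gene/IGR),
#'   `start`, `end` (0-based half-open; `end` may exceed the genome length
#'   only for the circular wrap-around IGR), `length`, `rank`, `feature_id`.
#' @export
dissect <- function(genome, genome_length = NULL, circular = NULL) {
  if (inherits(genome, "annotated_genome")) {
    feats <- genome$features
    genome_length <- nchar(genome$seq)
    if (is.null(circular)) circular <- genome$circular
  } else {
    feats <- genome
    if (is.null(genome_length)) stop("genome_length required")
    if (is.null(circular)) circular <- FALSE
  }
  feats <- feats[feats$type %in% GENE_KIND_TYPES, , drop = FALSE]
  if (nrow(feats) == 0L) stop("no gene-kind features to dissect")
  if (any(feats$end <= feats$start)) stop("feature with end <= start")
  if (any(feats$start < 0 | feats$end > genome_length))
    stop("feature outside genome")
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]

  segs <- list()
  add <- function(id, kind, start, end, feature_id = NA_character_) {
    segs[[length(segs) + 1L]] <<- data.frame(
      segment_id = id, kind = kind, start = start, end = end,
      length = end - start, feature_id = feature_id,
      stringsAsFactors = FALSE)
  }

  n <- nrow(feats)
  first_start <- feats$start[1]
  running_end <- 0L
  # leading gap (linear only; circular genomes defer it to the wrap IGR)
  lead_gap <- first_start > 0L
  if (lead_gap && !circular)
    add(sprintf("IGR_ori-%s", feats$id[1]), "IGR", 0L, first_start)
  for (i in seq_len(n)) {
    if (i > 1L) {
      gap_start <- running_end
      if (feats$start[i] > gap_start)
        add(sprintf("IGR_%s-%s", feats$id[i - 1L], feats$id[i]), "IGR",
            gap_start, feats$start[i])
    }
    add(feats$id[i], "gene", feats$start[i], feats$end[i], feats$id[i])
    running_end <- max(running_end, feats$end[i])
  }
  trail_gap <- running_end < genome_length
  if (!circular) {
    if (trail_gap)
      add(sprintf("IGR_%s-ter", feats$id[n]), "IGR", running_end, genome_length)
  } else if (trail_gap || lead_gap) {
    add(sprintf("IGR_%s-%s", feats$id[n], feats$id[1]), "IGR",
        running_end, genome_length + first_start)
  }
  out <- do.call(rbind, segs)
  # genome order: by start, with the wrap IGR (if any) last by construction
  out <- out[order(out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "genome_length") <- genome_length
  attr(out, "circular") <- circular
  class(out) <- c("segment_table", class(out))
  out
}

#' Per-segment coverage rates from a coverage mask
#'
#' Coverage rate is the *breadth* statistic of in silico CGH: the percentage
#' of a segment's nucleotides covered by at least one mapped read. Counts
#' are exact integers; the rate is stored unrounded.
#'
#' @param mask a `coverage_mask`.
#' @param segments a `segment_table` from [dissect()].
#' @return the segment table with `covered_bases` and `coverage_rate`
#'   (percentage in \[0, 100\]) columns added.
#' @export
coverage_rates <- function(mask, segments) {
  stopifnot(inherits(mask, "coverage_mask"))
  L <- attr(segments, "genome_length")
  if (!is.null(L) && mask$length != L)
    stop("mask length does not match the segmented genome")
  L <- mask$length
  cs <- c(0, cumsum(mask$covered))
  span_sum <- function(s, e) {
    if (e <= L) return(cs[e + 1L] - cs[s + 1L])
    (cs[L + 1L] - cs[s + 1L]) + cs[e - L + 1L] # wrap-around IGR
  }
  covered <- mapply(span_sum, segments$start, segments$end)
  segments$covered_bases <- as.integer(covered)
  segments$coverage_rate <- 100 * covered / segments$length
  segments
}

#' Flag low-coverage-rate (LCR) segments
#'
#' A segment is LCR when its coverage rate is *strictly* below the
#' threshold; such a segment is inferred absent from the query genome.
#'
#' @param coverage a segment table with `coverage_rate` (from
#'   [coverage_rates()]).
#' @param threshold percentage in \[0, 100\]; 20 is the published default.
#' @export
call_lcr <- function(coverage, threshold = 20) {
  if (threshold < 0 || threshold > 100) stop("threshold must be in [0,100]")
  coverage$lcr_flag <- coverage$coverage_rate < threshold
  attr(coverage, "lcr_threshold") <- threshold
  coverage
}

#' Histogram of coverage rates
#'
#' Bins `[0,10), [10,20), ..., [90,100]`; the last bin is closed so that
#' fully covered segments are counted.
#'
#' @param coverage segment table with `coverage_rate`.
#' @param bin_width bin width in percentage points (divides 100).
#' @return named integer vector of counts; sums to the number of segments.
#' @export
rate_histogram <- function(coverage, bin_width = 10) {
  stopifnot(100 %% bin_width == 0)
  nb <- as.integer(100 / bin_width)
  lab <- sprintf("[%g,%g%s", bin_width * (seq_len(nb) - 1L),
                 bin_width * seq_len(nb),
                 c(rep(")", nb - 1L), "]"))
  counts <- integer(nb)
  if (nrow(coverage)) {
    idx <- pmin(floor(coverage$coverage_rate / bin_width) + 1L, nb)
    tab <- tabulate(idx, nbins = nb)
    counts <- tab
  }
  setNames(counts, lab)
}
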