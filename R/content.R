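#' Per-query LCR gene summary
#'
#' Reports the number of LCR (absent) genes and their percentage of the
#' reference's gene complement. The exact percentage is retained; the
#' reported value is rounded to the nearest integer (ties away from zero),
#' except that values below 1 are reported to two decimals so that very
#' small fractions (e.g. 2 of 4,569 genes = 0.04) remain visible.
#'
#' @param n_lcr_genes count of LCR genes, or an `lcr_callset` list with a
#'   `lcr_gene_ids` element.
#' @param total_genes total protein-coding plus RNA genes in the reference.
#' @param query_id optional label.
#' @param expected_size optional expected genome size (bp) to carry along.
#' @param rounding `"half_away"` (default) or `"half_even"`.
#' @return one-row data frame: `query_id`, `n_lcr_genes`, `total_genes`,
#'   `pct_exact`, `pct_reported`, `expected_size`.
#' @export
summarize_query <- function(n_lcr_genes, total_genes, query_id = NA_character_,
                            expected_size = NA_real_,
                            rounding = c("half_away", "half_even")) {
  rounding <- match.arg(rounding)
  if (is.list(n_lcr_genes) && !is.null(n_lcr_genes$lcr_gene_ids))
    n_lcr_genes <- length(n_lcr_genes$lcr_gene_ids)
  if (total_genes <= 0) stop("total_genes must be > 0")
  pct <- 100 * n_lcr_genes / total_genes
  reported <- if (pct < 1) round(pct, 2)
  else if (rounding == "half_away") floor(pct + 0.5)
  else round(pct)
  data.frame(query_id = query_id, n_lcr_genes = as.integer(n_lcr_genes),
             total_genes = as.integer(total_genes),
             pct_exact = pct, pct_reported = reported,
             expected_size = expected_size, stringsAsFactors = FALSE)
}

#' Nonredundant union of LCR genes and its membership (Venn) partition
#'
#' Every gene scored LCR in at least one query is assigned to exactly one
#' membership pattern (which queries flagged it); pattern percentages are
#' relative to the union size.
#'
#' @param callsets named list (2-4 entries) of character vectors of LCR
#'   gene ids, one per query, all against the same reference.
#' @return a `data.frame` with `pattern` (query names joined by `+`),
#'   `count` and `pct`; the union size is attached as attribute
#'   `"union_size"`.
#' @export
nonredundant_partition <- function(callsets) {
  k <- length(callsets)
  if (k < 2 || k > 4) stop("2 to 4 callsets required")
  if (is.null(names(callsets)) || anyNA(names(callsets)))
    names(callsets) <- paste0("Q", seq_len(k))
  callsets <- lapply(callsets, function(x) unique(as.character(x)))
  union_ids <- unique(unlist(callsets, use.names = FALSE))
  membership <- vapply(callsets, function(s) union_ids %in% s,
                       logical(length(union_ids)))
  if (length(union_ids) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE],
                    1L, identity, simplify = FALSE)
  rows <- lapply(patterns, function(p) {
    count <- if (length(union_ids))
      sum(apply(membership, 1L, function(m) all(m == p))) else 0L
    data.frame(pattern = paste(names(callsets)[p], collapse = "+"),
               count = as.integer(count), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  usz <- length(union_ids)
  out$pct <- if (usz) 100 * out$count / usz else rep(0, nrow(out))
  attr(out, "union_size") <- usz
  out
}

#' Expected genome size of a query
#'
#' Computed by subtracting the total length of LCR segments (genes and IGRs
#' both) from the reference genome size, i.e. assuming the query lacks
#' every region scored absent. Real genomes can exceed this expectation
#' when they carry DNA absent from the reference.
#'
#' @param reference_size reference genome size in bp.
#' @param lcr_segments flagged segment table (rows with `lcr_flag` are
#'   subtracted), or a numeric vector of LCR segment lengths.
#' @return expected size in bp.
#' @export
expected_genome_size <- function(reference_size, lcr_segments) {
  lens <- if (is.data.frame(lcr_segments)) {
    if (!is.null(lcr_segments$lcr_flag))
      lcr_segments$length[lcr_segments$lcr_flag]
    else lcr_segments$length
  } else as.numeric(lcr_segments)
  reference_size - sum(lens)
}

#' Genome-position track of coverage rates
#'
#' One point per segment in genome order, suitable for bar plotting of
#' coverage-rate landscapes along the reference.
#'
#' @param coverage segment table with `coverage_rate` and `rank`.
#' @return data frame with `rank`, `segment_id`, `kind`, `coverage_rate`.
#' @export
position_track <- function(coverage) {
  if (nrow(coverage) == 0L)
    return(data.frame(rank = integer(0), segment_id = character(0),
                      kind = character(0), coverage_rate = numeric(0)))
  out <- coverage[order(coverage$rank),
                  c("rank", "segment_id", "kind", "coverage_rate")]
  rownames(out) <- NULL
  out
}
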