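#' Find LCR gene clusters and independent LCR genes
#'
#' Maximal runs of consecutive LCR segments are computed first; a run
#' containing two or more LCR genes is an LCR gene cluster (a candidate
#' deleted/inserted genomic island), a run with exactly one LCR gene
#' contributes an independent LCR gene, and IGR-only runs form no cluster
#' (they are recorded separately). Any intervening non-LCR segment — gene
#' or IGR — breaks a run (strictest reading of "consecutive"); an optional
#' tolerance allows short non-LCR IGRs inside a run for robustness studies.
#' On circular genomes a run spanning the origin is joined.
#'
#' @param flagged a flagged segment table from [call_lcr()], ordered by
#'   `rank`.
#' @param circular logical; defaults to the segment table's attribute.
#' @param igr_gap_tolerance maximum total length (bp) of non-LCR *IGR*
#'   segments allowed inside a run (default 0: any non-LCR segment breaks).
#' @return list with `clusters` (data frame: `cluster_id`, `start`, `end`,
#'   `n_lcr_genes`, `n_segments`, `member_ids`, `gene_ids`),
#'   `independent_gene_ids`, and `igr_only_runs`.
#' @export
find_clusters <- function(flagged, circular = NULL, igr_gap_tolerance = 0) {
  if (is.null(circular)) circular <- isTRUE(attr(flagged, "circular"))
  if (is.unsorted(flagged$rank)) stop("segments must be ordered by rank")
  n <- nrow(flagged)
  if (n == 0L || !any(flagged$lcr_flag))
    return(list(clusters = empty_cluster_df(),
                independent_gene_ids = character(0),
                igr_only_runs = list()))

  in_run <- flagged$lcr_flag
  if (igr_gap_tolerance > 0) {
    # absorb short non-LCR IGRs sandwiched between LCR segments
    for (i in seq_len(n)) {
      if (!in_run[i] && flagged$kind[i] == "IGR" &&
          flagged$length[i] <= igr_gap_tolerance &&
          i > 1L && i < n && in_run[i - 1L] && flagged$lcr_flag[i + 1L])
        in_run[i] <- TRUE
    }
  }

  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(seq, starts[r$values], ends[r$values])

  # circular: join a run touching the last segment with one at the first
  if (circular && length(runs) > 1L &&
      runs[[1]][1] == 1L && tail(runs[[length(runs)]], 1L) == n) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }

  clusters <- list()
  independents <- character(0)
  igr_only <- list()
  for (run in runs) {
    genes <- flagged$kind[run] == "gene"
    gene_ids <- flagged$feature_id[run][genes]
    if (sum(genes) >= 2L) {
      clusters[[length(clusters) + 1L]] <- data.frame(
        start = flagged$start[run[1]], end = flagged$end[run[length(run)]],
        n_lcr_genes = sum(genes), n_segments = length(run),
        member_ids = paste(flagged$segment_id[run], collapse = ","),
        gene_ids = paste(gene_ids, collapse = ","),
        wraps = run[1] > run[length(run)],
        stringsAsFactors = FALSE)
    } else if (sum(genes) == 1L) {
      independents <- c(independents, gene_ids)
    } else {
      igr_only[[length(igr_only) + 1L]] <- flagged$segment_id[run]
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else empty_cluster_df()
  if (nrow(cl)) {
    cl <- cl[order(cl$start), , drop = FALSE]
    cl$cluster_id <- sprintf("C%03d", seq_len(nrow(cl)))
    cl <- cl[, c("cluster_id", setdiff(names(cl), "cluster_id"))]
    rownames(cl) <- NULL
  }
  list(clusters = cl, independent_gene_ids = independents,
       igr_only_runs = igr_only)
}

empty_cluster_df <- function() {
  data.frame(cluster_id = character(0), start = numeric(0), end = numeric(0),
             n_lcr_genes = integer(0), n_segments = integer(0),
             member_ids = character(0), gene_ids = character(0),
             wraps = logical(0), stringsAsFactors = FALSE)
}

#' Cluster size distribution
#'
#' @param clusters cluster data frame from [find_clusters()] (or the whole
#'   result list).
#' @param independents character vector of independent LCR gene ids (taken
#'   from the list when `clusters` is a [find_clusters()] result).
#' @return list with `by_size` (named counts keyed by genes per cluster)
#'   and `n_independent`.
#' @export
cluster_size_distribution <- function(clusters, independents = character(0)) {
  if (is.list(clusters) && !is.data.frame(clusters)) {
    independents <- clusters$independent_gene_ids
    clusters <- clusters$clusters
  }
  by_size <- if (nrow(clusters)) {
    t <- table(clusters$n_lcr_genes)
    setNames(as.integer(t), names(t))
  } else setNames(integer(0), character(0))
  list(by_size = by_size, n_independent = length(independents))
}

#' Export cluster spans as BED (0-based half-open)
#' @param clusters cluster data frame.
#' @param genome_id reference name for the BED chrom column.
#' @param path output path.
#' @export
write_clusters_bed <- function(clusters, genome_id, path) {
  df <- data.frame(chrom = genome_id, start = clusters$start,
                   end = clusters$end, name = clusters$cluster_id)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
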