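#' Scoring scheme for local alignment
#'
#' A gap of length L costs `gap_open + L * gap_extend` (the first gapped
#' base pays both penalties).
#'
#' @param match,mismatch,gap_open,gap_extend integer scores; `match > 0`,
#'   penalties `<= 0`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                          gap_extend = -2L) {
  if (match <= 0) stop("match score must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("penalties must be <= 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment score of two nucleotide sequences; `N` never
#' matches. Ties for the optimum are broken toward the smallest end
#' coordinates (in `a`, then in `b`).
#'
#' @param a,b sequences over A/C/G/T/N (character or DNAString).
#' @param scoring an [align_scoring()].
#' @return list: `score` (>= 0), 1-based inclusive aligned intervals
#'   `a_start`..`a_end`, `b_start`..`b_end` (0s for an empty alignment),
#'   `align_len` (columns), `n_match`, `identity` (matches / columns; NA
#'   for an empty alignment).
#' @export
sw_align <- function(a, b, scoring = align_scoring()) {
  a <- as_dna_string(a); b <- as_dna_string(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  r <- .sw_align_cpp(a, b, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  r$identity <- if (r$align_len > 0) r$n_match / r$align_len else NA_real_
  r
}

# Reference windows just outside a cluster span, [start-window, start) and
# [end, end+window), clipped to the genome on linear references and wrapped
# on circular ones. For a wrap-spanning cluster the roles are preserved:
# the left window precedes `start`, the right window follows `end`.
cluster_end_windows <- function(genome, cluster, window) {
  L <- nchar(genome$seq)
  s <- cluster$start; e <- cluster$end
  circ <- isTRUE(genome$circular)
  left <- if (circ) {
    ls <- (s - window) %% L
    extract_span(genome$seq, ls, ls + min(window, L), circular = TRUE)
  } else extract_span(genome$seq, max(0L, s - window), max(s, 1L))
  right <- if (circ) {
    re <- e %% L
    extract_span(genome$seq, re, re + min(window, L), circular = TRUE)
  } else extract_span(genome$seq, min(e, L - 1L), min(L, e + window))
  left_origin <- if (circ) (s - window) %% L else max(0L, s - window)
  right_origin <- if (circ) e %% L else e
  list(left = left, right = right,
       left_origin = left_origin, right_origin = right_origin)
}

#' Detect tRNA direct repeats at both ends of an LCR cluster
#'
#' Genomic islands are typically integrated at tRNA genes, leaving a direct
#' repeat of (part of) the tRNA at both island ends. The detector flags a
#' cluster when some annotated tRNA gene — or a high-identity copy of one —
#' lies within `window` bp of *both* cluster ends in the same (direct
#' repeat) orientation.
#'
#' @param cluster one row of a cluster data frame.
#' @param genome the reference `annotated_genome`.
#' @param window search window beyond each end (bp, default 2000).
#' @param min_identity,min_cover a copy qualifies when a local alignment
#'   reaches `min_identity` over at least `min_cover` of the tRNA length.
#' @param scoring an [align_scoring()].
#' @return list: `flag`, `trna_id`, and the matched window intervals
#'   (`left_hit`, `right_hit`; 1-based within each window) used for masking.
#' @export
detect_trna_repeats <- function(cluster, genome, window = 2000L,
                                min_identity = 0.90, min_cover = 0.70,
                                scoring = align_scoring()) {
  trna <- genome$features[genome$features$type == "tRNA", , drop = FALSE]
  if (nrow(trna) == 0L)
    return(list(flag = FALSE, trna_id = NA_character_,
                left_hit = NULL, right_hit = NULL))
  w <- cluster_end_windows(genome, cluster, window)
  best <- NULL
  for (i in seq_len(nrow(trna))) {
    tseq <- substring(genome$seq, trna$start[i] + 1L, trna$end[i])
    tlen <- nchar(tseq)
    for (orient in c("+", "-")) {
      q <- if (orient == "+") tseq else revcomp(tseq)
      hl <- sw_align(q, w$left, scoring)
      hr <- sw_align(q, w$right, scoring)
      ok <- function(h) h$align_len >= min_cover * tlen &&
        !is.na(h$identity) && h$identity >= min_identity
      if (ok(hl) && ok(hr)) {
        best <- list(flag = TRUE, trna_id = trna$id[i],
                     left_hit = c(hl$b_start, hl$b_end),
                     right_hit = c(hr$b_start, hr$b_end))
        break
      }
    }
    if (!is.null(best)) break
  }
  best %||% list(flag = FALSE, trna_id = NA_character_,
                 left_hit = NULL, right_hit = NULL)
}

#' Detect generic direct repeats at the ends of an LCR cluster
#'
#' A segment flanked by homologous sequences in the same orientation can be
#' excised by recombination. The two end windows are locally aligned; the
#' cluster is flagged when the best alignment spans at least `min_len`
#' columns at `min_identity` *and* reaches a score equivalent to `min_len`
#' exact matches (`score >= match * min_len`). The score floor is what
#' gives the detector its specificity: the best local alignment of two
#' multi-kb windows reaches 15 columns at 85% identity by chance alone
#' (short micro-homologies are ubiquitous), whereas a score equivalent to a
#' 15 bp exact repeat is not attained by unrelated sequence. tRNA-derived
#' repeats (per the tRNA detector) and annotated IS elements are masked out
#' first so that they are not double-counted as generic repeats.
#'
#' @param cluster one cluster row.
#' @param genome the reference `annotated_genome`.
#' @param window window beyond each end (bp).
#' @param min_len minimum alignment length (bp).
#' @param min_identity minimum identity over the alignment.
#' @param scoring an [align_scoring()].
#' @param mask_trna result of [detect_trna_repeats()] for this cluster, or
#'   NULL to skip tRNA masking.
#' @param mask_is logical: mask annotated IS features inside the windows.
#' @return list: `flag`, `repeat_len`, `identity`, `score`.
#' @export
detect_direct_repeats <- function(cluster, genome, window = 2000L,
                                  min_len = 15L, min_identity = 0.85,
                                  scoring = align_scoring(),
                                  mask_trna = NULL, mask_is = TRUE) {
  w <- cluster_end_windows(genome, cluster, window)
  left <- w$left; right <- w$right
  mask_interval <- function(s, iv) {
    if (is.null(iv)) return(s)
    n <- iv[2] - iv[1] + 1L
    paste0(substr(s, 1L, iv[1] - 1L), strrep("N", n),
           substr(s, iv[2] + 1L, nchar(s)))
  }
  if (!is.null(mask_trna) && isTRUE(mask_trna$flag)) {
    left <- mask_interval(left, mask_trna$left_hit)
    right <- mask_interval(right, mask_trna$right_hit)
  }
  if (mask_is) {
    isf <- genome$features[!is.na(genome$features$is_family), , drop = FALSE]
    L <- nchar(genome$seq)
    mask_feats <- function(s, origin) {
      if (!nrow(isf)) return(s)
      wlen <- nchar(s)
      for (i in seq_len(nrow(isf))) {
        # window-local coordinates (window may wrap on circular genomes)
        off <- (isf$start[i] - origin) %% L
        if (off < wlen) {
          a <- off + 1L
          b <- min(wlen, off + (isf$end[i] - isf$start[i]))
          s <- mask_interval(s, c(a, b))
        }
      }
      s
    }
    left <- mask_feats(left, w$left_origin)
    right <- mask_feats(right, w$right_origin)
  }
  h <- sw_align(left, right, scoring)
  flag <- h$align_len >= min_len && !is.na(h$identity) &&
    h$identity >= min_identity && h$score >= scoring$match * min_len
  list(flag = flag, repeat_len = h$align_len,
       identity = h$identity, score = h$score)
}

#' Detect same-family IS elements at both ends of an LCR cluster
#'
#' Two insertion-sequence copies of one family flanking a region permit its
#' excision by homologous recombination. Flags the cluster when annotated
#' IS features occur inside both end windows and share a family.
#'
#' @param cluster one cluster row.
#' @param genome the reference `annotated_genome` (IS features carry
#'   `is_family` labels).
#' @param window window beyond each end (bp).
#' @return list: `flag`, `family`.
#' @export
detect_same_is <- function(cluster, genome, window = 2000L) {
  isf <- genome$features[!is.na(genome$features$is_family), , drop = FALSE]
  if (nrow(isf) == 0L) return(list(flag = FALSE, family = NA_character_))
  L <- nchar(genome$seq)
  w <- cluster_end_windows(genome, cluster, window)
  fams_in <- function(origin, wlen) {
    off <- (isf$start - origin) %% L
    isf$is_family[off < wlen]
  }
  lf <- fams_in(w$left_origin, nchar(w$left))
  rf <- fams_in(w$right_origin, nchar(w$right))
  shared <- intersect(lf, rf)
  if (length(shared)) list(flag = TRUE, family = sort(shared)[1])
  else list(flag = FALSE, family = NA_character_)
}

#' Classify the flanking elements of every LCR cluster
#'
#' @param clusters cluster data frame from [find_clusters()].
#' @param genome the reference `annotated_genome`.
#' @param window,min_len,min_identity detector thresholds.
#' @param scoring an [align_scoring()].
#' @return a flank-report data frame: one row per cluster with
#'   `trna_repeat`, `trna_id`, `direct_repeat`, `repeat_len`,
#'   `repeat_identity`, `same_is`, `is_family`.
#' @export
classify_flanks <- function(clusters, genome, window = 2000L, min_len = 15L,
                            min_identity = 0.85, scoring = align_scoring()) {
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    tr <- detect_trna_repeats(cl, genome, window, scoring = scoring)
    dr <- detect_direct_repeats(cl, genome, window, min_len, min_identity,
                                scoring, mask_trna = tr)
    si <- detect_same_is(cl, genome, window)
    data.frame(cluster_id = cl$cluster_id, start = cl$start, end = cl$end,
               n_lcr_genes = cl$n_lcr_genes,
               trna_repeat = tr$flag, trna_id = tr$trna_id,
               direct_repeat = dr$flag, repeat_len = dr$repeat_len,
               repeat_identity = dr$identity,
               same_is = si$flag, is_family = si$family,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), start = numeric(0),
               end = numeric(0), n_lcr_genes = integer(0),
               trna_repeat = logical(0), trna_id = character(0),
               direct_repeat = logical(0), repeat_len = integer(0),
               repeat_identity = numeric(0), same_is = logical(0),
               is_family = character(0), stringsAsFactors = FALSE)
}

#' Tabulate flank classes over nonredundant clusters
#'
#' Clusters found in several queries are deduplicated by identical
#' reference span (`start`, `end`) before counting; optionally,
#' near-identical spans (interval Jaccard >= `jaccard_merge`) are merged.
#'
#' @param reports flank-report data frames (one per query) or a single
#'   combined data frame.
#' @param jaccard_merge optional threshold in (0, 1\]; NULL disables
#'   near-duplicate merging.
#' @return one-row data frame: `total`, `trna_repeats`, `direct_repeats`,
#'   `same_is`.
#' @export
tabulate_flanks <- function(reports, jaccard_merge = NULL) {
  df <- if (is.data.frame(reports)) reports
        else if (length(reports)) do.call(rbind, reports) else NULL
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(total = 0L, trna_repeats = 0L, direct_repeats = 0L,
                      same_is = 0L))
  df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
  if (!is.null(jaccard_merge) && nrow(df) > 1L) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in 2:nrow(df)) for (j in which(keep[seq_len(i - 1L)])) {
      inter <- max(0, min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]))
      uni <- max(df$end[i], df$end[j]) - min(df$start[i], df$start[j])
      if (uni > 0 && inter / uni >= jaccard_merge) { keep[i] <- FALSE; break }
    }
    df <- df[keep, , drop = FALSE]
  }
  data.frame(total = nrow(df),
             trna_repeats = sum(df$trna_repeat),
             direct_repeats = sum(df$direct_repeat & !df$trna_repeat),
             same_is = sum(df$same_is))
}
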