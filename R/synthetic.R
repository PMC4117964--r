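#' Specification of a synthetic annotated reference genome
#'
#' The generator emulates a bacterial chromosome as an alternating layout of
#' intergenic regions (IGRs) and genes: `IGR g1 IGR g2 ... gN IGR`. Gene and
#' IGR lengths are drawn from geometric distributions truncated at 90 bp
#' (genes, rounded to codons) and 30 bp (IGRs) so that no degenerate segment
#' arises. A configurable subset of features is annotated as tRNA genes,
#' IS (insertion-sequence) transposase genes with family labels, and a
#' "highly expressed" set used as the codon-adaptation reference.
#'
#' @param n_genes number of gene-kind features (protein-coding plus RNA).
#' @param mean_gene_len,mean_igr_len mean lengths in bp.
#' @param gc_background GC fraction of intergenic sequence.
#' @param gc3,codon_bias parameters of the native [codon_model()].
#' @param n_trna,n_is number of tRNA genes and of IS-annotated genes.
#' @param is_families recycled family labels for IS features.
#' @param n_highly_expressed size of the codon-adaptation reference set.
#' @param circular logical; bacterial chromosomes default to circular.
#' @param seed integer seed; identical specs give byte-identical output.
#' @export
genome_spec <- function(n_genes = 200, mean_gene_len = 900, mean_igr_len = 150,
                        gc_background = 0.70, gc3 = 0.80, codon_bias = 2,
                        n_trna = 8, n_is = 6,
                        is_families = c("IS3", "IS110", "IS256"),
                        n_highly_expressed = 20, circular = TRUE, seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (mean_gene_len <= 0 || mean_igr_len <= 0) stop("mean lengths must be > 0")
  stop_if_not_fraction(gc_background, "gc_background")
  structure(list(n_genes = as.integer(n_genes),
                 mean_gene_len = mean_gene_len, mean_igr_len = mean_igr_len,
                 gc_background = gc_background, gc3 = gc3,
                 codon_bias = codon_bias,
                 n_trna = as.integer(min(n_trna, n_genes)),
                 n_is = as.integer(min(n_is, n_genes)),
                 is_families = is_families,
                 n_highly_expressed = as.integer(n_highly_expressed),
                 circular = isTRUE(circular), seed = as.integer(seed)),
            class = "genome_spec")
}

MIN_GENE_LEN <- 90L
MIN_IGR_LEN <- 30L
TRNA_LEN <- 76L

draw_gene_lengths <- function(n, mean_len) {
  p <- 3 / (max(mean_len - MIN_GENE_LEN, 3) + 3)
  MIN_GENE_LEN + 3L * rgeom(n, p)
}

draw_igr_lengths <- function(n, mean_len) {
  p <- 1 / (max(mean_len - MIN_IGR_LEN, 1) + 1)
  MIN_IGR_LEN + rgeom(n, p)
}

#' Generate an annotated reference genome
#'
#' @param spec a [genome_spec()].
#' @return an `annotated_genome`: genome sequence plus a feature table
#'   (0-based half-open coordinates internally; exported GFF3 is 1-based).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    model <- codon_model(gc3 = spec$gc3, bias = spec$codon_bias)

    trna_idx <- sort(sample.int(n, spec$n_trna))
    pool <- setdiff(seq_len(n), trna_idx)
    is_idx <- sort(sample(pool, min(spec$n_is, length(pool))))
    he_pool <- setdiff(pool, is_idx)
    he_idx <- sort(sample(he_pool, min(spec$n_highly_expressed, length(he_pool))))

    gene_len <- draw_gene_lengths(n, spec$mean_gene_len)
    gene_len[trna_idx] <- TRNA_LEN
    igr_len <- draw_igr_lengths(n + 1L, spec$mean_igr_len)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    parts <- character(2L * n + 1L)
    feat <- vector("list", n)
    pos <- 0L
    amino_acids <- NULL
    for (i in seq_len(n)) {
      parts[2L * i - 1L] <- sample_noncoding(igr_len[i], spec$gc_background)
      pos <- pos + igr_len[i]
      is_trna <- i %in% trna_idx
      body <- if (is_trna) sample_noncoding(TRNA_LEN, spec$gc_background)
              else sample_cds(gene_len[i], model)
      placed <- if (strand[i] == "+") body else revcomp(body)
      parts[2L * i] <- placed
      id <- if (is_trna) sprintf("FSYN_R%04d", i) else sprintf("FSYN_%04d", i)
      feat[[i]] <- data.frame(
        id = id,
        type = if (is_trna) "tRNA" else "gene",
        start = pos, end = pos + nchar(body),
        strand = strand[i],
        is_family = NA_character_,
        highly_expressed = i %in% he_idx,
        stringsAsFactors = FALSE)
      pos <- pos + nchar(body)
    }
    parts[2L * n + 1L] <- sample_noncoding(igr_len[n + 1L], spec$gc_background)
    features <- do.call(rbind, feat)
    features$is_family[match(is_idx, seq_len(n))] <-
      rep_len(spec$is_families, length(is_idx))

    structure(list(genome_id = sprintf("synref_seed%d", spec$seed),
                   seq = paste0(parts, collapse = ""),
                   features = features,
                   circular = spec$circular,
                   codon_model = model,
                   spec = spec),
              class = "annotated_genome")
  })
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d features (%d tRNA, %d IS)\n",
              x$genome_id, format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), sum(x$features$type == "tRNA"),
              sum(!is.na(x$features$is_family))))
  invisible(x)
}

#' Extract feature sequences on the annotated (coding) strand
#'
#' @param genome an `annotated_genome`.
#' @param ids feature ids; default all protein-coding genes.
#' @return a named [Biostrings::DNAStringSet].
#' @export
extract_cds <- function(genome, ids = NULL) {
  feats <- genome$features
  if (is.null(ids)) ids <- feats$id[feats$type == "gene"]
  rows <- feats[match(ids, feats$id), , drop = FALSE]
  if (anyNA(rows$id)) stop("unknown feature id(s)")
  seqs <- substring(genome$seq, rows$start + 1L, rows$end)
  minus <- rows$strand == "-"
  if (any(minus)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
    seqs[minus] <- rc
  }
  setNames(Biostrings::DNAStringSet(seqs), rows$id)
}

#' Plan of structural edits deriving a query genome from the reference
#'
#' Deletions are runs of consecutive gene-kind features: the span from the
#' start of `first` to the end of `last` (genes plus the IGRs between them)
#' is excised, modelling loss of a gene cluster (`first != last`) or of an
#' isolated gene (`first == last`). Each deletion may carry a `flank_style`
#' describing the mobile-element context planted around the span in the
#' reference by [install_flank_elements()]. Insertions splice foreign
#' gene-like sequence (drawn from a GC3/bias-shifted codon model) into an
#' IGR, modelling acquired DNA present in the query but absent from the
#' reference.
#'
#' @param deletions list of `list(first=, last=, flank_style=)` with feature
#'   ids; `flank_style` one of "none", "direct_repeat", "trna_repeat",
#'   "same_is".
#' @param insertions list of `list(anchor=, n_genes=, gc3_shift=, bias=)`;
#'   `anchor` is a 0-based reference position that must fall inside an IGR.
#' @param seed integer seed for the edit content.
#' @export
edit_plan <- function(deletions = list(), insertions = list(), seed = 1) {
  norm_del <- lapply(deletions, function(d) {
    list(first = d$first, last = d$last %||% d$first,
         flank_style = match.arg(d$flank_style %||% "none",
                                 c("none", "direct_repeat", "trna_repeat", "same_is")))
  })
  norm_ins <- lapply(insertions, function(i) {
    list(anchor = i$anchor, n_genes = i$n_genes %||% 5L,
         gc3_shift = i$gc3_shift %||% -0.15, bias = i$bias %||% 0,
         flank_style = match.arg(i$flank_style %||% "none",
                                 c("none", "direct_repeat", "trna_repeat", "same_is")))
  })
  structure(list(deletions = norm_del, insertions = norm_ins,
                 seed = as.integer(seed)),
            class = "edit_plan")
}

# Resolve a deletion run to its 0-based half-open reference interval and the
# gene-kind feature ids it spans.
deletion_interval <- function(genome, del) {
  feats <- genome$features
  i1 <- match(del$first, feats$id); i2 <- match(del$last, feats$id)
  if (is.na(i1) || is.na(i2)) stop("deletion names unknown feature id(s)")
  if (i2 < i1) stop("deletion run must be in genome order")
  list(start = feats$start[i1], end = feats$end[i2],
       gene_ids = feats$id[i1:i2])
}

#' Plant flanking mobile elements around planned deletions in the reference
#'
#' Flank classification inspects the *reference* sequence around the ends of
#' an absent region, so the elements must exist in the reference before
#' queries are derived. For every planned deletion with a non-"none"
#' `flank_style`, this splices into the two IGRs immediately flanking the
#' deletion span: a 20 bp direct repeat (`direct_repeat`), an unannotated
#' copy of one annotated tRNA gene at both ends (`trna_repeat`), or two
#' annotated IS copies of a single family (`same_is`). All downstream plans
#' must reference the returned genome.
#'
#' @param genome an `annotated_genome`.
#' @param plans one [edit_plan()] or a list of them (flanked deletions are
#'   pooled across plans).
#' @param repeat_len length of generic direct repeats (bp).
#' @param margin distance (bp) between a planted element and the deletion
#'   span boundary.
#' @param seed integer seed for element content.
#' @return the modified `annotated_genome`.
#' @export
install_flank_elements <- function(genome, plans, repeat_len = 20L,
                                   margin = 10L, seed = 1) {
  if (inherits(plans, "edit_plan")) plans <- list(plans)
  dels <- do.call(c, lapply(plans, function(p)
    Filter(function(d) d$flank_style != "none", p$deletions)))
  if (length(dels) == 0L) return(genome)

  with_seed(seed, {
    # one splice job per element; apply right-to-left so coordinates stay valid
    jobs <- list()
    is_copy_n <- 0L
    for (d in dels) {
      iv <- deletion_interval(genome, d)
      if (d$flank_style == "direct_repeat") {
        rep_seq <- sample_noncoding(repeat_len, genome$spec$gc_background %||% 0.5)
        jobs <- c(jobs, list(
          list(at = iv$start - margin, seq = rep_seq, feat = NULL),
          list(at = iv$end + margin, seq = rep_seq, feat = NULL)))
      } else if (d$flank_style == "trna_repeat") {
        trna <- genome$features[genome$features$type == "tRNA", , drop = FALSE]
        if (nrow(trna) == 0L) stop("trna_repeat flank requires annotated tRNA genes")
        pick <- trna[sample.int(nrow(trna), 1L), ]
        tseq <- substring(genome$seq, pick$start + 1L, pick$end)
        if (pick$strand == "-") tseq <- revcomp(tseq)
        jobs <- c(jobs, list(
          list(at = iv$start - margin, seq = tseq, feat = NULL),
          list(at = iv$end + margin, seq = tseq, feat = NULL)))
      } else { # same_is
        fams <- unique(stats::na.omit(genome$features$is_family))
        fam <- if (length(fams)) sample(fams, 1L) else "IS3"
        is_seq <- sample_cds(798L, genome$codon_model %||% codon_model())
        for (at in c(iv$start - margin, iv$end + margin)) {
          is_copy_n <- is_copy_n + 1L
          jobs <- c(jobs, list(list(
            at = at, seq = is_seq,
            feat = data.frame(id = sprintf("FSYN_ISc%02d", is_copy_n),
                              type = "mobile_genetic_element",
                              start = at, end = at + nchar(is_seq),
                              strand = "+", is_family = fam,
                              highly_expressed = FALSE,
                              stringsAsFactors = FALSE))))
        }
      }
    }
    ord <- order(vapply(jobs, `[[`, numeric(1), "at"), decreasing = TRUE)
    seq <- genome$seq
    feats <- genome$features
    for (j in jobs[ord]) {
      at <- j$at
      if (at < 0L || at > nchar(seq)) stop("flank splice point outside genome")
      if (any(feats$start < at & feats$end > at))
        stop("flank splice point falls inside an annotated feature")
      len <- nchar(j$seq)
      seq <- paste0(substr(seq, 1L, at), j$seq,
                    substr(seq, at + 1L, nchar(seq)))
      shift <- feats$start >= at
      feats$start[shift] <- feats$start[shift] + len
      feats$end[shift] <- feats$end[shift] + len
      if (!is.null(j$feat)) feats <- rbind(feats, j$feat)
    }
    feats <- feats[order(feats$start), ]
    rownames(feats) <- NULL
    genome$seq <- seq
    genome$features <- feats
    genome
  })
}

#' Apply an edit plan: derive a query genome and its truth manifest
#'
#' @param genome the (flank-decorated) reference `annotated_genome`.
#' @param plan an [edit_plan()].
#' @param query_id identifier recorded in the manifest.
#' @return list with `seq` (query genome sequence) and `manifest`
#'   (a `truth_manifest`).
#' @export
apply_edits <- function(genome, plan, query_id = "query") {
  stopifnot(inherits(genome, "annotated_genome"), inherits(plan, "edit_plan"))
  L <- nchar(genome$seq)
  feats <- genome$features
  gene_kind <- feats$type %in% c("gene", "tRNA")

  dels <- lapply(plan$deletions, function(d) {
    iv <- deletion_interval(genome, d)
    c(iv, list(flank_style = d$flank_style))
  })
  if (length(dels) > 1L) {
    s <- vapply(dels, `[[`, numeric(1), "start")
    e <- vapply(dels, `[[`, numeric(1), "end")
    o <- order(s)
    if (any(s[o][-1] < e[o][-length(e)])) stop("overlapping deletions")
    dels <- dels[o]
  }

  with_seed(plan$seed, {
    ins <- lapply(plan$insertions, function(i) {
      at <- as.integer(i$anchor)
      if (at < 0L || at > L) stop("insertion anchor outside reference")
      inside_gene <- any(feats$start < at & feats$end > at & gene_kind)
      if (inside_gene) stop("insertion anchored inside a gene")
      model <- shift_codon_model(genome$codon_model %||% codon_model(),
                                 gc3_shift = i$gc3_shift, bias = i$bias)
      n <- as.integer(i$n_genes)
      glen <- draw_gene_lengths(n, genome$spec$mean_gene_len %||% 900)
      ilen <- draw_igr_lengths(n + 1L, genome$spec$mean_igr_len %||% 150)
      cds <- vapply(glen, sample_cds, character(1), model = model)
      igrs <- vapply(ilen, sample_noncoding, character(1),
                     gc = min(max((genome$spec$gc_background %||% 0.7) +
                                    i$gc3_shift, 0.05), 0.95))
      segseq <- paste0(paste0(igrs[seq_len(n)], cds, collapse = ""), igrs[n + 1L])
      list(at = at, seq = segseq, cds = cds, flank_style = i$flank_style)
    })
    if (length(ins) > 1L) ins <- ins[order(vapply(ins, `[[`, numeric(1), "at"))]

    # deletion/insertion edit points must not interleave within one another
    del_iv <- if (length(dels))
      cbind(vapply(dels, `[[`, numeric(1), "start"),
            vapply(dels, `[[`, numeric(1), "end")) else matrix(numeric(0), 0, 2)
    for (iv in ins) {
      if (nrow(del_iv) && any(iv$at > del_iv[, 1] & iv$at < del_iv[, 2]))
        stop("insertion anchored inside a deleted span")
    }

    # assemble query left-to-right
    points <- rbind(
      if (length(dels)) data.frame(at = del_iv[, 1], end = del_iv[, 2],
                                   type = "del", idx = seq_along(dels)),
      if (length(ins)) data.frame(at = vapply(ins, `[[`, numeric(1), "at"),
                                  end = vapply(ins, `[[`, numeric(1), "at"),
                                  type = "ins", idx = seq_along(ins)))
    out <- character(0)
    ins_rows <- list()
    cur <- 0L
    qpos <- 0L
    if (!is.null(points) && nrow(points)) {
      points <- points[order(points$at), ]
      for (k in seq_len(nrow(points))) {
        keep <- substr(genome$seq, cur + 1L, points$at[k])
        out <- c(out, keep)
        qpos <- qpos + nchar(keep)
        if (points$type[k] == "ins") {
          iseq <- ins[[points$idx[k]]]$seq
          out <- c(out, iseq)
          ins_rows[[length(ins_rows) + 1L]] <- data.frame(
            ref_anchor = points$at[k], query_start = qpos,
            query_end = qpos + nchar(iseq), length = nchar(iseq),
            flank_style = ins[[points$idx[k]]]$flank_style,
            stringsAsFactors = FALSE)
          qpos <- qpos + nchar(iseq)
        }
        cur <- as.integer(points$end[k])
      }
    }
    out <- c(out, substr(genome$seq, cur + 1L, L))
    qseq <- paste0(out, collapse = "")

    del_genes <- unique(unlist(lapply(dels, `[[`, "gene_ids")))
    # genes partially (not fully) overlapped by a deleted interval
    partial <- character(0)
    if (nrow(del_iv)) {
      for (r in seq_len(nrow(del_iv))) {
        ov <- feats$start < del_iv[r, 2] & feats$end > del_iv[r, 1] & gene_kind
        full <- feats$start >= del_iv[r, 1] & feats$end <= del_iv[r, 2]
        partial <- c(partial, feats$id[ov & !full])
      }
    }
    del_df <- if (length(dels)) data.frame(
      ref_start = del_iv[, 1], ref_end = del_iv[, 2],
      length = del_iv[, 2] - del_iv[, 1],
      n_genes = vapply(dels, function(d) length(d$gene_ids), integer(1)),
      flank_style = vapply(dels, `[[`, character(1), "flank_style"),
      stringsAsFactors = FALSE) else
      data.frame(ref_start = numeric(0), ref_end = numeric(0),
                 length = numeric(0), n_genes = integer(0),
                 flank_style = character(0))
    ins_df <- if (length(ins_rows)) do.call(rbind, ins_rows) else
      data.frame(ref_anchor = numeric(0), query_start = numeric(0),
                 query_end = numeric(0), length = numeric(0),
                 flank_style = character(0))

    manifest <- structure(list(
      query_id = query_id,
      reference_id = genome$genome_id,
      deleted_genes_full = setdiff(del_genes, partial),
      deleted_genes_partial = unique(partial),
      deletions = del_df,
      insertions = ins_df,
      foreign_cds = Biostrings::DNAStringSet(
        unlist(lapply(ins, `[[`, "cds")) %||% character(0)),
      reference_size = L,
      expected_size = L - sum(del_df$length) + sum(ins_df$length)),
      class = "truth_manifest")
    stopifnot(nchar(qseq) == manifest$expected_size)
    list(seq = qseq, manifest = manifest)
  })
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf(
    "<truth_manifest> %s vs %s: %d deletions (%d genes), %d insertions, %s -> %s bp\n",
    x$query_id, x$reference_id, nrow(x$deletions),
    length(x$deleted_genes_full), nrow(x$insertions),
    format(x$reference_size, big.mark = ","),
    format(x$expected_size, big.mark = ",")))
  invisible(x)
}

#' Specification of a short-read simulation
#'
#' @param read_len read length in bp (50 by default, fragment-end style).
#' @param depth target fold-coverage; the read count is
#'   `ceiling(depth * genome_len / read_len)`.
#' @param sub_error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @export
read_sim_spec <- function(read_len = 50L, depth = 20, sub_error_rate = 0.01,
                          seed = 1) {
  if (depth <= 0) stop("depth must be > 0")
  stop_if_not_fraction(sub_error_rate, "sub_error_rate")
  structure(list(read_len = as.integer(read_len), depth = depth,
                 sub_error_rate = sub_error_rate, seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate uniform-depth single-end reads with substitution errors
#'
#' Reads start uniformly on the (linearized) genome, half on each strand;
#' substitution errors are independent per base. Read names encode the
#' 0-based source position and strand (`read_<i>:<pos>:<strand>`) for
#' provenance checks.
#'
#' @param seq genome sequence (character or DNAString).
#' @param spec a [read_sim_spec()].
#' @return a `read_set`: named [Biostrings::DNAStringSet] plus a truth
#'   data frame of source positions.
#' @export
simulate_reads <- function(seq, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  seq <- as_dna_string(seq)
  L <- nchar(seq)
  rl <- spec$read_len
  if (L < rl) stop("genome shorter than read length")
  n <- as.integer(ceiling(spec$depth * L / rl))
  with_seed(spec$seed, {
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- substring(seq, starts + 1L, starts + rl)
    minus <- strand == "-"
    if (any(minus)) reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
    if (spec$sub_error_rate > 0) {
      chars <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
      hit <- which(runif(length(chars)) < spec$sub_error_rate)
      if (length(hit)) {
        # substitute with one of the three other bases
        alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                      nrow = 3,
                      dimnames = list(NULL, c("A", "C", "G", "T")))
        pick <- sample.int(3L, length(hit), replace = TRUE)
        chars[hit] <- alt[cbind(pick, match(chars[hit], colnames(alt)))]
        m <- matrix(chars, nrow = rl)
        reads <- do.call(paste0, lapply(seq_len(rl), function(i) m[i, ]))
      }
    }
    names(reads) <- sprintf("read_%07d:%d:%s", seq_len(n), starts, strand)
    structure(list(reads = Biostrings::DNAStringSet(setNames(reads, names(reads))),
                   truth = data.frame(start = starts, strand = strand,
                                      stringsAsFactors = FALSE),
                   spec = spec),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads x %d bp (depth %.1f, error %.3g)\n",
              length(x$reads), x$spec$read_len, x$spec$depth,
              x$spec$sub_error_rate))
  invisible(x)
}
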