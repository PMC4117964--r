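#' Run the full in silico CGH pipeline over one reference and several queries
#'
#' For every query: build the coverage mask (mapping reads with the
#' built-in mapper, or ingesting SAM/BAM), dissect the reference, compute
#' coverage rates, flag LCR segments, find LCR gene clusters and classify
#' their flanks. Across queries: the LCR summary table, the nonredundant
#' Venn partition, the flank-class table over nonredundant clusters, and
#' per-gene GC3/CAI records grouped by nonredundant-LCR membership.
#'
#' @param reference an `annotated_genome` (or `list(fasta=, gff3=)` paths).
#' @param queries named list; each element is a `read_set`, DNAStringSet,
#'   FASTQ path, or `list(alignments = <SAM/BAM path>)`.
#' @param lcr_threshold LCR coverage-rate threshold (percentage).
#' @param mapper a [mapper_config()].
#' @param flank list of flank-detector settings (`window`, `min_len`,
#'   `min_identity`).
#' @param out_dir optional directory; when given, all result tables are
#'   written as TSV plus a machine-readable JSON run manifest.
#' @param seed recorded in the run manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return a result bundle (list) with per-query and cross-query tables.
#' @export
run_pipeline <- function(reference, queries, lcr_threshold = 20,
                         mapper = mapper_config(),
                         flank = list(window = 2000L, min_len = 15L,
                                      min_identity = 0.85),
                         out_dir = NULL, seed = NA_integer_) {
  if (is.list(reference) && !inherits(reference, "annotated_genome"))
    reference <- read_reference(reference$fasta, reference$gff3)
  if (is.null(names(queries)) || anyNA(names(queries)))
    stop("queries must be a named list")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  segments <- stage("segmentation", dissect(reference))
  ref_len <- nchar(reference$seq)
  total_genes <- sum(reference$features$type %in% GENE_KIND_TYPES)

  per_query <- list()
  for (q in names(queries)) {
    input <- queries[[q]]
    mask <- stage(paste0("mapping:", q), {
      if (is.list(input) && !is.null(input$alignments))
        load_alignments(input$alignments, ref_len,
                        genome_id = reference$genome_id)
      else map_reads(input, reference, mapper)
    })
    covtab <- stage(paste0("coverage:", q),
                    call_lcr(coverage_rates(mask, segments), lcr_threshold))
    cl <- stage(paste0("clusters:", q), find_clusters(covtab))
    fl <- stage(paste0("flanks:", q),
                classify_flanks(cl$clusters, reference,
                                window = flank$window %||% 2000L,
                                min_len = flank$min_len %||% 15L,
                                min_identity = flank$min_identity %||% 0.85))
    lcr_gene_ids <- covtab$feature_id[covtab$lcr_flag & covtab$kind == "gene"]
    lcr_lengths <- covtab$length[covtab$lcr_flag]
    per_query[[q]] <- list(
      mask = mask, coverage = covtab, clusters = cl, flanks = fl,
      lcr_gene_ids = lcr_gene_ids,
      histogram = rate_histogram(covtab),
      track = position_track(covtab),
      summary = summarize_query(length(lcr_gene_ids), total_genes,
                                query_id = q,
                                expected_size = expected_genome_size(
                                  ref_len, lcr_lengths)))
  }

  summary_tab <- do.call(rbind, lapply(per_query, `[[`, "summary"))
  rownames(summary_tab) <- NULL
  callsets <- lapply(per_query, `[[`, "lcr_gene_ids")
  venn <- if (length(callsets) >= 2) nonredundant_partition(callsets) else NULL
  nonredundant <- unique(unlist(callsets, use.names = FALSE))
  flank_table <- tabulate_flanks(lapply(per_query, `[[`, "flanks"))
  props <- stage("properties",
                 gene_properties(reference, lcr_nonredundant = nonredundant))
  contrast <- if (any(props$lcr_nonredundant) && !all(props$lcr_nonredundant))
    group_contrast(props) else NULL

  bundle <- list(reference_id = reference$genome_id,
                 genome_length = ref_len, total_genes = total_genes,
                 lcr_threshold = lcr_threshold,
                 per_query = per_query, summary = summary_tab,
                 venn = venn, nonredundant_lcr_genes = nonredundant,
                 flank_table = flank_table, properties = props,
                 contrast = contrast, seed = seed)

  if (!is.null(out_dir)) write_bundle(bundle, out_dir, mapper, flank)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir, mapper, flank) {
  p <- function(...) file.path(out_dir, ...)
  for (q in names(bundle$per_query)) {
    pq <- bundle$per_query[[q]]
    cov <- pq$coverage
    write_tsv_file(data.frame(
      segment_id = cov$segment_id, kind = cov$kind,
      start = cov$start + 1L, end = cov$end, length = cov$length,
      covered_bases = cov$covered_bases,
      coverage_rate = round(cov$coverage_rate, 4),
      lcr_flag = cov$lcr_flag), p(sprintf("coverage_%s.tsv", q)))
    write_tsv_file(pq$clusters$clusters, p(sprintf("clusters_%s.tsv", q)))
    write_tsv_file(pq$flanks, p(sprintf("flanks_%s.tsv", q)))
    write_tsv_file(pq$track, p(sprintf("track_%s.tsv", q)))
    write_tsv_file(data.frame(bin = names(pq$histogram),
                              count = unname(pq$histogram)),
                   p(sprintf("histogram_%s.tsv", q)))
  }
  write_tsv_file(bundle$summary, p("summary.tsv"))
  if (!is.null(bundle$venn)) write_tsv_file(bundle$venn, p("venn.tsv"))
  write_tsv_file(bundle$flank_table, p("flank_table.tsv"))
  write_tsv_file(bundle$properties, p("properties.tsv"))
  manifest <- list(
    package = "iscgh",
    version = as.character(utils::packageVersion("iscgh")),
    reference_id = bundle$reference_id,
    genome_length = bundle$genome_length,
    total_genes = bundle$total_genes,
    lcr_threshold = bundle$lcr_threshold,
    mapper = unclass(mapper), flank = flank,
    queries = names(bundle$per_query), seed = bundle$seed)
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

# ---------------------------------------------------------------------------
# Demo scenario: one high-GC reference, four query strains emulating the
# contrast between a shuffling-prone broad-host-range group (heavy gene
# loss plus foreign insertions), an intermediate group, and conservative
# narrow-host-range strains (little or no loss).

demo_plans <- function(genome, seed) {
  # choose non-overlapping, non-adjacent runs of consecutive gene-kind
  # features per query, avoiding IS-annotated and tRNA genes; large runs
  # are placed first so that the genome does not fragment
  feats <- genome$features[genome$features$type %in% GENE_KIND_TYPES, ]
  feats <- feats[order(feats$start), ]
  n <- nrow(feats)
  avoid <- !is.na(feats$is_family) | feats$type == "tRNA"

  # baseline plan is defined for a 200-gene reference (5% / 15% / 30% of
  # genes deleted); smaller demo genomes scale the runs proportionally
  f <- n / 200
  sc <- function(x) pmax(1L, as.integer(round(x * f)))
  iso <- function(x) max(0L, as.integer(round(x * f)))
  wanted <- rbind(
    data.frame(query = "casuarina_mild",
               size = c(sc(c(2L, 3L)), rep(1L, iso(5))), flank = "none"),
    data.frame(query = "alnus_like",
               size = c(sc(c(5L, 8L, 12L)), rep(1L, iso(5))),
               flank = c("trna_repeat", "direct_repeat", "same_is",
                         rep("none", iso(5)))),
    data.frame(query = "elaeagnus_like",
               size = c(sc(c(2L, 3L, 4L, 6L, 8L, 10L, 12L)),
                        rep(1L, iso(15))),
               flank = "none"))

  with_seed(seed, {
    used <- rep(FALSE, n)
    place <- function(size) {
      ok <- which(vapply(seq_len(n - size + 1L), function(i) {
        lo <- max(1L, i - 1L); hi <- min(n, i + size)
        !any(used[lo:hi]) && !any(avoid[i:(i + size - 1L)])
      }, logical(1)))
      if (!length(ok)) stop("cannot place deletion run")
      i <- sample(ok, 1L)
      used[i:(i + size - 1L)] <<- TRUE
      list(first = feats$id[i], last = feats$id[i + size - 1L])
    }
    wanted <- wanted[order(-wanted$size), ]
    runs <- lapply(seq_len(nrow(wanted)), function(k) {
      r <- place(wanted$size[k])
      r$flank_style <- wanted$flank[k]
      r$query <- wanted$query[k]
      r
    })
    plans <- list(casuarina_like = edit_plan(seed = child_seed(seed, "q1")))
    for (q in unique(wanted$query)) {
      dels <- Filter(function(r) r$query == q, runs)
      dels <- lapply(dels, function(r) r[c("first", "last", "flank_style")])
      plans[[q]] <- edit_plan(deletions = dels, seed = child_seed(seed, q))
    }
    plans[c("casuarina_like", "casuarina_mild", "alnus_like",
            "elaeagnus_like")]
  })
}

# IGR midpoints of the (decorated) reference usable as insertion anchors,
# at least `clear` bp from any feature and from deleted spans.
pick_insertion_anchors <- function(genome, plans, k, seed, clear = 10L) {
  feats <- genome$features
  feats <- feats[order(feats$start), ]
  gaps <- data.frame(s = head(feats$end, -1), e = tail(feats$start, -1))
  gaps <- gaps[gaps$e - gaps$s >= 2L * clear + 2L, ]
  mid <- floor((gaps$s + gaps$e) / 2)
  del_iv <- do.call(rbind, lapply(plans, function(p)
    do.call(rbind, lapply(p$deletions, function(d) {
      iv <- deletion_interval(genome, d)
      c(iv$start, iv$end)
    }))))
  if (!is.null(del_iv) && nrow(del_iv))
    mid <- mid[!vapply(mid, function(m)
      any(m > del_iv[, 1] - clear & m < del_iv[, 2] + clear), logical(1))]
  with_seed(seed, sample(mid, k))
}

#' Build and analyze a self-contained synthetic four-strain study
#'
#' Generates a ~200-gene annotated reference, derives four query genomes
#' with known edits — no loss (`casuarina_like`), 5% of genes deleted
#' (`casuarina_mild`), 15% in clusters of 5/8/12 plus isolated genes with
#' tRNA-repeat / direct-repeat / same-IS flanks (`alnus_like`), and 30%
#' deleted plus three foreign insertions (`elaeagnus_like`) — simulates
#' 50 bp reads, runs the full pipeline, and scores recovery against the
#' truth manifests.
#'
#' @param seed master integer seed.
#' @param depth read depth (fold-coverage).
#' @param error per-base substitution error rate.
#' @param n_genes reference gene count.
#' @param out_dir optional output directory passed to [run_pipeline()].
#' @return list: `genome`, `plans`, `manifests`, `reads`, pipeline
#'   `bundle`, and truth-recovery `metrics`.
#' @export
make_demo <- function(seed = 1, depth = 20, error = 0.01, n_genes = 200,
                      out_dir = NULL) {
  genome <- generate_reference(genome_spec(
    n_genes = n_genes,
    n_trna = max(2L, as.integer(round(8 * n_genes / 200))),
    n_is = max(2L, as.integer(round(6 * n_genes / 200))),
    n_highly_expressed = max(5L, as.integer(round(20 * n_genes / 200))),
    seed = child_seed(seed, "ref")))
  plans <- demo_plans(genome, child_seed(seed, "plans"))
  genome <- install_flank_elements(genome, plans,
                                   seed = child_seed(seed, "flanks"))
  # foreign insertions are anchored on the decorated reference so that the
  # anchors stay clear of features and of every planned deletion span
  anchors <- pick_insertion_anchors(genome, plans, 3L,
                                    child_seed(seed, "anchors"))
  plans$elaeagnus_like <- edit_plan(
    deletions = plans$elaeagnus_like$deletions,
    insertions = lapply(anchors, function(a) list(anchor = a, n_genes = 5L)),
    seed = plans$elaeagnus_like$seed)
  manifests <- list(); reads <- list()
  for (q in names(plans)) {
    ed <- apply_edits(genome, plans[[q]], query_id = q)
    manifests[[q]] <- ed$manifest
    reads[[q]] <- simulate_reads(ed$seq, read_sim_spec(
      depth = depth, sub_error_rate = error,
      seed = child_seed(seed, paste0("reads_", q))))
  }
  bundle <- run_pipeline(genome, reads, out_dir = out_dir, seed = seed)
  metrics <- demo_metrics(bundle, manifests, plans)
  list(genome = genome, plans = plans, manifests = manifests,
       reads = reads, bundle = bundle, metrics = metrics)
}

demo_metrics <- function(bundle, manifests, plans) {
  per <- lapply(names(manifests), function(q) {
    truth <- manifests[[q]]$deleted_genes_full
    calls <- bundle$per_query[[q]]$lcr_gene_ids
    tp <- length(intersect(calls, truth))
    precision <- if (length(calls)) tp / length(calls) else 1
    recall <- if (length(truth)) tp / length(truth) else 1
    cov <- bundle$per_query[[q]]$coverage
    partial <- cov$covered_bases > 0 & cov$covered_bases < cov$length
    ins_len <- sum(manifests[[q]]$insertions$length)
    size_err <- abs(bundle$per_query[[q]]$summary$expected_size -
                      (manifests[[q]]$expected_size - ins_len))
    planted <- vapply(plans[[q]]$deletions,
                      function(d) length(deletion_interval_ids(bundle, d)),
                      integer(1))
    data.frame(query_id = q, n_truth = length(truth), n_called = length(calls),
               precision = precision, recall = recall,
               expected_size = bundle$per_query[[q]]$summary$expected_size,
               manifest_size = manifests[[q]]$expected_size,
               inserted_len = ins_len, size_error = size_err,
               size_tolerance = sum(cov$length[partial]),
               n_planted_clusters = sum(planted >= 2L),
               n_planted_isolated = sum(planted == 1L),
               n_found_clusters = nrow(bundle$per_query[[q]]$clusters$clusters),
               n_independent = length(
                 bundle$per_query[[q]]$clusters$independent_gene_ids),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  hist_all <- Reduce(`+`, lapply(bundle$per_query, `[[`, "histogram"))
  bimodal <- (hist_all[1] + hist_all[length(hist_all)]) / sum(hist_all)
  list(per_query = per, bimodal_fraction = unname(bimodal))
}

# gene ids spanned by one planned deletion, resolved against the reference
# used in the bundle (count only; id lookup happens in the truth manifest)
deletion_interval_ids <- function(bundle, d) {
  cov <- bundle$per_query[[1]]$coverage
  genes <- cov$feature_id[cov$kind == "gene"]
  i1 <- match(d$first, genes); i2 <- match(d$last, genes)
  if (is.na(i1) || is.na(i2)) return(0L)
  genes[i1:i2]
}
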