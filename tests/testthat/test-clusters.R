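# small flagged segment tables built directly
flag_tab <- function(kinds, flags, ids = NULL) {
  n <- length(kinds)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  data.frame(segment_id = ids, kind = kinds,
             start = (seq_len(n) - 1) * 100, end = seq_len(n) * 100,
             length = 100, rank = seq_len(n),
             feature_id = ifelse(kinds == "gene", ids, NA_character_),
             lcr_flag = flags, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cluster definition: >=2 LCR genes in one consecutive LCR run", {
  # gene-IGR-gene, all LCR: one cluster of two genes
  r <- find_clusters(flag_tab(c("gene", "IGR", "gene"), c(TRUE, TRUE, TRUE)))
  expect_equal(nrow(r$clusters), 1L)
  expect_equal(r$clusters$n_lcr_genes, 2L)
  expect_equal(r$independent_gene_ids, character(0))

  # a non-LCR IGR breaks the run: two independent genes, no cluster
  r2 <- find_clusters(flag_tab(c("gene", "IGR", "gene"),
                               c(TRUE, FALSE, TRUE)))
  expect_equal(nrow(r2$clusters), 0L)
  expect_equal(length(r2$independent_gene_ids), 2L)

  # IGR-only LCR runs form no cluster but are recorded
  r3 <- find_clusters(flag_tab(c("gene", "IGR", "gene"),
                               c(FALSE, TRUE, FALSE)))
  expect_equal(nrow(r3$clusters), 0L)
  expect_equal(length(r3$igr_only_runs), 1L)
})

test_that("cluster accounting satisfies the partition invariant", {
  set.seed(5)
  for (k in 1:25) {
    n <- sample(10:60, 1)
    kinds <- rep(c("gene", "IGR"), length.out = n)
    flags <- runif(n) < 0.4
    tab <- flag_tab(kinds, flags)
    r <- find_clusters(tab)
    total_lcr_genes <- sum(flags & kinds == "gene")
    in_clusters <- sum(r$clusters$n_lcr_genes)
    expect_equal(in_clusters + length(r$independent_gene_ids),
                 total_lcr_genes)
    # idempotence
    r2 <- find_clusters(tab)
    expect_identical(r, r2)
    # clusters are disjoint, non-adjacent runs of LCR segments
    if (nrow(r$clusters) > 1) {
      members <- lapply(strsplit(r$clusters$member_ids, ","), match,
                        table = tab$segment_id)
      for (i in seq_along(members)) {
        expect_true(all(tab$lcr_flag[members[[i]]]))
        expect_true(all(diff(members[[i]]) == 1))
      }
      all_m <- sort(unlist(members))
      expect_false(any(duplicated(all_m)))
    }
  }
})

test_that("a circular genome joins LCR runs across the origin", {
  tab <- flag_tab(c("gene", "IGR", "gene", "IGR", "gene"),
                  c(TRUE, FALSE, FALSE, TRUE, TRUE))
  attr(tab, "circular") <- TRUE
  r <- find_clusters(tab)
  expect_equal(nrow(r$clusters), 1L)
  expect_equal(r$clusters$n_lcr_genes, 2L)
  expect_true(r$clusters$wraps)
})

test_that("the IGR gap tolerance can bridge short non-LCR IGRs", {
  tab <- flag_tab(c("gene", "IGR", "gene"), c(TRUE, FALSE, TRUE))
  r0 <- find_clusters(tab, igr_gap_tolerance = 0)
  expect_equal(nrow(r0$clusters), 0L)
  r1 <- find_clusters(tab, igr_gap_tolerance = 100)
  expect_equal(nrow(r1$clusters), 1L)
})

test_that("planted deletion structure is recovered end to end", {
  g <- generate_reference(genome_spec(n_genes = 80, n_trna = 0, n_is = 0,
                                      seed = 31))
  feats <- g$features[g$features$type == "gene", ]
  ord <- feats[order(feats$start), ]
  run_at <- function(i, size) list(first = ord$id[i],
                                   last = ord$id[i + size - 1])
  plan <- edit_plan(deletions = c(
    list(run_at(3, 5), run_at(15, 8), run_at(30, 12)),
    lapply(c(50, 55, 60, 65), run_at, size = 1)), seed = 2)
  ed <- apply_edits(g, plan, query_id = "q")
  rs <- simulate_reads(ed$seq, read_sim_spec(depth = 20, sub_error_rate = 0,
                                             seed = 3))
  cov <- call_lcr(coverage_rates(map_reads(rs, g), dissect(g)))
  r <- find_clusters(cov)
  d <- cluster_size_distribution(r)
  expect_equal(d$by_size, setNames(c(1L, 1L, 1L), c("5", "8", "12")))
  expect_equal(d$n_independent, 4L)
})

test_that("size distributions summarize clusters and independents", {
  cl <- data.frame(n_lcr_genes = c(2L, 2L, 5L))
  d <- cluster_size_distribution(cl, independents = c("a", "b"))
  expect_equal(d$by_size, setNames(c(2L, 1L), c("2", "5")))
  expect_equal(d$n_independent, 2L)
  d0 <- cluster_size_distribution(empty <- data.frame(n_lcr_genes = integer(0)))
  expect_equal(length(d0$by_size), 0L)
})
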