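test_that("local alignment handles the degenerate and perfect cases", {
  h <- sw_align("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(h$score, 20L)
  expect_equal(h$identity, 1)
  expect_equal(c(h$a_start, h$a_end), c(1L, 10L))

  h0 <- sw_align("AAAA", "CCCC")
  expect_equal(h0$score, 0L)
  expect_equal(h0$align_len, 0L)

  # N never matches, even against N
  expect_equal(sw_align("NNNN", "NNNN")$score, 0L)
  expect_error(sw_align("", "ACGT"), "empty")
})

test_that("alignment scores are symmetric and respect the scoring scheme", {
  set.seed(2)
  for (k in 1:25) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    expect_equal(sw_align(a, b)$score, sw_align(b, a)$score)
  }
  # one mismatch inside a run: extend (2*9-3=15) vs split (best run 10)
  a <- "ACGTACGTTACGT"
  b <- sub("TT", "TG", a)
  h <- sw_align(a, b)
  expect_equal(h$score, max(2 * 13 - 5, 2 * 8))
})

test_that("sw_align equals the plain-DP and Biostrings oracles on 12-mers", {
  set.seed(4)
  for (k in 1:100) {
    a <- random_dna(sample(4:12, 1))
    b <- random_dna(sample(4:12, 1))
    got <- sw_align(a, b)$score
    expect_equal(got, sw_score_oracle(a, b))
    if (got > 0) expect_equal(got, biostrings_local_score(a, b))
  }
})

test_that("sw_align equals the exhaustive substring-pair oracle on short pairs", {
  set.seed(9)
  for (k in 1:12) {
    a <- random_dna(sample(4:8, 1))
    b <- random_dna(sample(4:8, 1))
    expect_equal(sw_align(a, b)$score, sw_exhaustive_oracle(a, b))
  }
})

# --- detectors on a constructed genome ------------------------------------

flanked_fixture <- function(seed = 51) {
  g <- generate_reference(genome_spec(n_genes = 60, n_trna = 3, n_is = 2,
                                      seed = seed))
  feats <- g$features[g$features$type == "gene" &
                        is.na(g$features$is_family), ]
  feats <- feats[order(feats$start), ]
  plan <- edit_plan(deletions = list(
    list(first = feats$id[5], last = feats$id[7],
         flank_style = "trna_repeat"),
    list(first = feats$id[15], last = feats$id[17],
         flank_style = "direct_repeat"),
    list(first = feats$id[25], last = feats$id[27],
         flank_style = "same_is"),
    list(first = feats$id[35], last = feats$id[37],
         flank_style = "none")), seed = seed + 1)
  g2 <- install_flank_elements(g, plan, seed = seed + 2)
  ed <- apply_edits(g2, plan, query_id = "q")
  rs <- simulate_reads(ed$seq, read_sim_spec(depth = 20, sub_error_rate = 0,
                                             seed = seed + 3))
  cov <- call_lcr(coverage_rates(map_reads(rs, g2), dissect(g2)))
  cl <- find_clusters(cov)
  list(genome = g2, clusters = cl$clusters, plan = plan)
}

test_that("planted flank styles are recovered correctly and exclusively", {
  fx <- flanked_fixture()
  expect_equal(nrow(fx$clusters), 4L)
  rep <- classify_flanks(fx$clusters, fx$genome)
  # order clusters by their planted style via the deletion spans
  styles <- vapply(seq_len(nrow(rep)), function(i) {
    iv <- vapply(fx$plan$deletions, function(d) {
      v <- iscgh:::deletion_interval(fx$genome, d)
      abs(v$start - rep$start[i]) < 5
    }, logical(1))
    fx$plan$deletions[[which(iv)]]$flank_style
  }, character(1))
  expect_setequal(styles, c("trna_repeat", "direct_repeat", "same_is", "none"))
  for (i in seq_len(nrow(rep))) {
    want <- c(trna_repeat = styles[i] == "trna_repeat",
              direct_repeat = styles[i] == "direct_repeat",
              same_is = styles[i] == "same_is")
    got <- c(trna_repeat = rep$trna_repeat[i],
             direct_repeat = rep$direct_repeat[i],
             same_is = rep$same_is[i])
    expect_equal(got, want)
  }
  # the direct repeat is reported at full length and identity
  d <- rep[styles == "direct_repeat", ]
  expect_gte(d$repeat_len, 20)
  expect_equal(d$repeat_identity, 1)
})

test_that("a tRNA at only one end does not trigger the tRNA-repeat flag", {
  set.seed(23)
  g <- manual_genome(random_dna(12000), rbind(
    feature_row("t1", 1000, 1076, type = "tRNA"),
    feature_row("g1", 3000, 3900), feature_row("g2", 4000, 4900)))
  cl <- data.frame(cluster_id = "C1", start = 3000, end = 4900,
                   n_lcr_genes = 2L, wraps = FALSE)
  r <- detect_trna_repeats(cl, g, window = 2500)
  expect_false(r$flag)   # tRNA reaches only the left window
  # and absent tRNA annotation can never flag
  g_no <- g; g_no$features <- g_no$features[g_no$features$type != "tRNA", ]
  expect_false(detect_trna_repeats(cl, g_no, window = 2500)$flag)
})

test_that("same-IS detection requires a shared family at both ends", {
  seqs <- strrep("A", 12000)
  feats <- rbind(
    feature_row("g1", 3000, 3900), feature_row("g2", 4000, 4900),
    feature_row("is1", 2000, 2800, type = "mobile_genetic_element",
                is_family = "IS3"),
    feature_row("is2", 5200, 6000, type = "mobile_genetic_element",
                is_family = "IS110"))
  g <- manual_genome(seqs, feats)
  cl <- data.frame(cluster_id = "C1", start = 3000, end = 4900,
                   n_lcr_genes = 2L, wraps = FALSE)
  expect_false(detect_same_is(cl, g, window = 2000)$flag)
  g$features$is_family[g$features$id == "is2"] <- "IS3"
  r <- detect_same_is(cl, g, window = 2000)
  expect_true(r$flag)
  expect_equal(r$family, "IS3")
})

test_that("unrelated random windows rarely show a direct repeat", {
  set.seed(17)
  n_fp <- 0L
  n_cases <- 40
  for (k in seq_len(n_cases)) {
    g <- manual_genome(random_dna(6000),
                       rbind(feature_row("g1", 2000, 2900),
                             feature_row("g2", 3000, 3900)))
    cl <- data.frame(cluster_id = "C1", start = 2000, end = 3900,
                     n_lcr_genes = 2L, wraps = FALSE)
    r <- detect_direct_repeats(cl, g, window = 2000)
    n_fp <- n_fp + r$flag
  }
  expect_lt(n_fp / n_cases, 0.05)
})

test_that("identical windows always show a direct repeat", {
  w <- random_dna(2000)
  g <- manual_genome(paste0(w, random_dna(1900), w),
                     rbind(feature_row("g1", 2000, 2900),
                           feature_row("g2", 3000, 3850)))
  cl <- data.frame(cluster_id = "C1", start = 2000, end = 3900,
                   n_lcr_genes = 2L, wraps = FALSE)
  r <- detect_direct_repeats(cl, g, window = 2000)
  expect_true(r$flag)
  expect_equal(r$identity, 1)
})

test_that("flank tabulation deduplicates identical spans across queries", {
  rep1 <- data.frame(cluster_id = c("C1", "C2", "C3"),
                     start = c(100, 500, 900), end = c(200, 600, 1000),
                     n_lcr_genes = 2L,
                     trna_repeat = c(TRUE, FALSE, FALSE),
                     trna_id = NA_character_,
                     direct_repeat = c(FALSE, TRUE, FALSE),
                     repeat_len = 0L, repeat_identity = NA_real_,
                     same_is = FALSE, is_family = NA_character_)
  rep2 <- rep1[1, ]          # same span found in a second query
  tab <- tabulate_flanks(list(rep1, rep2))
  expect_equal(tab$total, 3L)
  expect_equal(tab$trna_repeats, 1L)
  expect_equal(tab$direct_repeats, 1L)
  expect_equal(tab$same_is, 0L)
  empty <- tabulate_flanks(list())
  expect_equal(empty$total, 0L)
})

test_that("widening the window never turns a true flag false", {
  fx <- flanked_fixture(seed = 71)
  rep_small <- classify_flanks(fx$clusters, fx$genome, window = 1000L)
  rep_big <- classify_flanks(fx$clusters, fx$genome, window = 3000L)
  for (col in c("trna_repeat", "same_is"))
    expect_true(all(rep_big[[col]] >= rep_small[[col]]))
})
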