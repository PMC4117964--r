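test_that("generate_reference builds in-frame genes with the requested layout", {
  g <- generate_reference(genome_spec(n_genes = 2, mean_gene_len = 300,
                                      mean_igr_len = 100, n_trna = 0,
                                      n_is = 0, seed = 1))
  genes <- g$features[g$features$type == "gene", ]
  expect_equal(nrow(genes), 2L)
  expect_true(all((genes$end - genes$start) %% 3 == 0))

  # coding-strand CDSs start ATG, end with a stop, and are internally
  # stop-free in frame
  cds <- as.character(extract_cds(g))
  for (s in cds) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_equal(cods[1], "ATG")
    expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("generation is byte-deterministic under a fixed seed", {
  s <- genome_spec(n_genes = 15, seed = 42)
  g1 <- generate_reference(s)
  g2 <- generate_reference(s)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$features, g2$features)
  g3 <- generate_reference(genome_spec(n_genes = 15, seed = 43))
  expect_false(identical(g1$seq, g3$seq))
})

test_that("invalid genome specs are rejected", {
  expect_error(genome_spec(n_genes = 0), "n_genes")
  expect_error(genome_spec(mean_gene_len = -5), "lengths")
  expect_error(genome_spec(gc_background = 1.5), "fraction")
})

test_that("a 200-gene genome dissects into the constructed segment count", {
  g <- generate_reference(genome_spec(n_genes = 200, seed = 7,
                                      circular = FALSE))
  segs <- dissect(g)
  # alternating layout: leading + trailing IGRs exist on a linear genome
  expect_equal(nrow(segs), 401L)
  expect_equal(sum(segs$kind == "gene"), 200L)
  # circular merges the two boundary IGRs into one wrap-around segment
  gc <- generate_reference(genome_spec(n_genes = 200, seed = 7,
                                       circular = TRUE))
  expect_equal(nrow(dissect(gc)), 400L)
})

test_that("apply_edits conserves length and records truth faithfully", {
  g <- tiny_genome(seed = 5)
  # empty plan: identity
  ed0 <- apply_edits(g, edit_plan(seed = 1), query_id = "q0")
  expect_identical(ed0$seq, g$seq)
  expect_equal(nrow(ed0$manifest$deletions), 0L)
  expect_equal(ed0$manifest$expected_size, nchar(g$seq))

  # single-gene deletion: length arithmetic and full-deletion bookkeeping
  genes <- g$features[g$features$type == "gene", ]
  pick <- genes$id[3]
  glen <- genes$end[3] - genes$start[3]
  ed1 <- apply_edits(g, edit_plan(deletions = list(list(first = pick)),
                                  seed = 1), query_id = "q1")
  expect_equal(nchar(ed1$seq), nchar(g$seq) - glen)
  expect_equal(ed1$manifest$deleted_genes_full, pick)
  expect_equal(nchar(ed1$seq), ed1$manifest$expected_size)
})

test_that("edit plan validation rejects bad edits", {
  g <- tiny_genome(seed = 5)
  genes <- g$features[g$features$type %in% c("gene", "tRNA"), ]
  # overlapping deletions
  p <- edit_plan(deletions = list(
    list(first = genes$id[2], last = genes$id[5]),
    list(first = genes$id[4], last = genes$id[6])), seed = 1)
  expect_error(apply_edits(g, p), "overlapping")
  # insertion inside a gene
  mid_gene <- floor((genes$start[2] + genes$end[2]) / 2)
  p2 <- edit_plan(insertions = list(list(anchor = mid_gene)), seed = 1)
  expect_error(apply_edits(g, p2), "inside a gene")
})

test_that("insertions splice foreign sequence and grow the manifest size", {
  g <- tiny_genome(seed = 9)
  f <- g$features
  gap <- data.frame(s = head(f$end, -1), e = tail(f$start, -1))
  gap <- gap[gap$e - gap$s >= 20, ][1, ]
  anchor <- floor((gap$s + gap$e) / 2)
  ed <- apply_edits(g, edit_plan(insertions = list(
    list(anchor = anchor, n_genes = 3)), seed = 2), query_id = "qi")
  m <- ed$manifest
  expect_equal(nrow(m$insertions), 1L)
  expect_equal(nchar(ed$seq), nchar(g$seq) + m$insertions$length)
  expect_equal(nchar(ed$seq), m$expected_size)
  # the inserted block sits at the recorded query coordinates
  ins_seq <- substr(ed$seq, m$insertions$query_start + 1L,
                    m$insertions$query_end)
  expect_true(grepl(as.character(m$foreign_cds[[1]]), ins_seq, fixed = TRUE))
  # flanks of the anchor are unchanged
  expect_identical(substr(ed$seq, 1, anchor), substr(g$seq, 1, anchor))
})

test_that("simulate_reads honours count arithmetic and exactness at zero error", {
  set.seed(30)
  seq5k <- random_dna(5000, gc = 0.6)
  rs <- simulate_reads(seq5k, read_sim_spec(depth = 1, read_len = 50,
                                            sub_error_rate = 0, seed = 4))
  expect_equal(length(rs$reads), 100L)
  # every error-free read is an exact substring of the genome or its
  # reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq5k)))
  hitseq <- as.character(rs$reads)
  expect_true(all(vapply(hitseq, function(r)
    grepl(r, seq5k, fixed = TRUE) || grepl(r, rc, fixed = TRUE), logical(1))))
  # determinism
  rs2 <- simulate_reads(seq5k, read_sim_spec(depth = 1, read_len = 50,
                                             sub_error_rate = 0, seed = 4))
  expect_identical(as.character(rs$reads), as.character(rs2$reads))
  expect_error(read_sim_spec(depth = 0), "depth")
})

test_that("observed substitution rate matches the specified error rate", {
  g <- tiny_genome(seed = 8)
  spec <- read_sim_spec(depth = 20, read_len = 50, sub_error_rate = 0.01,
                        seed = 6)
  rs <- simulate_reads(g$seq, spec)
  # compare each read to its source window on the correct strand
  src <- substring(g$seq, rs$truth$start + 1L, rs$truth$start + 50L)
  minus <- rs$truth$strand == "-"
  src[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(src[minus])))
  mm <- sum(vapply(seq_along(src), function(i)
    sum(strsplit(src[i], "")[[1]] != strsplit(as.character(rs$reads[[i]]),
                                              "")[[1]]), integer(1)))
  total <- 50 * length(src)
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(mm / total - 0.01), 3 * se)
})

test_that("install_flank_elements plants retrievable elements and keeps ids valid", {
  g <- tiny_genome(n_genes = 20, seed = 12)
  genes <- g$features[g$features$type == "gene" &
                        is.na(g$features$is_family), ]
  plan <- edit_plan(deletions = list(
    list(first = genes$id[3], last = genes$id[4],
         flank_style = "direct_repeat")), seed = 1)
  g2 <- install_flank_elements(g, plan, seed = 2)
  expect_gt(nchar(g2$seq), nchar(g$seq))
  # the deletion still resolves, and a 20 bp repeat brackets its span
  iv <- iscgh:::deletion_interval(g2, plan$deletions[[1]])
  left <- substr(g2$seq, iv$start - 35, iv$start)
  right <- substr(g2$seq, iv$end + 1, iv$end + 36)
  h <- sw_align(left, right)
  expect_gte(h$n_match, 20)   # the 20 bp planted repeat, possibly extended
  expect_gte(h$identity, 0.9)
})

test_that("reference and manifest round-trip through their file formats", {
  g <- tiny_genome(seed = 21)
  fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
  write_reference(g, fa, gf)
  g2 <- read_reference(fa, gf, circular = g$circular)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$features[, c("id", "type", "start", "end", "strand")],
                   g$features[, c("id", "type", "start", "end", "strand")])
  expect_identical(g2$features$is_family, g$features$is_family)

  rs <- simulate_reads(substr(g$seq, 1, 2000),
                       read_sim_spec(depth = 2, seed = 1))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back <- read_fastq(fq)
  expect_equal(length(back), length(rs$reads))
  expect_identical(as.character(back), as.character(rs$reads),
                   ignore_attr = TRUE)

  ed <- apply_edits(g, edit_plan(deletions = list(
    list(first = g$features$id[2])), seed = 1), query_id = "qx")
  tsv <- tempfile(fileext = ".tsv")
  write_manifest(ed$manifest, tsv)
  tab <- read.delim(tsv)
  expect_true("deletion" %in% tab$edit_type)
  expect_equal(sum(tab$edit_type == "deleted_gene_full"),
               length(ed$manifest$deleted_genes_full))
})
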