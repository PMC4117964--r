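test_that("load_alignments builds the union coverage of primary alignments", {
  ref_len <- 500L
  sam0 <- write_test_sam(tempfile(fileext = ".sam"), "chr", ref_len,
                         data.frame(qname = character(0), flag = integer(0),
                                    pos1 = integer(0), cigar = character(0),
                                    seq = character(0)))
  m0 <- load_alignments(sam0, ref_len)
  expect_equal(sum(m0$covered), 0L)

  # one 50 bp read at [100,150): exactly 50 covered bases
  sam1 <- write_test_sam(tempfile(fileext = ".sam"), "chr", ref_len,
                         data.frame(qname = "r1", flag = 0L, pos1 = 101L,
                                    cigar = "50M", seq = strrep("A", 50)))
  m1 <- load_alignments(sam1, ref_len)
  expect_equal(sum(m1$covered), 50L)
  expect_equal(which(m1$covered == 1L), 101:150)

  # overlapping reads [100,150) + [120,170): union of 70 bases
  sam2 <- write_test_sam(tempfile(fileext = ".sam"), "chr", ref_len,
                         data.frame(qname = c("r1", "r2"), flag = c(0L, 0L),
                                    pos1 = c(101L, 121L),
                                    cigar = c("50M", "50M"),
                                    seq = strrep("A", 50)))
  expect_equal(sum(load_alignments(sam2, ref_len)$covered), 70L)
})

test_that("secondary/unmapped records and clipped bases do not cover", {
  ref_len <- 300L
  aln <- data.frame(
    qname = c("sec", "unm", "clip"),
    flag = c(256L, 4L, 0L),                # secondary, unmapped, primary
    pos1 = c(11L, 11L, 101L),
    cigar = c("50M", "*", "10S30M10S"),    # clipped read covers only 30
    seq = strrep("A", 50))
  sam <- write_test_sam(tempfile(fileext = ".sam"), "chr", ref_len, aln)
  m <- load_alignments(sam, ref_len)
  expect_equal(sum(m$covered), 30L)
  expect_equal(which(m$covered == 1L), 101:130)
  expect_error(load_alignments(sam, ref_len + 1L), "length mismatch")
})

test_that("map_reads covers mapped spans and is strand-symmetric", {
  set.seed(1)
  ref <- random_dna(400)
  # forward exact read
  r_fwd <- substr(ref, 101, 150)
  # reverse complement of the first 50 bases
  r_rev <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(substr(ref, 1, 50), "")[[1]]),
                        collapse = ""))
  # read absent from the reference entirely
  r_absent <- strrep("AC", 25)
  m <- map_reads(c(a = r_fwd, b = r_rev, c = r_absent), ref)
  expect_equal(which(m$covered == 1L), c(1:50, 101:150))
  hits <- attr(m, "hits")
  expect_setequal(hits$pos, c(0L, 100L))
  expect_equal(hits$strand[hits$pos == 0L], "-")
})

test_that("mapper hit set equals the naive all-positions oracle", {
  set.seed(7)
  n_cases <- 30
  for (k in seq_len(n_cases)) {
    ref <- random_dna(sample(300:2000, 1))
    cfg <- mapper_config(seed_k = 12L, max_mismatches = sample(0:3, 1))
    reads <- character(6)
    for (i in 1:6) {
      p <- sample(nchar(ref) - 30L, 1)
      r <- substr(ref, p, p + 29L)
      # inject up to 4 mismatches at random positions
      nmm <- sample(0:4, 1)
      if (nmm) {
        pos <- sample(30L, nmm)
        v <- strsplit(r, "")[[1]]
        v[pos] <- vapply(v[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        r <- paste0(v, collapse = "")
      }
      if (runif(1) < 0.5)
        r <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(r, "")[[1]]), collapse = ""))
      reads[i] <- r
    }
    m <- map_reads(reads, ref, cfg)
    hits <- attr(m, "hits")
    for (i in seq_along(reads)) {
      got <- hits[hits$read == i, c("pos", "strand", "mismatches")]
      got <- got[order(got$pos, got$strand), ]
      want <- naive_map_oracle(reads[i], ref, cfg$seed_k, cfg$max_mismatches)
      want <- want[order(want$pos, want$strand), ]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    }
  }
})

test_that("with one allowed mismatch the seed condition is never limiting", {
  # pigeonhole: one mismatch in a 50-mer leaves an exact run >= 25 >= 18,
  # so the mapper must equal the pure mismatch-threshold scan
  set.seed(11)
  for (k in 1:20) {
    ref <- random_dna(800)
    p <- sample(750, 1)
    r <- substr(ref, p, p + 49L)
    v <- strsplit(r, "")[[1]]
    i <- sample(50, 1)
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    r <- paste0(v, collapse = "")
    m <- map_reads(r, ref, mapper_config(seed_k = 18, max_mismatches = 1))
    got <- attr(m, "hits")[, c("pos", "strand", "mismatches")]
    want <- naive_map_oracle(r, ref, 18, 1, require_seed = FALSE)
    got <- got[order(got$pos, got$strand), ]
    want <- want[order(want$pos, want$strand), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("coverage is monotone in reads and in the mismatch budget", {
  set.seed(3)
  ref <- random_dna(1000)
  reads <- vapply(1:20, function(i) {
    p <- sample(950, 1)
    r <- substr(ref, p, p + 49L)
    v <- strsplit(r, "")[[1]]
    pos <- sample(50, 2)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste0(v, collapse = "")
  }, character(1))
  m10 <- map_reads(reads[1:10], ref)
  m20 <- map_reads(reads, ref)
  expect_true(all(m20$covered >= m10$covered))
  h_strict <- attr(map_reads(reads, ref, mapper_config(max_mismatches = 1)),
                   "hits")
  h_loose <- attr(map_reads(reads, ref, mapper_config(max_mismatches = 3)),
                  "hits")
  key <- function(h) paste(h$read, h$pos, h$strand)
  expect_true(all(key(h_strict) %in% key(h_loose)))
})

test_that("the mapper's own SAM reproduces its coverage mask", {
  g <- tiny_genome(seed = 14)
  rs <- simulate_reads(g$seq, read_sim_spec(depth = 3, sub_error_rate = 0.005,
                                            seed = 2))
  sam <- tempfile(fileext = ".sam")
  m1 <- map_reads(rs, g, sam_out = sam)
  m2 <- load_alignments(sam, nchar(g$seq), genome_id = g$genome_id)
  expect_identical(m1$covered, m2$covered)
})

test_that("error-free deep coverage reaches effectively every base", {
  g <- tiny_genome(seed = 4)
  rs <- simulate_reads(g$seq, read_sim_spec(depth = 20, sub_error_rate = 0,
                                            seed = 3))
  m <- map_reads(rs, g)
  expect_gte(mean(m$covered), 1 - exp(-20) - 0.005)
  # read provenance: every error-free read has at least its source hit
  hits <- attr(m, "hits")
  expect_true(all(seq_along(rs$reads) %in% hits$read))
})
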