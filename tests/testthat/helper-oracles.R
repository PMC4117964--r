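# Independent oracles used across the suite. These deliberately share no
# code with the package implementation paths they check.

# --- naive mapping oracle -------------------------------------------------
# All-positions scan implementing the published mapping definition: a read
# maps at p iff mismatches(read, ref[p..p+n)) <= max_mm and the longest
# exact run is >= seed_k. Returns data.frame(pos, strand, mismatches).
naive_map_oracle <- function(read, ref, seed_k, max_mm,
                             require_seed = TRUE) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  n <- nchar(read)
  L <- nchar(ref)
  refv <- strsplit(ref, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else rc(read)
    qv <- strsplit(q, "")[[1]]
    for (p in 0:(L - n)) {
      win <- refv[(p + 1):(p + n)]
      eq <- win == qv & qv %in% c("A", "C", "G", "T")
      mm <- sum(!eq)
      if (mm > max_mm) next
      if (require_seed) {
        runs <- rle(eq)
        longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
        if (longest < seed_k) next
      }
      hits[[length(hits) + 1L]] <- data.frame(
        pos = p, strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(pos = integer(0), strand = character(0),
               mismatches = integer(0))
}

# --- local alignment oracles ----------------------------------------------
# Plain full-matrix local DP, score only, written with explicit loops.
# Gap of length k costs open + k * ext.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            open = -5, ext = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (av[i - 1] == "N" || bv[j - 1] == "N") mismatch
         else if (av[i - 1] == bv[j - 1]) match else mismatch
    E[i, j] <- max(H[i, j - 1] + open + ext, E[i, j - 1] + ext)
    F[i, j] <- max(H[i - 1, j] + open + ext, F[i - 1, j] + ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Literal exhaustive oracle: max over all substring pairs of the *global*
# affine alignment score (no free ends), floored at zero.
sw_exhaustive_oracle <- function(a, b, match = 2, mismatch = -3,
                                 open = -5, ext = -2) {
  global_affine <- function(av, bv) {
    n <- length(av); m <- length(bv)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
    F <- matrix(NEG, n + 1, m + 1)
    M[1, 1] <- 0
    for (j in seq_len(m)) E[1, j + 1] <- open + ext * j
    for (i in seq_len(n)) F[i + 1, 1] <- open + ext * i
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + s
      E[i, j] <- max(M[i, j - 1] + open + ext, E[i, j - 1] + ext)
      F[i, j] <- max(M[i - 1, j] + open + ext, F[i - 1, j] + ext)
    }
    max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv))
      best <- max(best, global_affine(av[i1:i2], bv[j1:j2]))
  best
}

# Biostrings local alignment score under the same scoring convention
# (gap of length k costs gapOpening + k * gapExtension).
biostrings_local_score <- function(a, b, match = 2, mismatch = -3,
                                   open = -5, ext = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = -open, gapExtension = -ext, scoreOnly = TRUE))
}

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}
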