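# Small shared fixtures, all built in code.

tiny_genome <- function(n_genes = 12, seed = 11, ...) {
  generate_reference(genome_spec(n_genes = n_genes, mean_gene_len = 300,
                                 mean_igr_len = 80, n_trna = 2, n_is = 2,
                                 n_highly_expressed = 4, seed = seed, ...))
}

# hand-built annotated genome with explicit feature coordinates
manual_genome <- function(seq, features, circular = FALSE,
                          genome_id = "manual") {
  structure(list(genome_id = genome_id, seq = seq, features = features,
                 circular = circular, codon_model = codon_model(),
                 spec = NULL),
            class = "annotated_genome")
}

feature_row <- function(id, start, end, type = "gene", strand = "+",
                        is_family = NA_character_, he = FALSE) {
  data.frame(id = id, type = type, start = start, end = end,
             strand = strand, is_family = is_family,
             highly_expressed = he, stringsAsFactors = FALSE)
}

# coverage mask with the given 0-based half-open intervals covered
mask_from_intervals <- function(length, intervals = list(),
                                genome_id = "manual") {
  covered <- integer(length)
  for (iv in intervals) covered[(iv[1] + 1):iv[2]] <- 1L
  structure(list(genome_id = genome_id, length = length, covered = covered),
            class = "coverage_mask")
}

# minimal SAM text file; aln = data.frame(qname, flag, pos1, cigar, seq)
write_test_sam <- function(path, ref_name, ref_len, aln) {
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  if (nrow(aln)) {
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                              aln$qname, aln$flag, ref_name, aln$pos1,
                              aln$cigar, aln$seq))
  }
  writeLines(lines, path)
  path
}
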