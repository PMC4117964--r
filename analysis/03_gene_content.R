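#!/usr/bin/env Rscript
# Cross-strain gene content: per-query LCR summary (counts, percentages,
# expected genome sizes), the nonredundant union and its Venn partition,
# and the comparison of expected versus true query genome sizes (true
# sizes from the truth manifests stand in for the wet-lab measurement).

suppressPackageStartupMessages(library(iscgh))

dat <- "results/data"
out <- "results"
genome <- read_reference(file.path(dat, "reference.fasta"),
                         file.path(dat, "reference.gff3"))
queries <- c("casuarina_like", "casuarina_mild", "alnus_like",
             "elaeagnus_like")
segs <- dissect(genome)
total_genes <- sum(genome$features$type %in% c("gene", "tRNA"))
ref_len <- nchar(genome$seq)

callsets <- list(); summaries <- list()
for (q in queries) {
  cov <- read.delim(file.path(out, sprintf("coverage_%s.tsv", q)))
  lcr_genes <- cov$segment_id[cov$lcr_flag & cov$kind == "gene"]
  callsets[[q]] <- lcr_genes
  exp_size <- expected_genome_size(ref_len, cov$length[cov$lcr_flag])
  truth <- read.delim(file.path(dat, sprintf("%s_truth.tsv", q)))
  true_size <- ref_len -
    sum(truth$length[truth$edit_type == "deletion"], na.rm = TRUE) +
    sum(truth$length[truth$edit_type == "insertion"], na.rm = TRUE)
  s <- summarize_query(length(lcr_genes), total_genes, query_id = q,
                       expected_size = exp_size)
  s$true_size <- true_size
  summaries[[q]] <- s
}
summary_tab <- do.call(rbind, summaries)
iscgh:::write_tsv_file(summary_tab, file.path(out, "summary.tsv"))
print(summary_tab, row.names = FALSE)

venn <- nonredundant_partition(callsets)
iscgh:::write_tsv_file(venn, file.path(out, "venn.tsv"))
cat(sprintf("nonredundant LCR genes: %d\n", attr(venn, "union_size")))
print(venn[venn$count > 0, ], row.names = FALSE)

cat("\nexpected vs true genome size (bp):\n")
for (q in queries) {
  s <- summaries[[q]]
  cat(sprintf("%-15s expected %7.0f  true %7.0f  (acquired DNA: %+d)\n",
              q, s$expected_size, s$true_size,
              as.integer(s$true_size - s$expected_size)))
}
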