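#!/usr/bin/env Rscript
# Clustering of absent genes and their flanking mobile elements: maximal
# runs of consecutive LCR segments with >=2 LCR genes are candidate
# genomic islands; each cluster's ends are searched for tRNA direct
# repeats, generic direct repeats (Smith-Waterman) and same-family IS
# pairs. Writes per-query cluster tables and the nonredundant flank-class
# table under results/.

suppressPackageStartupMessages(library(iscgh))

dat <- "results/data"
out <- "results"
genome <- read_reference(file.path(dat, "reference.fasta"),
                         file.path(dat, "reference.gff3"))
queries <- c("casuarina_like", "casuarina_mild", "alnus_like",
             "elaeagnus_like")
segs <- dissect(genome)

reports <- list()
for (q in queries) {
  disk <- read.delim(file.path(out, sprintf("coverage_%s.tsv", q)))
  cov <- segs
  cov$covered_bases <- disk$covered_bases
  cov$coverage_rate <- 100 * disk$covered_bases / disk$length
  cov <- call_lcr(cov)
  cl <- find_clusters(cov)
  fl <- classify_flanks(cl$clusters, genome)
  reports[[q]] <- fl
  iscgh:::write_tsv_file(cl$clusters,
                         file.path(out, sprintf("clusters_%s.tsv", q)))
  d <- cluster_size_distribution(cl)
  sizes <- if (length(d$by_size))
    paste(sprintf("%sx%d genes", d$by_size, as.integer(names(d$by_size))),
          collapse = ", ") else "none"
  cat(sprintf("%-15s clusters: %s; independent LCR genes: %d\n",
              q, sizes, d$n_independent))
}
tab <- tabulate_flanks(reports)
iscgh:::write_tsv_file(tab, file.path(out, "flank_table.tsv"))
cat(sprintf("nonredundant clusters: %d (tRNA repeats %d, direct repeats %d, same-family IS %d)\n",
            tab$total, tab$trna_repeats, tab$direct_repeats, tab$same_is))
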