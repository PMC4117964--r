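#!/usr/bin/env Rscript
# Build the synthetic four-strain study: one annotated high-GC reference
# chromosome and four query genomes emulating the spectrum from a
# conservative narrow-host-range strain (no gene loss) to a heavily
# shuffled broad-host-range strain (30% of genes deleted plus foreign
# insertions). Writes the reference (FASTA + GFF3), per-query reads
# (FASTQ) and truth manifests under results/data/.

suppressPackageStartupMessages(library(iscgh))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- generate_reference(genome_spec(n_genes = 200, seed = seed))
plans <- iscgh:::demo_plans(genome, iscgh:::child_seed(seed, "plans"))
genome <- install_flank_elements(genome, plans,
                                 seed = iscgh:::child_seed(seed, "flanks"))
anchors <- iscgh:::pick_insertion_anchors(genome, plans, 3L,
                                          iscgh:::child_seed(seed, "anchors"))
plans$elaeagnus_like <- edit_plan(
  deletions = plans$elaeagnus_like$deletions,
  insertions = lapply(anchors, function(a) list(anchor = a, n_genes = 5L)),
  seed = plans$elaeagnus_like$seed)

write_reference(genome, file.path(out, "reference.fasta"),
                file.path(out, "reference.gff3"))
cat(sprintf("reference: %s bp, %d features\n",
            format(nchar(genome$seq), big.mark = ","),
            nrow(genome$features)))

for (q in names(plans)) {
  ed <- apply_edits(genome, plans[[q]], query_id = q)
  rs <- simulate_reads(ed$seq, read_sim_spec(
    depth = 20, sub_error_rate = 0.01,
    seed = iscgh:::child_seed(seed, paste0("reads_", q))))
  write_fastq(rs, file.path(out, sprintf("%s.fastq", q)))
  write_manifest(ed$manifest, file.path(out, sprintf("%s_truth.tsv", q)))
  cat(sprintf("%-15s %7d bp query, %6d reads, %3d genes deleted\n",
              q, nchar(ed$seq), length(rs$reads),
              length(ed$manifest$deleted_genes_full)))
}
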