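#' GC content at third codon positions (GC3)
#'
#' Computed strictly on the annotated coding strand. The terminal stop
#' codon is excluded; ambiguous third-position bases are skipped from both
#' numerator and denominator. Atypically low GC3 in a high-GC genome marks
#' a gene as a candidate horizontal acquisition.
#'
#' @param cds coding sequence(s): character vector or
#'   [Biostrings::DNAStringSet]; each length must be divisible by 3.
#' @return percentage(s) in \[0, 100\].
#' @export
gc3 <- function(cds) {
  seqs <- if (inherits(cds, "DNAStringSet")) as.character(cds)
          else toupper(as.character(cds))
  vapply(seqs, function(s) {
    if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (length(cods) && cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
      cods <- cods[-length(cods)]
    thirds <- substr(cods, 3, 3)
    thirds <- thirds[thirds %in% c("A", "C", "G", "T")]
    if (length(thirds) == 0L) return(NA_real_)
    100 * mean(thirds %in% c("G", "C"))
  }, numeric(1), USE.NAMES = !is.null(names(seqs)))
}

split_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

#' Relative-adaptedness codon weights from a reference gene set
#'
#' For each amino acid, `w(codon) = count(codon) / count(most frequent
#' synonymous codon)` over a reference set of (typically highly expressed,
#' e.g. ribosomal-protein) genes. Stop codons are excluded; zero-count
#' codons are floored at 0.01 to keep geometric means finite. When counts
#' tie at the family maximum, the lexicographically first codon is the
#' designated preferred codon (all tied codons keep w = 1).
#'
#' @param reference_set coding sequences of the reference gene set
#'   (character vector or [Biostrings::DNAStringSet]).
#' @return a `codon_weights` object: numeric `w` named by codon, plus a
#'   `table` data frame (`codon`, `aa`, `count`, `w`, `preferred`).
#' @export
codon_weights <- function(reference_set) {
  seqs <- if (inherits(reference_set, "DNAStringSet"))
    as.character(reference_set) else toupper(as.character(reference_set))
  if (length(seqs) == 0L) stop("empty reference set")
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  counts <- setNames(integer(length(sense)), names(sense))
  for (s in seqs) {
    if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
    cods <- split_codons(s)
    cods <- cods[cods %in% names(sense)]
    t <- table(cods)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  w <- numeric(length(sense))
  names(w) <- names(sense)
  preferred <- logical(length(sense))
  for (aa in unique(sense)) {
    i <- which(sense == aa)
    mx <- max(counts[i])
    if (mx == 0L) { w[i] <- 1; preferred[i[order(names(sense)[i])][1]] <- TRUE; next }
    w[i] <- pmax(counts[i] / mx, 0.01)
    tied <- i[counts[i] == mx]
    preferred[tied[order(names(sense)[tied])][1]] <- TRUE
  }
  structure(list(w = w,
                 table = data.frame(codon = names(sense), aa = unname(sense),
                                    count = unname(counts), w = unname(w),
                                    preferred = preferred,
                                    stringsAsFactors = FALSE),
                 n_reference_genes = length(seqs)),
            class = "codon_weights")
}

#' @export
print.codon_weights <- function(x, ...) {
  cat(sprintf("<codon_weights> from %d reference genes; %d codons\n",
              x$n_reference_genes, length(x$w)))
  invisible(x)
}

CAI_EXCLUDED_CODONS <- c("ATG", "TGG", "TAA", "TAG", "TGA")

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative adaptedness over a gene's codons, excluding
#' Met and Trp (single-codon families) and stop codons. Values near 1 mark
#' codon usage matching the (highly expressed) reference set; low values
#' are suggestive of foreign origin.
#'
#' @param cds coding sequence(s).
#' @param weights a [codon_weights()] object.
#' @return CAI value(s) in (0, 1\].
#' @export
cai <- function(cds, weights) {
  stopifnot(inherits(weights, "codon_weights"))
  seqs <- if (inherits(cds, "DNAStringSet")) as.character(cds)
          else toupper(as.character(cds))
  vapply(seqs, function(s) {
    if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
    cods <- split_codons(s)
    cods <- cods[cods %in% names(weights$w) &
                   !cods %in% CAI_EXCLUDED_CODONS]
    if (length(cods) == 0L) stop("no countable codons")
    exp(mean(log(weights$w[cods])))
  }, numeric(1), USE.NAMES = !is.null(names(seqs)))
}

#' Per-gene GC3 and CAI records
#'
#' @param genome an `annotated_genome` (protein-coding genes are used), or
#'   a named [Biostrings::DNAStringSet] of CDSs.
#' @param weights a [codon_weights()]; by default built from the genome's
#'   designated highly expressed genes.
#' @param lcr_nonredundant optional character vector of gene ids in the
#'   nonredundant LCR union, recorded as a logical flag.
#' @return data frame: `gene_id`, `gc3`, `cai`, `lcr_nonredundant`.
#' @export
gene_properties <- function(genome, weights = NULL,
                            lcr_nonredundant = character(0)) {
  cds <- if (inherits(genome, "annotated_genome")) extract_cds(genome)
         else genome
  if (is.null(weights)) {
    if (!inherits(genome, "annotated_genome"))
      stop("weights required when genome is a plain CDS set")
    he <- genome$features$id[genome$features$highly_expressed &
                              genome$features$type == "gene"]
    if (length(he) == 0L) he <- names(cds)
    weights <- codon_weights(extract_cds(genome, he))
  }
  data.frame(gene_id = names(cds),
             gc3 = unname(gc3(cds)),
             cai = unname(cai(cds, weights)),
             lcr_nonredundant = names(cds) %in% lcr_nonredundant,
             stringsAsFactors = FALSE)
}

#' Contrast GC3 and CAI between gene groups
#'
#' Arithmetic group means (and their difference) of GC3 and CAI between
#' the nonredundant-LCR group and all other genes.
#'
#' @param records data frame from [gene_properties()].
#' @param group logical vector or column name defining the first group
#'   (default the `lcr_nonredundant` column).
#' @return data frame with one row per statistic (`gc3`, `cai`):
#'   `mean_group`, `mean_other`, `difference` (group minus other).
#' @export
group_contrast <- function(records, group = "lcr_nonredundant") {
  g <- if (is.character(group)) records[[group]] else group
  g <- as.logical(g)
  if (!any(g) || all(g)) stop("both groups must be non-empty")
  stat <- function(col) {
    c(mean_group = mean(records[[col]][g]),
      mean_other = mean(records[[col]][!g]),
      difference = mean(records[[col]][g]) - mean(records[[col]][!g]))
  }
  out <- rbind(gc3 = stat("gc3"), cai = stat("cai"))
  data.frame(statistic = rownames(out), out, row.names = NULL)
}
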