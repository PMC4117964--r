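#' Codon-usage models for synthetic coding sequences
#'
#' A codon model fixes, for every amino acid, a probability over its
#' synonymous codons. Two knobs control the model: `gc3`, the preference for
#' codons ending in G or C (the dominant axis of codon usage in high-GC
#' actinobacteria such as *Frankia*), and `bias`, an extra multiplicative
#' weight on one designated preferred codon per family (lexicographically
#' first among the most-GC3 codons). Native chromosomal genes use a high-GC3,
#' biased model; horizontally acquired ("foreign") material is emulated by
#' lowering `gc3` and removing the preference, which depresses both GC3 and
#' the codon adaptation index of the resulting genes.
#'
#' @param gc3 target preference for G/C at third codon positions, in (0,1).
#' @param bias non-negative surcharge multiplier `(1 + bias)` applied to the
#'   preferred codon of each synonymous family; 0 removes the preference.
#' @return an object of class `codon_model` with the per-codon sampling
#'   probabilities (sense codons only, standard bacterial code).
#' @export
codon_model <- function(gc3 = 0.80, bias = 2) {
  stop_if_not_fraction(gc3, "gc3")
  stopifnot(is.numeric(bias), bias >= 0)
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  codons <- names(sense)
  third_gc <- substr(codons, 3, 3) %in% c("G", "C")
  w <- ifelse(third_gc, gc3, 1 - gc3)
  prob <- numeric(length(codons))
  preferred <- character(0)
  for (aa in unique(sense)) {
    i <- which(sense == aa)
    fam <- codons[i]
    fw <- w[i]
    # preferred codon: lexicographically first among the max-GC3 codons
    pick <- fam[order(-third_gc[i], fam)][1]
    fw[fam == pick] <- fw[fam == pick] * (1 + bias)
    prob[i] <- fw / sum(fw)
    preferred <- c(preferred, pick)
  }
  structure(list(gc3 = gc3, bias = bias,
                 codons = codons, aa = unname(sense),
                 prob = setNames(prob, codons),
                 preferred = preferred),
            class = "codon_model")
}

#' Derive a shifted ("foreign") codon model
#'
#' @param model a `codon_model`.
#' @param gc3_shift additive change to the GC3 preference (fraction; the
#'   default, -0.15, lowers GC3 by 15 percentage points).
#' @param bias new preference surcharge (default 0: unbiased usage).
#' @export
shift_codon_model <- function(model, gc3_shift = -0.15, bias = 0) {
  stopifnot(inherits(model, "codon_model"))
  codon_model(gc3 = min(max(model$gc3 + gc3_shift, 0.02), 0.98), bias = bias)
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("<codon_model> gc3 preference %.2f, preferred-codon bias %.1f\n",
              x$gc3, x$bias))
  invisible(x)
}

# Sample one CDS: ATG start, body drawn from the model, one stop codon.
# `len` must be a multiple of 3 and >= 9. Internal stops are impossible by
# construction (the model covers sense codons only).
sample_cds <- function(len, model) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_body <- len / 3 - 2
  aas <- sample(unique(model$aa), n_body, replace = TRUE)
  body <- vapply(aas, function(a) {
    i <- which(model$aa == a)
    sample(model$codons[i], 1L, prob = model$prob[i])
  }, character(1))
  stop_codon <- sample(c("TGA", "TAA", "TAG"), 1L, prob = c(0.6, 0.25, 0.15))
  paste0("ATG", paste0(body, collapse = ""), stop_codon)
}

# Random non-coding sequence at a given GC fraction.
sample_noncoding <- function(len, gc) {
  if (len <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}
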