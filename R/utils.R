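#' @importFrom stats rgeom runif setNames
#' @importFrom utils head tail write.table read.delim
NULL

# Run expr with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Derive a child seed from a parent seed and a stream label, staying inside
# the 32-bit integer range.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 1009 + offs) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dna_string <- function(x) {
  if (inherits(x, "DNAString")) return(as.character(x))
  if (inherits(x, "DNAStringSet")) return(as.character(x[[1]]))
  toupper(as.character(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Extract [start, end) (0-based half-open) from a genome sequence string,
# wrapping past the origin when circular and end > length.
extract_span <- function(seq, start, end, circular = FALSE) {
  L <- nchar(seq)
  stopifnot(start >= 0, end > start)
  if (end <= L) return(substr(seq, start + 1L, end))
  if (!circular) stop("span exceeds a linear genome")
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
}

stop_if_not_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a fraction in [0, 1]", name))
}
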