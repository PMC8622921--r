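# Internal helpers shared across modules.

# Split a DNA string into consecutive codons.  `n` is truncated to a multiple
# of 3; callers that require exact framing validate beforehand.
split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Standard genetic code keyed by codon, taken from Biostrings.  Codons with
# any non-ACGT letter translate to 'X'.
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("AACGT")
revcomp_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA string: uppercase A/C/G/T/N only.
check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains letters outside A/C/G/T/N: %s", what,
                 paste(unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), ""))),
                       collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  Used by the simulator and bootstrap for reproducibility
# without clobbering the session stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Small deterministic content fingerprint (32-bit polynomial hash) for run
# reports; avoids a dependency for a non-cryptographic checksum.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
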