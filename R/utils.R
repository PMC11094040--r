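# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, N allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalize to the single internal alphabet: uppercase DNA, U -> T
normalize_dna <- function(x) toupper(chartr("Uu", "Tt", x))

check_dna_alphabet <- function(x, what = "sequence", ids = NULL) {
  bad <- which(!grepl("^[ACGT]+$", x))
  if (length(bad)) {
    id <- if (is.null(ids)) bad[1] else ids[bad[1]]
    stop(sprintf("invalid %s (record %s): only A/C/G/T allowed and must be non-empty",
                 what, id), call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic integer offsets for staged RNG, kept below 2^31
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
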