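# 1U/10A nucleotide-bias classification: uridine at position 1 and adenine
# at position 10 (1-based on the mature piRNA, U stored as T) are the
# hallmarks of Siwi-bound and BmAgo3-bound piRNAs; position 10 is the
# nucleotide 5' of the ping-pong cleavage site between nucleotides 10 and
# 11 of the guiding piRNA.

BIAS_CLASSES <- c("U1A10", "U1_only", "A10_only", "neither")

#' Classify sequences by 1U/10A bias
#'
#' @param sequence character vector of piRNA sequences (DNA alphabet,
#'   length >= 10).
#' @return factor with levels U1A10, U1_only, A10_only, neither.
#' @export
classify_bias <- function(sequence) {
  if (any(nchar(sequence) < 10L)) {
    stop("bias classification needs sequences of length >= 10", call. = FALSE)
  }
  u1 <- substr(sequence, 1L, 1L) == "T"
  a10 <- substr(sequence, 10L, 10L) == "A"
  cls <- fifelse(u1 & a10, "U1A10",
                 fifelse(u1, "U1_only", fifelse(a10, "A10_only", "neither")))
  factor(cls, levels = BIAS_CLASSES)
}

#' Per-group 1U/10A bias fractions
#'
#' For each expression group, the counts and relative fractions of the four
#' bias classes; fractions sum to 1 within every non-empty group, and empty
#' groups are absent from the output.
#'
#' @param groups data.table(key, group); keys must be disjoint across
#'   groups.
#' @param sequences named character vector of piRNA sequences, indexed by
#'   key.
#' @return data.table(group, bias_class, count, fraction).
#' @export
bias_fraction_table <- function(groups, sequences) {
  groups <- as.data.table(groups)
  if (anyDuplicated(groups$key)) {
    stop("groups must be disjoint: duplicated key ",
         groups$key[duplicated(groups$key)][1], call. = FALSE)
  }
  miss <- setdiff(groups$key, names(sequences))
  if (length(miss)) stop("no sequence for key ", miss[1], call. = FALSE)
  tab <- copy(groups)[, bias_class := classify_bias(sequences[key])]
  grid <- CJ(group = unique(groups$group), bias_class = factor(BIAS_CLASSES,
                                                               levels = BIAS_CLASSES))
  cnt <- tab[, .(count = .N), by = .(group, bias_class)]
  out <- cnt[grid, on = c("group", "bias_class")]
  out[is.na(count), count := 0L]
  out[, fraction := count / sum(count), by = group]
  setorder(out, group, bias_class)
  out[]
}
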