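# Read cleanup emulating the library protocol in reverse: the sequenced
# insert is  4-nt UMI + small RNA + 4-nt UMI + 3'-adapter,  so preprocessing
# is 3'-adapter removal, exact-duplicate collapsing (PCR dedup; UMIs still
# attached, so distinct molecules survive), UMI stripping from both ends and
# a strict > 12 nt length gate.  Discards are data, not errors: every stage
# returns them with a reason tag so the pipeline can account for them.

#' Preprocessing configuration
#'
#' @param adapter3_core common part of the 3' adapter, downstream of the
#'   randomized 4 nt (default TGGAATTCTCGGGTGCCAAGG).
#' @param umi_len_5p,umi_len_3p randomized-end lengths to strip (4 and 4).
#' @param min_len_after minimum kept core length; the default 13 encodes the
#'   strict "longer than 12 nt" rule.
#' @param adapter_min_overlap minimum adapter prefix length that may hang off
#'   the 3' end of the read and still count as an adapter occurrence.
#' @param adapter_max_error_rate mismatch budget per matched window,
#'   `floor(overlap * rate)` mismatches allowed (ungapped).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(adapter3_core = "TGGAATTCTCGGGTGCCAAGG",
                              umi_len_5p = 4L, umi_len_3p = 4L,
                              min_len_after = 13L,
                              adapter_min_overlap = 6L,
                              adapter_max_error_rate = 0.1) {
  adapter3_core <- normalize_dna(adapter3_core)
  check_dna_alphabet(adapter3_core, "adapter")
  stopifnot(umi_len_5p >= 0L, umi_len_3p >= 0L, min_len_after >= 1L,
            adapter_min_overlap >= 1L,
            adapter_max_error_rate >= 0, adapter_max_error_rate < 0.5)
  structure(list(adapter3_core = adapter3_core,
                 umi_len_5p = as.integer(umi_len_5p),
                 umi_len_3p = as.integer(umi_len_3p),
                 min_len_after = as.integer(min_len_after),
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_error_rate = adapter_max_error_rate),
            class = "preprocess_config")
}

as_read_table <- function(reads) {
  if (is.character(reads)) {
    reads <- data.table(read_id = paste0("read", seq_along(reads)),
                        sequence = reads, quality = NA_character_, count = 1L)
  }
  reads <- as.data.table(reads)
  if (is.null(reads$quality)) reads[, quality := NA_character_]
  if (is.null(reads$count)) reads[, count := 1L]
  reads
}

#' Remove the 3' adapter
#'
#' Finds the leftmost adapter occurrence: either the full adapter core
#' anywhere in the read, or an adapter prefix of at least
#' `adapter_min_overlap` nt ending exactly at the read's 3' end; in both
#' cases `floor(matched_length * adapter_max_error_rate)` mismatches are
#' tolerated (no indels).  The read is cut immediately before the
#' occurrence.  Reads with no detected adapter are discarded with reason
#' `"no_adapter"` -- by library design a genuine insert always carries the
#' adapter, so adapterless reads are dimers or junk.  Empty inserts (adapter
#' at position 1) are kept here and fall to the downstream length gate.
#'
#' @param reads data.table(read_id, sequence, quality, count) or a character
#'   vector of sequences.
#' @param config a [preprocess_config()].
#' @return list(kept, discarded); `discarded` carries a `reason` column.
#' @export
trim_adapter3 <- function(reads, config = preprocess_config()) {
  reads <- as_read_table(reads)
  ad <- config$adapter3_core
  alen <- nchar(ad)
  er <- config$adapter_max_error_rate
  n <- nrow(reads)
  if (n == 0L) return(list(kept = reads, discarded = cbind(reads, reason = character(0))))
  seqs <- reads$sequence
  len <- nchar(seqs)
  pos <- rep(NA_integer_, n)

  # full-adapter occurrences anywhere in the read (leftmost wins)
  mm_full <- floor(alen * er)
  m <- Biostrings::vmatchPattern(ad, Biostrings::DNAStringSet(seqs),
                                 max.mismatch = mm_full, fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  has_full <- lengths(starts) > 0L
  pos[has_full] <- vapply(starts[has_full], min, integer(1))

  # partial adapter prefix flush with the 3' end; longest overlap = leftmost cut
  ad_int <- utf8ToInt(ad)
  o_hi <- min(alen - 1L, max(len))
  if (o_hi >= config$adapter_min_overlap) {
    for (o in seq(o_hi, config$adapter_min_overlap)) {
      idx <- which(is.na(pos) & len >= o)
      if (!length(idx)) next
      suf <- substring(seqs[idx], len[idx] - o + 1L, len[idx])
      ints <- matrix(utf8ToInt(paste(suf, collapse = "")), nrow = o)
      mm <- colSums(ints != ad_int[seq_len(o)])
      hit <- mm <= floor(o * er)
      pos[idx[hit]] <- len[idx][hit] - o + 1L
    }
  }

  found <- !is.na(pos)
  kept <- reads[found]
  cut_at <- pos[found]
  kept[, sequence := substr(sequence, 1L, cut_at - 1L)]
  kept[, quality := fifelse(is.na(quality), quality,
                            substr(quality, 1L, cut_at - 1L))]
  discarded <- reads[!found][, reason := "no_adapter"]
  list(kept = kept[], discarded = discarded[])
}

#' Collapse exact duplicate reads
#'
#' One record per distinct full sequence (UMIs still attached), count reset
#' to 1: this removes PCR duplicates, it does not accumulate abundance.
#' Output is ordered lexicographically by sequence; the representative
#' read_id is the first occurrence in input order.  Idempotent.
#'
#' @param reads read table (post adapter trimming).
#' @return data.table(read_id, sequence, quality, count = 1).
#' @export
collapse_exact_duplicates <- function(reads) {
  reads <- as_read_table(reads)
  out <- reads[, .(read_id = read_id[1L]), by = sequence]
  out[, `:=`(quality = NA_character_, count = 1L)]
  setorder(out, sequence)
  setcolorder(out, c("read_id", "sequence", "quality", "count"))
  out[]
}

#' Strip the randomized 4-nt ends (UMIs)
#'
#' Returns the core `read[umi5+1 : len-umi3]` with the UMI pair recorded for
#' audit.  Reads too short to contain both UMIs plus one core nucleotide are
#' discarded with reason `"too_short_for_umi"`; cores shorter than
#' `min_len_after` (i.e. not longer than 12 nt under the defaults) with
#' reason `"below_min_length"`.
#'
#' @inheritParams trim_adapter3
#' @return list(kept, discarded); kept has columns read_id, sequence (core),
#'   umi5, umi3, count.
#' @export
strip_umis <- function(reads, config = preprocess_config()) {
  reads <- as_read_table(reads)
  u5 <- config$umi_len_5p
  u3 <- config$umi_len_3p
  len <- nchar(reads$sequence)
  too_short <- len < u5 + u3 + 1L
  disc1 <- reads[too_short][, reason := "too_short_for_umi"]
  rest <- reads[!too_short]
  rlen <- len[!too_short]
  umi5 <- substr(rest$sequence, 1L, u5)
  umi3 <- substr(rest$sequence, rlen - u3 + 1L, rlen)
  core <- substr(rest$sequence, u5 + 1L, rlen - u3)
  rest[, `:=`(umi5 = umi5, umi3 = umi3, sequence = core)]
  short_core <- nchar(rest$sequence) < config$min_len_after
  disc2 <- rest[short_core][, reason := "below_min_length"]
  kept <- rest[!short_core, .(read_id, sequence, umi5, umi3, count)]
  list(kept = kept[], discarded = rbind(disc1, disc2, fill = TRUE)[])
}

#' Keep reads in the piRNA length window
#'
#' Inclusive bounds on both ends; the defaults extract 23-32 nt reads.
#'
#' @param reads read table of UMI-stripped cores.
#' @param lo,hi inclusive length bounds.
#' @return list(kept, discarded_by_length) where the latter tabulates
#'   dropped read counts per length.
#' @export
length_gate_pirna <- function(reads, lo = 23L, hi = 32L) {
  if (lo > hi) stop("length gate misconfigured: lo > hi", call. = FALSE)
  reads <- as.data.table(reads)
  len <- nchar(reads$sequence)
  keep <- len >= lo & len <= hi
  dropped <- reads[!keep]
  tab <- dropped[, .(count = sum(count)), by = .(length = nchar(sequence))]
  setorder(tab, length)
  list(kept = reads[keep], discarded_by_length = tab[])
}

#' Full preprocessing pipeline
#'
#' trim -> collapse -> strip, in the protocol's order, then aggregation of
#' identical cores: after UMI removal, records sharing a core came from
#' distinct molecules, so the aggregated count is a molecule count.
#'
#' @inheritParams trim_adapter3
#' @return list(cores = data.table(sequence, count), report = list of stage
#'   tallies).
#' @export
preprocess_reads <- function(reads, config = preprocess_config()) {
  reads <- as_read_table(reads)
  tr <- trim_adapter3(reads, config)
  co <- collapse_exact_duplicates(tr$kept)
  st <- strip_umis(co, config)
  cores <- st$kept[, .(count = sum(count)), by = sequence]
  setorder(cores, sequence)
  report <- list(
    n_input = nrow(reads),
    n_no_adapter = nrow(tr$discarded),
    n_molecules = nrow(co),
    n_too_short_for_umi = sum(st$discarded$reason == "too_short_for_umi"),
    n_below_min_length = sum(st$discarded$reason == "below_min_length"),
    n_core_species = nrow(cores),
    n_core_molecules = sum(cores$count))
  list(cores = cores[], report = report)
}
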