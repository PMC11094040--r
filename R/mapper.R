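# Self-contained ungapped mapper with bowtie -v style semantics: end-to-end
# alignment, Hamming distance 0 or 1, both strands, best-stratum reporting
# (exact hits suppress one-mismatch hits) and a fully deterministic
# tie-break.  The index is a per-query-length hash join: every panel
# substring of the query length, on both strands, keyed by sequence; a
# one-mismatch lookup joins the query's full substitution neighborhood.
# Panels here are transposon consensus sets of a few tens of kilobases, so
# the index is small and the search exact by construction.

#' Mapper configuration
#'
#' @param max_mismatches 0 or 1 (default 1, the "single-nucleotide mismatch"
#'   policy).
#' @param report_policy `"best_single"` keeps exactly one hit per read via the
#'   deterministic tie-break (fewest mismatches, then te_id lexicographic,
#'   then lowest start, then plus before minus); `"all_best"` keeps every
#'   best-stratum hit (multiple mapping).
#' @param strict_five_prime_anchor when TRUE, a one-mismatch hit whose
#'   mismatch falls on the read's 5' nucleotide is not accepted as a 5'-end
#'   match in [match_five_prime()]; the default allows the mismatch budget
#'   anywhere.
#' @return an object of class `mapper_config`.
#' @export
mapper_config <- function(max_mismatches = 1L,
                          report_policy = c("best_single", "all_best"),
                          strict_five_prime_anchor = FALSE) {
  max_mismatches <- as.integer(max_mismatches)
  if (!max_mismatches %in% c(0L, 1L)) stop("max_mismatches must be 0 or 1",
                                           call. = FALSE)
  structure(list(max_mismatches = max_mismatches,
                 report_policy = match.arg(report_policy),
                 strict_five_prime_anchor = isTRUE(strict_five_prime_anchor)),
            class = "mapper_config")
}

#' Build a search index over a transposon panel
#'
#' @param panel panel table from [read_te_panel()] (te_id must be unique).
#' @return an object of class `te_index`; per-length substring tables are
#'   built lazily and cached.
#' @export
build_te_index <- function(panel) {
  panel <- as.data.table(panel)
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  if (anyDuplicated(panel$te_id)) {
    stop("duplicate te_id: ", panel$te_id[duplicated(panel$te_id)][1],
         call. = FALSE)
  }
  check_dna_alphabet(panel$sequence, "TE sequence", panel$te_id)
  idx <- new.env(parent = emptyenv())
  idx$panel <- copy(panel)
  idx$seq_plus <- setNames(panel$sequence, panel$te_id)
  idx$seq_minus <- setNames(revcomp(panel$sequence), panel$te_id)
  idx$te_len <- setNames(nchar(panel$sequence), panel$te_id)
  idx$cache <- new.env(parent = emptyenv())
  class(idx) <- "te_index"
  idx
}

# all panel substrings of length L on both strands, keyed by sequence;
# start0 is the 0-based TE coordinate of the window's leftmost base
length_table <- function(index, L) {
  key <- as.character(L)
  hit <- index$cache[[key]]
  if (!is.null(hit)) return(hit)
  pieces <- vector("list", 2L * length(index$te_len))
  k <- 0L
  for (te in names(index$te_len)) {
    n <- index$te_len[[te]]
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    k <- k + 1L
    pieces[[k]] <- data.table(
      seq = substring(index$seq_plus[[te]], starts, starts + L - 1L),
      te_id = te, strand = "+", start0 = starts - 1L)
    k <- k + 1L
    pieces[[k]] <- data.table(
      seq = substring(index$seq_minus[[te]], starts, starts + L - 1L),
      te_id = te, strand = "-", start0 = n - (starts - 1L) - L)
  }
  tab <- rbindlist(pieces[seq_len(k)])
  if (nrow(tab)) setkey(tab, seq)
  index$cache[[key]] <- tab
  tab
}

# all sequences at Hamming distance exactly 1 from each query (same length)
mismatch_neighborhood <- function(qs, L) {
  out <- vector("list", 4L * L)
  k <- 0L
  for (p in seq_len(L)) {
    orig <- substr(qs, p, p)
    pre <- substr(qs, 1L, p - 1L)
    suf <- substr(qs, p + 1L, L)
    for (b in DNA_BASES) {
      keep <- orig != b
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.table(variant = paste0(pre[keep], b, suf[keep]),
                             origin = qs[keep])
    }
  }
  rbindlist(out[seq_len(k)])
}

# core search over unique sequences; returns best-stratum hits with columns
# (sequence, te_id, strand, start0, end0, mismatches, five_prime_pos)
map_sequences <- function(seqs, index, config = mapper_config()) {
  seqs <- unique(seqs)
  res <- list()
  for (L in sort(unique(nchar(seqs)))) {
    qs <- seqs[nchar(seqs) == L]
    tab <- length_table(index, L)
    if (nrow(tab) == 0L) next
    ex <- tab[J(qs), nomatch = 0L]
    ex[, mismatches := 0L]
    res[[length(res) + 1L]] <- ex
    if (config$max_mismatches >= 1L) {
      rest <- setdiff(qs, unique(ex$seq))
      if (length(rest)) {
        nb <- mismatch_neighborhood(rest, L)
        one <- tab[nb, on = .(seq = variant), nomatch = 0L,
                   allow.cartesian = TRUE]
        if (nrow(one)) {
          one[, `:=`(seq = origin, origin = NULL, mismatches = 1L)]
          res[[length(res) + 1L]] <- one
        }
      }
    }
  }
  if (!length(res)) {
    return(data.table(sequence = character(), te_id = character(),
                      strand = character(), start0 = integer(),
                      end0 = integer(), mismatches = integer(),
                      five_prime_pos = integer()))
  }
  hits <- rbindlist(res, use.names = TRUE)
  setnames(hits, "seq", "sequence")
  hits[, end0 := start0 + nchar(sequence)]
  hits[, five_prime_pos := five_prime_from_hit(start0, end0, strand)]
  setorder(hits, sequence, mismatches, te_id, start0, strand)
  hits[]
}

#' Map reads against the panel
#'
#' End-to-end ungapped alignment on both strands with at most
#' `max_mismatches` substitutions; only the best stratum is reported (a read
#' with any exact placement reports no one-mismatch placements).  Under
#' `best_single` exactly one hit per read survives the deterministic
#' tie-break, so repeated runs are byte-identical.
#'
#' @param reads character vector of sequences, or a table with a `sequence`
#'   column (and optionally `read_id`).
#' @param index a [build_te_index()] object.
#' @param config a [mapper_config()].
#' @return data.table(read_id, sequence, te_id, strand, start0, end0,
#'   mismatches, five_prime_pos); reads without a hit are absent.
#' @export
map_reads <- function(reads, index, config = mapper_config()) {
  if (is.character(reads)) {
    reads <- data.table(read_id = paste0("read", seq_along(reads)),
                        sequence = reads)
  }
  reads <- as.data.table(reads)
  if (is.null(reads$read_id)) reads[, read_id := paste0("read", .I)]
  hits <- map_sequences(reads$sequence, index, config)
  if (config$report_policy == "best_single" && nrow(hits)) {
    hits <- hits[hits[, .I[1L], by = sequence]$V1]
  }
  out <- hits[reads[, .(read_id, sequence)], on = "sequence",
              nomatch = 0L, allow.cartesian = TRUE]
  setcolorder(out, c("read_id", "sequence", "te_id", "strand", "start0",
                     "end0", "mismatches", "five_prime_pos"))
  setorder(out, read_id, mismatches, te_id, start0, strand)
  out[]
}

#' @rdname map_reads
#' @param core a single read sequence.
#' @export
map_read <- function(core, index, config = mapper_config()) {
  stopifnot(length(core) == 1L)
  map_reads(core, index, config)
}

# drop 1-mismatch hits whose mismatch sits on the read's 5' nucleotide
strict_anchor_filter <- function(hits, index) {
  if (!nrow(hits)) return(hits)
  te_base <- function(te, pos) substr(index$seq_plus[te], pos, pos)
  read5 <- substr(hits$sequence, 1L, 1L)
  panel5 <- te_base(hits$te_id, hits$five_prime_pos)
  ok <- hits$mismatches == 0L |
    ifelse(hits$strand == "+", read5 == panel5,
           read5 == chartr("ACGT", "TGCA", panel5))
  hits[ok]
}

#' Match a read to reference piRNA 5' anchors
#'
#' A read is a 5'-end match to a reference piRNA when any of its
#' best-stratum hits places its 5' nucleotide on the reference's
#' (te_id, strand, five_prime_pos) anchor; read and reference lengths need
#' not agree.
#'
#' @param core a single read sequence.
#' @param index a [build_te_index()] object.
#' @param refs reference annotation table.
#' @param config a [mapper_config()] (5'-anchor matching always considers
#'   every best-stratum hit).
#' @return character vector of matching pirna_ids (sorted, possibly empty).
#' @export
match_five_prime <- function(core, index, refs, config = mapper_config()) {
  stopifnot(length(core) == 1L)
  hits <- map_sequences(core, index, config)
  if (config$strict_five_prime_anchor) hits <- strict_anchor_filter(hits, index)
  m <- merge(hits, as.data.table(refs),
             by = c("te_id", "strand", "five_prime_pos"))
  sort(unique(m$pirna_id))
}

#' Per-reference-piRNA counts with fractional multi-anchor assignment
#'
#' Each core contributes its molecule count split evenly (1/k) across the k
#' reference anchors it matches, conserving total counts.
#'
#' @param cores data.table(sequence, count) of UMI-stripped cores (already
#'   length-gated to the piRNA window by the caller).
#' @param index a [build_te_index()] object.
#' @param refs reference annotation table.
#' @param config a [mapper_config()].
#' @param hits optional precomputed best-stratum hits from `map_sequences`-
#'   compatible output (columns sequence, te_id, strand, five_prime_pos,
#'   mismatches), to avoid re-mapping.
#' @return named numeric vector of counts over all `refs$pirna_id` (zeros
#'   for unmatched references).
#' @export
count_reference_pirnas <- function(cores, index, refs,
                                   config = mapper_config(), hits = NULL) {
  cores <- as.data.table(cores)
  if (is.null(hits)) hits <- map_sequences(cores$sequence, index, config)
  if (config$strict_five_prime_anchor) hits <- strict_anchor_filter(hits, index)
  counts <- setNames(numeric(nrow(refs)), refs$pirna_id)
  if (!nrow(hits) || !nrow(cores)) return(counts)
  m <- merge(hits, as.data.table(refs)[, .(te_id, strand, five_prime_pos, pirna_id)],
             by = c("te_id", "strand", "five_prime_pos"))
  m <- unique(m[, .(sequence, pirna_id)])
  if (!nrow(m)) return(counts)
  m[, k := .N, by = sequence]
  m <- m[cores, on = "sequence", nomatch = 0L]
  agg <- m[, .(count = sum(count / k)), by = pirna_id]
  counts[agg$pirna_id] <- agg$count
  counts
}

#' Tally read 5' ends by genomic anchor
#'
#' Aggregates molecule counts of all reads in the piRNA length window over
#' (te_id, strand, five_prime_pos), pooling read lengths; a read with h
#' best-stratum hits contributes 1/h to each.  This is the per-position 5'
#' end table that partner lookup draws from -- partners need not be
#' annotated reference piRNAs.
#'
#' @inheritParams count_reference_pirnas
#' @param lo,hi inclusive read-length window (23-32 nt).
#' @return data.table(te_id, strand, five_prime_pos, count).
#' @export
five_prime_site_tally <- function(cores, index, config = mapper_config(),
                                  lo = 23L, hi = 32L, hits = NULL) {
  cores <- as.data.table(cores)
  len <- nchar(cores$sequence)
  cores <- cores[len >= lo & len <= hi]
  if (is.null(hits)) {
    hits <- map_sequences(cores$sequence, index, config)
  } else {
    hits <- hits[sequence %in% cores$sequence]
  }
  if (!nrow(hits) || !nrow(cores)) {
    return(data.table(te_id = character(), strand = character(),
                      five_prime_pos = integer(), count = numeric()))
  }
  hits <- copy(hits)[, h := .N, by = sequence]
  m <- hits[cores, on = "sequence", nomatch = 0L, allow.cartesian = TRUE]
  tal <- m[, .(count = sum(count / h)), by = .(te_id, strand, five_prime_pos)]
  setorder(tal, te_id, strand, five_prime_pos)
  tal[]
}

#' Normalization denominator: reads with at least one best-stratum hit
#'
#' In synthetic mode the panel plus its decoy sequence stands in for the
#' genome, so "genome-mapped" means mapped anywhere on the index.
#'
#' @inheritParams count_reference_pirnas
#' @return total molecule count of mapped cores (numeric scalar).
#' @export
genome_mapped_denominator <- function(cores, index, config = mapper_config(),
                                      hits = NULL) {
  cores <- as.data.table(cores)
  if (is.null(hits)) hits <- map_sequences(cores$sequence, index, config)
  mapped <- unique(hits$sequence)
  sum(cores[sequence %in% mapped, count])
}

#' Normalize a count library to reads-per-million
#'
#' @param counts named non-negative counts (per pirna_id or te_id).
#' @param denominator library-size total; `genome_mapped` uses reads mapped
#'   to the genome stand-in, `reference_matched` the total count over the
#'   reference piRNA set (the IP-library convention).
#' @param denominator_mode provenance tag, `"genome_mapped"` or
#'   `"reference_matched"`.
#' @param library_id free-text library label.
#' @param role one of control, kd, siwi_ip, ago3_ip.
#' @return object of class `library_counts` with elements library_id, role,
#'   counts, denominator, denominator_mode, rpm.
#' @export
normalize_library <- function(counts, denominator,
                              denominator_mode = c("genome_mapped",
                                                   "reference_matched"),
                              library_id = "library",
                              role = c("control", "kd", "siwi_ip", "ago3_ip")) {
  denominator_mode <- match.arg(denominator_mode)
  role <- match.arg(role)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (!is.finite(denominator) || denominator <= 0) {
    stop("empty library: normalization denominator must be > 0", call. = FALSE)
  }
  structure(list(library_id = library_id, role = role, counts = counts,
                 denominator = denominator, denominator_mode = denominator_mode,
                 rpm = counts / denominator * 1e6),
            class = "library_counts")
}

#' @export
print.library_counts <- function(x, ...) {
  cat(sprintf("<library_counts> %s (%s): %d keys, denominator %.0f (%s)\n",
              x$library_id, x$role, length(x$counts), x$denominator,
              x$denominator_mode))
  invisible(x)
}
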