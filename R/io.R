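# Readers and writers for the package's external formats: FASTA transposon
# panels, FASTQ small-RNA libraries, the TSV reference-piRNA annotation,
# BED6 alignment dumps and generic TSV/JSON result tables.
#
# Coordinate conventions: alignment hits are 0-based half-open (BED);
# reference piRNA 5' positions are 1-based on the transposon.  The only
# places the two meet are `five_prime_from_hit()` in the mapper and the
# BED writer below.

#' Read a transposon panel from FASTA
#'
#' Sequences are uppercased and U is normalized to T so that a single DNA
#' alphabet is used throughout.  Any character outside A/C/G/T (including N)
#' is a parse error, as is an empty file or a duplicated identifier.
#'
#' @param path FASTA file (plain or gzip).
#' @param rrna_te_ids identifiers of rRNA-containing transposons whose
#'   piRNAs must be excluded from ping-pong classification.
#' @param decoy_te_ids identifiers of non-transposon decoy sequences that
#'   participate in mapping (normalization denominator) but not in TE-level
#'   expression tables.
#' @return data.table with columns te_id, sequence, is_rrna_te, is_decoy.
#' @export
read_te_panel <- function(path, rrna_te_ids = character(), decoy_te_ids = character()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  te_id <- sub("\\s.*$", "", names(set))
  sequence <- normalize_dna(as.character(set))
  check_dna_alphabet(sequence, "FASTA sequence", te_id)
  if (anyDuplicated(te_id)) {
    stop("duplicate te_id in panel: ", te_id[duplicated(te_id)][1], call. = FALSE)
  }
  data.table(te_id = te_id, sequence = unname(sequence),
             is_rrna_te = te_id %in% rrna_te_ids,
             is_decoy = te_id %in% decoy_te_ids)
}

#' Write a transposon panel to FASTA
#'
#' @param panel data.table as returned by [read_te_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_te_panel <- function(panel, path) {
  set <- Biostrings::BStringSet(panel$sequence)
  names(set) <- panel$te_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read the reference piRNA annotation
#'
#' The annotation is a TSV with columns pirna_id, te_id, strand,
#' five_prime_pos (1-based transposon coordinate of the piRNA 5' nucleotide)
#' and sequence.  When `panel` is supplied, each sequence is checked against
#' the transposon: a plus-strand piRNA must equal the TE subsequence starting
#' at its 5' position, a minus-strand piRNA the reverse complement ending
#' there.
#'
#' @param path TSV file.
#' @param panel optional panel for sequence/coordinate validation.
#' @return data.table(pirna_id, te_id, strand, five_prime_pos, sequence).
#' @export
read_reference_pirnas <- function(path, panel = NULL) {
  refs <- fread(path, sep = "\t", colClasses = list(character = "pirna_id"))
  need <- c("pirna_id", "te_id", "strand", "five_prime_pos", "sequence")
  miss <- setdiff(need, names(refs))
  if (length(miss)) stop("reference annotation missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  refs <- refs[, need, with = FALSE]
  refs[, sequence := normalize_dna(sequence)]
  refs[, five_prime_pos := as.integer(five_prime_pos)]
  validate_reference_pirnas(refs, panel)
  refs[]
}

#' @rdname read_reference_pirnas
#' @param refs annotation table to validate.
#' @export
validate_reference_pirnas <- function(refs, panel = NULL) {
  if (anyDuplicated(refs$pirna_id)) {
    stop("duplicate pirna_id: ", refs$pirna_id[duplicated(refs$pirna_id)][1],
         call. = FALSE)
  }
  if (!all(refs$strand %in% c("+", "-"))) {
    stop("reference strand must be '+' or '-'", call. = FALSE)
  }
  check_dna_alphabet(refs$sequence, "reference piRNA sequence", refs$pirna_id)
  len <- nchar(refs$sequence)
  bad <- which(len < 23L | len > 32L)
  if (length(bad)) {
    stop("reference piRNA length outside 23-32 nt: ", refs$pirna_id[bad[1]],
         " (", len[bad[1]], " nt)", call. = FALSE)
  }
  if (!is.null(panel)) {
    te_seq <- setNames(panel$sequence, panel$te_id)
    unknown <- setdiff(refs$te_id, names(te_seq))
    if (length(unknown)) stop("reference piRNA on unknown TE: ", unknown[1],
                              call. = FALSE)
    p <- refs$five_prime_pos
    expect <- ifelse(refs$strand == "+",
                     substr(te_seq[refs$te_id], p, p + len - 1L),
                     revcomp(substr(te_seq[refs$te_id], p - len + 1L, p)))
    bad <- which(expect != refs$sequence)
    if (length(bad)) {
      stop("reference piRNA sequence does not match its TE coordinates: ",
           refs$pirna_id[bad[1]], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a reference piRNA annotation
#'
#' @inheritParams validate_reference_pirnas
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_reference_pirnas <- function(refs, path) {
  fwrite(refs, path, sep = "\t")
  invisible(path)
}

#' Read a small RNA FASTQ library
#'
#' Order-preserving; each record starts with count 1 (counts only become
#' molecule counts after duplicate collapsing).  Truncated records and
#' quality strings whose length differs from the read are errors.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data.table(read_id, sequence, quality, count).
#' @export
read_small_rna_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  # structural validation on the raw lines: the parser pads or silently
  # drops malformed trailing records, so neither truncated blocks nor
  # sequence/quality length disagreements may reach it
  con <- gzfile(path, "r")
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ '%s': incomplete 4-line block at record %d",
                 path, length(lines) %/% 4L + 1L), call. = FALSE)
  }
  seq_len_raw <- nchar(lines[seq(2L, length(lines), by = 4L)])
  qual_len_raw <- nchar(lines[seq(4L, length(lines), by = 4L)])
  bad <- which(seq_len_raw != qual_len_raw)
  if (length(bad)) {
    stop(sprintf("FASTQ record %d ('%s'): quality length %d != sequence length %d",
                 bad[1], sub("^@", "", lines[4L * (bad[1] - 1L) + 1L]),
                 qual_len_raw[bad[1]], seq_len_raw[bad[1]]), call. = FALSE)
  }
  rm(lines)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  qual <- as.character(S4Vectors::mcols(set)$qualities)
  seqs <- as.character(set)
  data.table(read_id = sub("\\s.*$", "", names(set)),
             sequence = unname(seqs), quality = unname(qual), count = 1L)
}

#' Write a small RNA FASTQ library
#'
#' @param reads data.table with read_id, sequence and optionally quality
#'   (missing qualities are written as constant 'I').
#' @param path output file; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_small_rna_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  fill <- is.na(qual)
  if (any(fill)) qual[fill] <- strrep("I", nchar(reads$sequence[fill]))
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write and read result tables (TSV or JSON)
#'
#' Column order is preserved and values round-trip losslessly; an empty
#' table writes a header-only TSV.
#'
#' @param x data.frame-like table.
#' @param path output file.
#' @param format "tsv" or "json".
#' @return `path`, invisibly (writer); a data.table (reader).
#' @export
write_result_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    fwrite(as.data.table(x), path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(x), path, dataframe = "columns",
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    fread(path, sep = "\t", na.strings = "NA")
  } else {
    as.data.table(jsonlite::fromJSON(path))
  }
}

#' Export and import alignment hits as BED6
#'
#' BED columns are (te_id, start, end, read_id, mismatches, strand) with
#' 0-based half-open coordinates; re-importing recomputes the 1-based
#' five_prime_pos from start/end/strand.
#'
#' @param hits alignment table from [map_reads()].
#' @param path output file.
#' @return `path`, invisibly (writer); a hits data.table (reader).
#' @export
write_bed6 <- function(hits, path) {
  bed <- data.table(chrom = hits$te_id, start = hits$start0, end = hits$end0,
                    name = hits$read_id %||% hits$sequence,
                    score = hits$mismatches, strand = hits$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  bed <- fread(path, sep = "\t", header = FALSE,
               col.names = c("te_id", "start0", "end0", "read_id",
                             "mismatches", "strand"))
  bed[, five_prime_pos := five_prime_from_hit(start0, end0, strand)]
  setcolorder(bed, c("read_id", "te_id", "strand", "start0", "end0",
                     "mismatches", "five_prime_pos"))
  bed[]
}

#' Convert between hit coordinates and 5' anchors
#'
#' For a plus-strand hit the 5' nucleotide sits at start+1 (1-based); for a
#' minus-strand hit it sits at the 1-based position equal to the exclusive
#' BED end.
#'
#' @param start0,end0 0-based half-open hit coordinates.
#' @param strand "+" or "-".
#' @return integer vector of 1-based 5' positions.
#' @export
five_prime_from_hit <- function(start0, end0, strand) {
  as.integer(ifelse(strand == "+", start0 + 1L, end0))
}
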