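# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain character/integer arithmetic only.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1))
}

# exhaustive Hamming scan of one read over all placements on both strands,
# returning only the best stratum
oracle_map <- function(read, panel, max_mm = 1) {
  r <- utf8ToInt(read)
  rc <- utf8ToInt(oracle_revcomp(read))
  L <- length(r)
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    tv <- utf8ToInt(panel$sequence[i])
    n <- length(tv)
    if (n < L) next
    for (start in 0:(n - L)) {
      win <- tv[(start + 1):(start + L)]
      mm_p <- sum(win != r)
      if (mm_p <= max_mm) {
        rows[[length(rows) + 1]] <- data.frame(
          te_id = panel$te_id[i], strand = "+", start0 = start,
          mismatches = mm_p)
      }
      mm_m <- sum(win != rc)
      if (mm_m <= max_mm) {
        rows[[length(rows) + 1]] <- data.frame(
          te_id = panel$te_id[i], strand = "-", start0 = start,
          mismatches = mm_m)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(te_id = character(), strand = character(),
                      start0 = integer(), mismatches = integer()))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits[order(hits$te_id, hits$start0, hits$strand), , drop = FALSE]
}

# leftmost adapter cut position under the trimming policy: full adapter
# anywhere, or an adapter prefix of >= min_overlap nt flush with the 3'
# end, with floor(overlap * error_rate) mismatches
oracle_trim_pos <- function(seq, adapter, min_overlap = 6, error_rate = 0.1) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  s <- utf8ToInt(seq)
  a <- utf8ToInt(adapter)
  for (cut in seq_len(n)) {
    o <- min(alen, n - cut + 1L)
    if (o < alen && o < min_overlap) next
    mm <- sum(s[cut:(cut + o - 1L)] != a[seq_len(o)])
    if (mm <= floor(o * error_rate)) return(cut)
  }
  NA_integer_
}

mutate_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  seq
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
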