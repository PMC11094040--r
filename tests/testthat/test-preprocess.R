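ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming cuts at the leftmost occurrence", {
  cfg <- preprocess_config()
  set.seed(1)
  insert <- random_seq(25)

  # exact adapter at the junction -> the insert
  out <- trim_adapter3(paste0(insert, ADAPTER), cfg)
  expect_equal(out$kept$sequence, insert)
  expect_equal(nrow(out$discarded), 0L)

  # adapter at position 1 -> empty insert kept (length gate handles it)
  out <- trim_adapter3(ADAPTER, cfg)
  expect_equal(out$kept$sequence, "")

  # one mismatch in the 21-nt adapter is within floor(21 * 0.1) = 2
  out <- trim_adapter3(paste0(insert, mutate_base(ADAPTER, 7L)), cfg)
  expect_equal(out$kept$sequence, insert)

  # no adapter anywhere -> discarded as data, not an error
  out <- trim_adapter3("ACACACACACACACACACACACACAC", cfg)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(out$discarded$reason, "no_adapter")

  # partial adapter prefix flush with the 3' end
  out <- trim_adapter3(paste0(insert, substr(ADAPTER, 1, 9)), cfg)
  expect_equal(out$kept$sequence, insert)

  # overlap below the 6-nt minimum is not an occurrence
  out <- trim_adapter3(paste0(insert, substr(ADAPTER, 1, 4)), cfg)
  expect_equal(nrow(out$kept), 0L)
})

test_that("adapter trimming agrees with the brute-force sliding-window oracle", {
  cfg <- preprocess_config()
  set.seed(7)
  cases <- character(0)
  for (i in 1:150) {
    insert <- random_seq(sample(0:35, 1))
    kind <- sample(c("exact", "mut1", "mut2", "partial", "none"), 1)
    read <- switch(kind,
      exact = paste0(insert, ADAPTER),
      mut1 = paste0(insert, mutate_base(ADAPTER, sample(21, 1))),
      mut2 = paste0(insert, mutate_base(mutate_base(ADAPTER, 3), 15)),
      partial = paste0(insert, substr(ADAPTER, 1, sample(3:20, 1))),
      none = random_seq(sample(15:60, 1)))
    cases <- c(cases, read)
  }
  got <- trim_adapter3(cases, cfg)
  expected_pos <- vapply(cases, oracle_trim_pos, integer(1),
                         adapter = ADAPTER, min_overlap = 6,
                         error_rate = 0.1, USE.NAMES = FALSE)
  expect_equal(sort(got$discarded$sequence), sort(cases[is.na(expected_pos)]))
  exp_kept <- substr(cases[!is.na(expected_pos)], 1,
                     expected_pos[!is.na(expected_pos)] - 1)
  expect_equal(sort(got$kept$sequence), sort(exp_kept))
})

test_that("duplicate collapsing keeps one record per distinct sequence", {
  x <- "ACGTACGTACGTACGTACGTACG"
  y <- "TTTTACGTACGTACGTACGTACG"
  out <- collapse_exact_duplicates(c(x, x, y))
  expect_equal(out$sequence, sort(c(x, y)))
  expect_equal(out$count, c(1L, 1L))

  # all-distinct input passes through (as a set)
  set.seed(3)
  distinct <- vapply(1:10, function(i) random_seq(30), character(1))
  out <- collapse_exact_duplicates(distinct)
  expect_setequal(out$sequence, distinct)

  # idempotence
  expect_equal(collapse_exact_duplicates(out), out)

  # same insert, different UMIs = different molecules, both kept
  insert <- random_seq(24)
  mols <- paste0(c("AAAA", "CCCC"), insert, c("GGGG", "TTTT"))
  expect_equal(nrow(collapse_exact_duplicates(c(mols, mols))), 2L)
})

test_that("UMI stripping applies the strict > 12 nt core gate", {
  cfg <- preprocess_config()
  set.seed(5)

  r31 <- random_seq(31)
  out <- strip_umis(r31, cfg)
  expect_equal(nchar(out$kept$sequence), 23L)
  expect_equal(out$kept$sequence, substr(r31, 5, 27))
  expect_equal(out$kept$umi5, substr(r31, 1, 4))
  expect_equal(out$kept$umi3, substr(r31, 28, 31))

  # 20-nt read -> 12-nt core -> discarded ("longer than 12 nt" is strict)
  out <- strip_umis(random_seq(20), cfg)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(out$discarded$reason, "below_min_length")

  # 21-nt read -> 13-nt core, the boundary case, kept
  out <- strip_umis(random_seq(21), cfg)
  expect_equal(nchar(out$kept$sequence), 13L)

  # too short to even contain the UMIs
  out <- strip_umis(random_seq(7), cfg)
  expect_equal(out$discarded$reason, "too_short_for_umi")

  # kept cores always lose exactly 8 nt
  lens <- 21:40
  out <- strip_umis(vapply(lens, random_seq, character(1)), cfg)
  expect_equal(nchar(out$kept$sequence), lens - 8L)
})

test_that("piRNA length gate is inclusive on both ends", {
  reads <- vapply(c(22, 23, 32, 33), random_seq, character(1))
  out <- length_gate_pirna(data.table::data.table(sequence = reads, count = 1L))
  expect_equal(nchar(out$kept$sequence), c(23L, 32L))
  expect_equal(out$discarded_by_length$length, c(22L, 33L))

  expect_equal(nrow(length_gate_pirna(
    data.table::data.table(sequence = character(), count = integer()))$kept), 0L)

  only25 <- length_gate_pirna(
    data.table::data.table(sequence = reads, count = 1L), lo = 25, hi = 25)
  expect_equal(nrow(only25$kept), 0L)
  expect_error(length_gate_pirna(
    data.table::data.table(sequence = reads, count = 1L), lo = 30, hi = 20),
    "lo > hi")
})

test_that("preprocessing is deterministic and inverts the read layout", {
  set.seed(11)
  inserts <- vapply(1:40, function(i) random_seq(sample(23:32, 1)),
                    character(1))
  reads <- paste0(vapply(seq_along(inserts), function(i) random_seq(4),
                         character(1)),
                  inserts,
                  vapply(seq_along(inserts), function(i) random_seq(4),
                         character(1)),
                  ADAPTER)
  # duplicate some reads (PCR copies collapse back to one molecule)
  reads <- c(reads, reads[1:10])
  out1 <- preprocess_reads(reads)
  out2 <- preprocess_reads(reads)
  expect_identical(out1, out2)
  got <- rep(out1$cores$sequence, out1$cores$count)
  expect_equal(sort(got), sort(inserts))
  expect_equal(out1$report$n_molecules, 40L)
})
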