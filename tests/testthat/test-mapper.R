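test_that("exact and one-mismatch placements are found, two are not", {
  fx <- tiny_fixture()
  index <- build_te_index(fx$panel)
  te1 <- fx$panel$sequence[1]
  core <- substr(te1, 11, 34)  # TE[10..34) in 0-based terms

  hit <- map_read(core, index)
  expect_equal(hit[, .(te_id, strand, start0, end0, mismatches)],
               data.table::data.table(te_id = "te1", strand = "+",
                                      start0 = 10L, end0 = 34L,
                                      mismatches = 0L))
  expect_equal(hit$five_prime_pos, 11L)

  mut1 <- mutate_base(core, 12L)
  hit <- map_read(mut1, index)
  expect_equal(hit$mismatches, 1L)
  expect_equal(hit$start0, 10L)

  mut2 <- mutate_base(mut1, 20L)
  expect_equal(nrow(map_read(mut2, index)), 0L)
  expect_equal(nrow(oracle_map(mut2, fx$panel)), 0L)
})

test_that("reverse-complement queries flip strand and keep coordinates", {
  fx <- tiny_fixture()
  index <- build_te_index(fx$panel)
  core <- substr(fx$panel$sequence[2], 40, 66)
  fwd <- map_read(core, index)
  rev <- map_read(oracle_revcomp(core), index)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev[, .(te_id, start0, end0)], fwd[, .(te_id, start0, end0)])
  expect_equal(rev$five_prime_pos, fwd$end0)
})

test_that("mapper equals the exhaustive Hamming scan on random panels", {
  set.seed(19)
  for (trial in 1:10) {
    n_te <- sample(1:3, 1)
    panel <- data.table::data.table(
      te_id = paste0("t", seq_len(n_te)),
      sequence = vapply(seq_len(n_te), function(i) random_seq(sample(150:400, 1)),
                        character(1)),
      is_rrna_te = FALSE, is_decoy = FALSE)
    index <- build_te_index(panel)
    for (r in 1:6) {
      L <- sample(23:32, 1)
      read <- switch(sample(3, 1),
        random_seq(L),
        { te <- sample(n_te, 1)
          s <- sample(nchar(panel$sequence[te]) - L, 1)
          win <- substr(panel$sequence[te], s + 1, s + L)
          if (runif(1) < 0.5) win <- oracle_revcomp(win)
          if (runif(1) < 0.6) win <- mutate_base(win, sample(L, 1))
          win },
        mutate_base(random_seq(L), 1))
      for (mm in 0:1) {
        got <- map_reads(read, index, mapper_config(mm, "all_best"))
        exp <- oracle_map(read, panel, mm)
        expect_equal(nrow(got), nrow(exp))
        if (nrow(exp)) {
          expect_equal(got[order(te_id, start0, strand),
                           .(te_id, strand, start0, mismatches)],
                       data.table::as.data.table(exp)[, .(te_id, strand,
                                                          start0, mismatches)])
        }
      }
    }
  }
})

test_that("best_single is deterministic and byte-stable through BED", {
  fx <- tiny_fixture()
  index <- build_te_index(fx$panel)
  set.seed(23)
  reads <- c(vapply(1:20, function(i) random_seq(25), character(1)),
             substr(fx$panel$sequence[1], 21, 46))
  h1 <- map_reads(reads, index, mapper_config(1, "best_single"))
  h2 <- map_reads(reads, index, mapper_config(1, "best_single"))
  expect_identical(h1, h2)
  expect_lte(max(table(h1$read_id)), 1L)
  b1 <- withr::local_tempfile(fileext = ".bed")
  b2 <- withr::local_tempfile(fileext = ".bed")
  write_bed6(h1, b1)
  write_bed6(h2, b2)
  expect_identical(readLines(b1), readLines(b2))

  # rebuilding the index gives identical query results
  h3 <- map_reads(reads, build_te_index(fx$panel), mapper_config(1, "best_single"))
  expect_identical(h1, h3)
})

test_that("5'-anchor matching follows the anchor, not the read length", {
  fx <- tiny_fixture()
  index <- build_te_index(fx$panel)
  te1 <- fx$panel$sequence[1]

  # 26-nt read starting at the 5' position of the 28-nt plus reference
  core26 <- substr(te1, 101, 126)
  expect_equal(match_five_prime(core26, index, fx$refs), "pa")
  # and on the minus reference (5' anchor at 110, any length)
  core24 <- oracle_revcomp(substr(te1, 110 - 23, 110))
  expect_equal(match_five_prime(core24, index, fx$refs), "pb")

  # one nucleotide downstream of every anchor -> no match
  off1 <- substr(te1, 102, 127)
  expect_equal(match_five_prime(off1, index, fx$refs), character(0))

  # a read matching anchors on two TEs is returned for both, and counted
  # fractionally
  shared <- substr(te1, 101, 126)
  panel2 <- data.table::copy(fx$panel)
  panel2[2, sequence := paste0(substr(sequence, 1, 60), shared,
                               substr(sequence, 87, 250))]
  refs2 <- rbind(fx$refs, data.table::data.table(
    pirna_id = "pc", te_id = "te2", strand = "+", five_prime_pos = 61L,
    sequence = substr(panel2$sequence[2], 61, 61 + 27)))
  idx2 <- build_te_index(panel2)
  expect_equal(match_five_prime(shared, idx2, refs2), c("pa", "pc"))
  counts <- count_reference_pirnas(
    data.table::data.table(sequence = shared, count = 4), idx2, refs2)
  expect_equal(unname(counts[c("pa", "pc")]), c(2, 2))
  expect_equal(sum(counts), 4)
})

test_that("strict 5'-anchor switch rejects a mismatch on the anchor base", {
  fx <- tiny_fixture()
  index <- build_te_index(fx$panel)
  core <- mutate_base(substr(fx$panel$sequence[1], 101, 126), 1L)
  expect_equal(match_five_prime(core, index, fx$refs), "pa")
  strict <- mapper_config(strict_five_prime_anchor = TRUE)
  expect_equal(match_five_prime(core, index, fx$refs, strict), character(0))
  # a mismatch elsewhere is still accepted under the strict switch
  core_mid <- mutate_base(substr(fx$panel$sequence[1], 101, 126), 13L)
  expect_equal(match_five_prime(core_mid, index, fx$refs, strict), "pa")
})

test_that("RPM normalization conserves scale", {
  lib <- normalize_library(c(a = 2, b = 8), 10, "genome_mapped")
  expect_equal(unname(lib$rpm), c(2e5, 8e5))

  ref <- normalize_library(c(a = 2, b = 8), 10, "reference_matched")
  expect_equal(sum(ref$rpm), 1e6)

  doubled <- normalize_library(c(a = 4, b = 16), 20, "genome_mapped")
  expect_equal(doubled$rpm, lib$rpm)

  expect_error(normalize_library(c(a = 1), 0, "genome_mapped"), "empty library")
  expect_error(normalize_library(c(a = -1), 10, "genome_mapped"), "negative")
})

test_that("5'-end tallies pool read lengths at one anchor", {
  fx <- tiny_fixture()
  index <- build_te_index(fx$panel)
  te1 <- fx$panel$sequence[1]
  cores <- data.table::data.table(
    sequence = c(substr(te1, 101, 125), substr(te1, 101, 128),
                 substr(te1, 131, 155)),
    count = c(3, 2, 5))
  tal <- five_prime_site_tally(cores, index)
  expect_equal(tal[five_prime_pos == 101, count], 5)
  expect_equal(tal[five_prime_pos == 131, count], 5)
})
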