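make_ip_libs <- function(siwi_counts, ago3_counts) {
  list(siwi = normalize_library(siwi_counts, sum(siwi_counts),
                                "reference_matched", "siwi", "siwi_ip"),
       ago3 = normalize_library(ago3_counts, sum(ago3_counts),
                                "reference_matched", "ago3", "ago3_ip"))
}

test_that("PIWI assignment uses strict RPM dominance with a raw-count floor", {
  refs <- data.table::data.table(pirna_id = c("p1", "p2", "p3", "p4"))
  # equal library totals so raw-count ties are RPM ties
  libs <- make_ip_libs(
    siwi_counts = c(p1 = 40, p2 = 1, p3 = 20, p4 = 5),
    ago3_counts = c(p1 = 5, p2 = 0, p3 = 20, p4 = 41))
  asg <- assign_piwi(libs$siwi, libs$ago3, refs)
  expect_equal(asg$call, c("S", "undetermined", "undetermined", "A"))
  # p2: "no more than 1 read in the IP libraries" -> undetermined
  # p3: equal raw counts and equal totals -> tied RPM -> undetermined

  # the floor applies jointly: 2 reads in one library is enough
  libs2 <- make_ip_libs(c(p1 = 2, p2 = 1, p3 = 1, p4 = 1),
                        c(p1 = 0, p2 = 1, p3 = 1, p4 = 1))
  expect_equal(assign_piwi(libs2$siwi, libs2$ago3, refs)$call[1], "S")

  # IP libraries must use the reference-matched denominator
  wrong <- normalize_library(c(p1 = 1), 10, "genome_mapped")
  expect_error(assign_piwi(wrong, libs$ago3, refs), "reference_matched")
})

test_that("partner coordinates realize the 5' 10-nt overlap geometry", {
  panel <- data.table::data.table(te_id = "te1", sequence = strrep("A", 200),
                                  is_rrna_te = FALSE, is_decoy = FALSE)
  refs <- data.table::data.table(
    pirna_id = c("plus101", "minus110", "plus3", "minus5"),
    te_id = "te1", strand = c("+", "-", "+", "-"),
    five_prime_pos = c(101L, 110L, 3L, 5L))
  pc <- partner_coordinate(refs, panel)
  expect_equal(pc$partner_strand, c("-", "+", "-", "+"))
  expect_equal(pc$partner_five_prime_pos, c(110L, 101L, 12L, -4L))
  expect_equal(pc$in_bounds, c(TRUE, TRUE, TRUE, FALSE))

  # partner-of-partner symmetry over random in-bounds anchors
  set.seed(12)
  rnd <- data.table::data.table(
    pirna_id = sprintf("r%02d", 1:30), te_id = "te1",
    strand = sample(c("+", "-"), 30, TRUE),
    five_prime_pos = sample(30:170, 30))
  fwd <- partner_coordinate(rnd, panel)
  back <- partner_coordinate(
    data.table::data.table(pirna_id = fwd$pirna_id, te_id = fwd$te_id,
                           strand = fwd$partner_strand,
                           five_prime_pos = fwd$partner_five_prime_pos),
    panel)
  expect_equal(back$partner_strand, rnd$strand)
  expect_equal(back$partner_five_prime_pos, rnd$five_prime_pos)
})

test_that("partner abundance aggregates lengths at the site and calls the PIWI", {
  coords <- data.table::data.table(
    pirna_id = c("x", "y", "z"), te_id = "te1",
    partner_strand = c("-", "-", "+"),
    partner_five_prime_pos = c(110L, 60L, 90L),
    in_bounds = TRUE)
  # tallies as produced by five_prime_site_tally: lengths already pooled
  siwi <- data.table::data.table(te_id = "te1", strand = "-",
                                 five_prime_pos = 110L, count = 0)
  ago3 <- data.table::data.table(te_id = "te1", strand = "-",
                                 five_prime_pos = 110L, count = 30)
  ps <- partner_abundance(coords, siwi, ago3, 1000, 1000)
  expect_equal(ps[pirna_id == "x", partner_call], "A")
  # no reads at the site in either IP -> undetermined
  expect_equal(ps[pirna_id == "y", partner_call], "undetermined")
  expect_equal(ps[pirna_id == "z", partner_call], "undetermined")
})

test_that("classification partitions the reference set with exclusions", {
  panel <- data.table::data.table(
    te_id = c("te1", "rrna_te"),
    sequence = c(strrep("A", 300), strrep("C", 300)),
    is_rrna_te = c(FALSE, TRUE), is_decoy = FALSE)
  refs <- data.table::data.table(
    pirna_id = sprintf("p%d", 1:6), te_id = c(rep("te1", 5), "rrna_te"),
    strand = "+", five_prime_pos = seq(10L, 260L, by = 50L))
  assignments <- data.table::data.table(
    pirna_id = refs$pirna_id,
    siwi_raw = c(30, 5, 30, 1, 30, 30), ago3_raw = c(5, 30, 5, 0, 5, 5),
    siwi_rpm = c(30, 5, 30, 1, 30, 30), ago3_rpm = c(5, 30, 5, 0, 5, 5))
  assignments[, call := c("S", "A", "S", "undetermined", "S", "S")]
  # partner calls chosen to realize each category
  partner_sites <- data.table::data.table(
    pirna_id = refs$pirna_id,
    partner_five_prime_pos = refs$five_prime_pos + 9L,
    partner_call = c("A", "S", "S", "S", "undetermined", "A"))
  # p2 own A + partner A would be ambiguous; set it so:
  partner_sites[2, partner_call := "A"]
  rec <- classify_pingpong(assignments, partner_sites, refs, panel)
  expect_equal(rec[match(refs$pirna_id, pirna_id), klass],
               c("A_to_S", "excl_ambiguous", "S_to_S", "excl_undetermined",
                 "excl_undetermined", "excl_rrna"))
  summ <- pingpong_summary(rec)
  expect_true(summ$partition_ok)
  expect_equal(summ$n, 6L)
  expect_equal(sum(unlist(summ$category_counts)), 6L)

  # the switch reports A/A as its own class instead of excluding it
  rec2 <- classify_pingpong(assignments, partner_sites, refs, panel,
                            report_a_to_a = TRUE)
  expect_equal(rec2[pirna_id == "p2", klass], "A_to_A")

  # rRNA precedence beats undetermined calls
  assignments2 <- data.table::copy(assignments)[6, call := "undetermined"]
  rec3 <- classify_pingpong(assignments2, partner_sites, refs, panel)
  expect_equal(rec3[pirna_id == "p6", klass], "excl_rrna")

  # a reference piRNA missing from the assignments is an error
  expect_error(classify_pingpong(assignments[-1], partner_sites, refs, panel),
               "missing")
})

test_that("swapping the IP libraries mirrors the heterotypic classes", {
  run <- cached_noiseless_run()
  norm <- run$results$libraries
  refs <- run$sim$refs
  panel <- run$sim$panel
  asg <- assign_piwi(norm$ago3_ip, norm$siwi_ip, refs)   # swapped
  coords <- partner_coordinate(refs, panel)
  # swapped tallies: reuse the pipeline's per-IP site tallies via partner
  # sites recomputed with the libraries exchanged
  ps <- run$results$partner_sites
  ps_swapped <- data.table::copy(ps)
  data.table::setnames(ps_swapped,
                       c("siwi_raw", "ago3_raw", "siwi_rpm", "ago3_rpm"),
                       c("ago3_raw", "siwi_raw", "ago3_rpm", "siwi_rpm"))
  ps_swapped[, partner_call := data.table::fcase(
    pmax(siwi_raw, ago3_raw) <= 1, "undetermined",
    siwi_rpm > ago3_rpm, "S",
    ago3_rpm > siwi_rpm, "A",
    default = "undetermined")]
  # report A/A as its own class so former S/S pairs stay visible
  rec_swapped <- classify_pingpong(asg, ps_swapped, refs, panel,
                                   report_a_to_a = TRUE)
  rec <- run$results$records
  m <- merge(rec[, .(pirna_id, klass)],
             rec_swapped[, .(pirna_id, klass_sw = klass)], by = "pirna_id")
  expect_equal(m[klass == "A_to_S", unique(klass_sw)], "S_to_A")
  expect_equal(m[klass == "S_to_A", unique(klass_sw)], "A_to_S")
  # Siwi/Siwi pairs become BmAgo3/BmAgo3 configurations under the swap
  expect_equal(m[klass == "S_to_S", unique(klass_sw)], "A_to_A")
})

test_that("class expression change is zero when nothing changes", {
  run <- cached_noiseless_run()
  rec <- run$results$records
  expr0 <- data.frame(
    key = rec$pirna_id, ctrl_rpm = 10, kd_rpm = 10,
    m_value = 0, a_value = log2(11))
  ch <- class_expression_change(rec, expr0)
  expect_equal(ch$median_m, rep(0, nrow(ch)))
  expect_setequal(ch$klass, c("A_to_S", "S_to_A", "S_to_S"))
})
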