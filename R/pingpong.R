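# The core classification: each annotated reference piRNA is assigned the
# PIWI protein it is predominantly bound to (Siwi vs BmAgo3, from the two
# IP libraries), its ping-pong partner site is located via the 5' 10-nt
# overlap geometry, the partner's PIWI is called from the same IP
# libraries, and the piRNA is labelled partner->own: A_to_S, S_to_A or
# S_to_S.  piRNAs from the rRNA-containing transposon, piRNAs whose own or
# partner call cannot be determined, and BmAgo3/BmAgo3 configurations
# (abundant on both strands, hence ambiguous) are excluded; the output is
# always a partition of the reference set.

PP_CLASSES <- c("A_to_S", "S_to_A", "S_to_S")
PP_CATEGORIES <- c(PP_CLASSES, "A_to_A", "excl_rrna", "excl_undetermined",
                   "excl_ambiguous")

# shared Siwi/BmAgo3 call: strictly more abundant in RPM wins; ties and
# sites with no more than `thr` raw reads in both IP libraries are
# undetermined
piwi_call <- function(siwi_raw, ago3_raw, siwi_rpm, ago3_rpm, thr) {
  fcase(pmax(siwi_raw, ago3_raw) <= thr, "undetermined",
        siwi_rpm > ago3_rpm, "S",
        ago3_rpm > siwi_rpm, "A",
        default = "undetermined")
}

#' Assign a bound PIWI to each reference piRNA
#'
#' Both IP libraries must be normalized with
#' `denominator_mode = "reference_matched"` (the IP convention: RPM against
#' the total read count over the reference piRNA set).  The call is S when
#' the Siwi-IP RPM is strictly larger, A when the BmAgo3-IP RPM is strictly
#' larger, and undetermined on ties or when neither library has more than
#' `low_count_threshold` raw reads.
#'
#' @param siwi_lib,ago3_lib `library_counts` objects keyed by pirna_id.
#' @param refs reference annotation table.
#' @param low_count_threshold raw-count floor (default 1: "no more than
#'   1 read in the IP libraries" is undetermined).
#' @return data.table(pirna_id, siwi_raw, ago3_raw, siwi_rpm, ago3_rpm,
#'   call).
#' @export
assign_piwi <- function(siwi_lib, ago3_lib, refs, low_count_threshold = 1) {
  for (lib in list(siwi_lib, ago3_lib)) {
    if (!identical(lib$denominator_mode, "reference_matched")) {
      stop("IP libraries must be normalized with denominator_mode = 'reference_matched'",
           call. = FALSE)
    }
  }
  refs <- as.data.table(refs)
  grab <- function(v, keys) {
    out <- unname(v[keys])
    out[is.na(out)] <- 0
    out
  }
  dt <- data.table(pirna_id = refs$pirna_id,
                   siwi_raw = grab(siwi_lib$counts, refs$pirna_id),
                   ago3_raw = grab(ago3_lib$counts, refs$pirna_id),
                   siwi_rpm = grab(siwi_lib$rpm, refs$pirna_id),
                   ago3_rpm = grab(ago3_lib$rpm, refs$pirna_id))
  dt[, call := piwi_call(siwi_raw, ago3_raw, siwi_rpm, ago3_rpm,
                         low_count_threshold)]
  dt[]
}

#' Ping-pong partner coordinate
#'
#' The partner of a piRNA whose 5' nucleotide sits at 1-based position p is
#' the species on the opposite strand whose 5' nucleotide sits at p + 9
#' (plus-strand source) or p - 9 (minus-strand source): the two 10-nt 5'
#' prefixes then base-pair over the same ten transposon positions.
#' Partners falling outside the transposon are flagged out of bounds.
#'
#' @param refs reference annotation table (one or more rows).
#' @param panel panel table (for transposon lengths).
#' @return data.table(pirna_id, te_id, partner_strand,
#'   partner_five_prime_pos, in_bounds).
#' @export
partner_coordinate <- function(refs, panel) {
  refs <- as.data.table(refs)
  te_len <- setNames(nchar(panel$sequence), panel$te_id)
  out <- data.table(
    pirna_id = refs$pirna_id,
    te_id = refs$te_id,
    partner_strand = fifelse(refs$strand == "+", "-", "+"),
    partner_five_prime_pos = as.integer(
      ifelse(refs$strand == "+", refs$five_prime_pos + 9L,
             refs$five_prime_pos - 9L)))
  out[, in_bounds := partner_five_prime_pos >= 1L &
        partner_five_prime_pos <= te_len[te_id]]
  out[]
}

#' Partner-site abundance and PIWI call
#'
#' Sums, in each IP library, all reads whose 5' end falls on the partner
#' coordinate (pooling read lengths) and applies the same call rule as
#' [assign_piwi()]; sites with no reads, or out-of-bounds partners, are
#' undetermined.
#'
#' @param partner_coords output of [partner_coordinate()].
#' @param siwi_tally,ago3_tally 5'-end tallies from
#'   [five_prime_site_tally()] on the two IP libraries.
#' @param siwi_denominator,ago3_denominator the reference-matched totals
#'   used to scale the IP libraries to RPM.
#' @param low_count_threshold raw-count floor, as in [assign_piwi()].
#' @return data.table(pirna_id, te_id, partner_strand,
#'   partner_five_prime_pos, siwi_raw, ago3_raw, siwi_rpm, ago3_rpm,
#'   partner_call).
#' @export
partner_abundance <- function(partner_coords, siwi_tally, ago3_tally,
                              siwi_denominator, ago3_denominator,
                              low_count_threshold = 1) {
  out <- as.data.table(partner_coords)
  lookup <- function(tally) {
    v <- tally[out, on = .(te_id, strand = partner_strand,
                           five_prime_pos = partner_five_prime_pos),
               x.count]
    v[is.na(v)] <- 0
    v
  }
  out[, siwi_raw := lookup(as.data.table(siwi_tally))]
  out[, ago3_raw := lookup(as.data.table(ago3_tally))]
  out[in_bounds == FALSE, `:=`(siwi_raw = 0, ago3_raw = 0)]
  out[, `:=`(siwi_rpm = siwi_raw / siwi_denominator * 1e6,
             ago3_rpm = ago3_raw / ago3_denominator * 1e6)]
  out[, partner_call := piwi_call(siwi_raw, ago3_raw, siwi_rpm, ago3_rpm,
                                  low_count_threshold)]
  out[in_bounds == FALSE, partner_call := "undetermined"]
  out[]
}

#' Classify reference piRNAs into ping-pong categories
#'
#' Exclusion precedence is rRNA transposon, then undetermined own/partner
#' call, then the ambiguous BmAgo3/BmAgo3 configuration; everything else is
#' labelled partner_call -> own_call.  By default A/A configurations are
#' excluded as ambiguous (sense and antisense both BmAgo3-bound);
#' `report_a_to_a = TRUE` reports them as their own A_to_A class instead.
#'
#' @param assignments output of [assign_piwi()].
#' @param partner_sites output of [partner_abundance()].
#' @param refs reference annotation table.
#' @param panel panel table (rRNA flags).
#' @param report_a_to_a report A/A as a class instead of excluding it.
#' @return data.table with one row per reference piRNA: pirna_id, te_id,
#'   strand, five_prime_pos, own_call, siwi_rpm, ago3_rpm,
#'   partner_five_prime_pos, partner_call, klass.  The klass column
#'   partitions the reference set.
#' @export
classify_pingpong <- function(assignments, partner_sites, refs, panel,
                              report_a_to_a = FALSE) {
  refs <- as.data.table(refs)
  assignments <- as.data.table(assignments)
  partner_sites <- as.data.table(partner_sites)
  miss <- setdiff(refs$pirna_id, assignments$pirna_id)
  if (length(miss)) stop("reference piRNA missing from assignments: ", miss[1],
                         call. = FALSE)
  miss <- setdiff(refs$pirna_id, partner_sites$pirna_id)
  if (length(miss)) stop("reference piRNA missing from partner sites: ",
                         miss[1], call. = FALSE)
  rrna_tes <- as.data.table(panel)[is_rrna_te == TRUE, te_id]
  out <- refs[, .(pirna_id, te_id, strand, five_prime_pos)]
  out <- assignments[, .(pirna_id, own_call = call, siwi_rpm, ago3_rpm)][
    out, on = "pirna_id"]
  out <- partner_sites[, .(pirna_id, partner_five_prime_pos, partner_call)][
    out, on = "pirna_id"]
  out[, klass := fcase(
    te_id %in% rrna_tes, "excl_rrna",
    own_call == "undetermined" | partner_call == "undetermined",
    "excl_undetermined",
    own_call == "A" & partner_call == "A",
    if (report_a_to_a) "A_to_A" else "excl_ambiguous",
    default = NA_character_)]
  out[is.na(klass), klass := paste0(partner_call, "_to_", own_call)]
  setcolorder(out, c("pirna_id", "te_id", "strand", "five_prime_pos",
                     "own_call", "siwi_rpm", "ago3_rpm",
                     "partner_five_prime_pos", "partner_call", "klass"))
  setorder(out, pirna_id)
  out[]
}

#' Category counts and partition check
#'
#' @param records output of [classify_pingpong()].
#' @return list(category_counts, n, partition_ok).
#' @export
pingpong_summary <- function(records) {
  records <- as.data.table(records)
  cnt <- records[, .N, by = klass]
  counts <- setNames(as.integer(cnt$N), cnt$klass)
  counts <- counts[order(match(names(counts), PP_CATEGORIES))]
  list(category_counts = as.list(counts), n = nrow(records),
       partition_ok = sum(counts) == nrow(records))
}

#' Class-level expression-change summary
#'
#' Joins the per-piRNA M values (knockdown vs control) onto the three
#' ping-pong classes and summarizes each class distribution; empty classes
#' are absent.
#'
#' @param records output of [classify_pingpong()].
#' @param expr_table piRNA expression table from
#'   [pirna_expression_table()] (column m_value keyed by `key`).
#' @return data.table(klass, n, median_m, q1_m, q3_m).
#' @export
class_expression_change <- function(records, expr_table) {
  records <- as.data.table(records)
  expr_table <- as.data.table(expr_table)
  m <- expr_table[records[klass %in% PP_CLASSES],
                  on = .(key = pirna_id), nomatch = 0L]
  out <- m[, .(n = .N,
               median_m = median(m_value),
               q1_m = unname(quantile(m_value, 0.25)),
               q3_m = unname(quantile(m_value, 0.75))), by = klass]
  setorder(out, klass)
  out[]
}

#' Compare classifier output with synthetic ground truth
#'
#' Recovery is measured over planted piRNAs whose true class is one of the
#' three ping-pong classes and that the generator intended to be
#' determinable (normal IP abundance, non-rRNA).
#'
#' @param records output of [classify_pingpong()].
#' @param truth truth table from [simulate_panel()].
#' @return list(n_evaluated, n_correct, recovery, confusion).
#' @export
evaluate_recovery <- function(records, truth) {
  truth <- as.data.table(truth)
  records <- as.data.table(records)
  eval_set <- truth[true_class %in% PP_CLASSES & expect_determinable == TRUE]
  m <- records[eval_set, on = "pirna_id"]
  confusion <- m[, .N, by = .(true_class, klass)]
  setorder(confusion, true_class, klass)
  list(n_evaluated = nrow(m),
       n_correct = sum(m$klass == m$true_class),
       recovery = mean(m$klass == m$true_class),
       confusion = confusion[])
}
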