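# MA-statistic expression-change analysis between a control and a knockdown
# library, at the TE level and at the reference-piRNA level, plus the
# rank-tertile grouping into increased / unchanged / decreased.

#' MA statistics for two normalized libraries
#'
#' With pseudocount c: M = log2((kd + c) / (ctrl + c)) and
#' A = (log2(kd + c) + log2(ctrl + c)) / 2.
#'
#' @param ctrl_rpm,kd_rpm non-negative RPM vectors.
#' @param pseudocount positive offset (default 1 RPM).
#' @return list(m_value, a_value).
#' @export
ma_stats <- function(ctrl_rpm, kd_rpm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (any(ctrl_rpm < 0) || any(kd_rpm < 0)) {
    stop("RPM values must be non-negative", call. = FALSE)
  }
  lc <- log2(ctrl_rpm + pseudocount)
  lk <- log2(kd_rpm + pseudocount)
  list(m_value = lk - lc, a_value = (lk + lc) / 2)
}

#' Expression filter for the piRNA-level MA analysis
#'
#' rRNA-TE piRNAs are always removed first; the remaining keys are kept
#' when either library reaches `min_rpm`.  Monotone in `min_rpm`.
#'
#' @param tbl data.table with columns key, ctrl_rpm, kd_rpm and logical
#'   is_rrna.
#' @param min_rpm expression threshold (default 0 keeps everything
#'   non-rRNA).
#' @return character vector of kept keys.
#' @export
expression_filter <- function(tbl, min_rpm = 0) {
  tbl <- as.data.table(tbl)
  tbl[is_rrna == FALSE & pmax(ctrl_rpm, kd_rpm) >= min_rpm, key]
}

#' Rank-tertile grouping of expression changes
#'
#' Keys must already be ranked by M descending (ties broken by key,
#' lexicographically).  The list is cut into three contiguous groups of
#' near-equal size; a remainder of 2 goes to the two outer groups
#' (increased, decreased), a remainder of 1 to the increased group.
#'
#' @param ranked_keys character vector, best-ranked (most increased) first.
#' @return data.table(key, group) with an attribute `sizes`, a named integer
#'   vector over increased/unchanged/decreased.
#' @export
tertile_groups <- function(ranked_keys) {
  n <- length(ranked_keys)
  if (n < 3L) stop("tertile grouping needs at least 3 keys", call. = FALSE)
  k <- n %/% 3L
  r <- n %% 3L
  sizes <- c(increased = k + as.integer(r >= 1L),
             unchanged = k,
             decreased = k + as.integer(r == 2L))
  group <- rep(c("increased", "unchanged", "decreased"), times = sizes)
  out <- data.table(group = group)
  out[, key := ranked_keys]
  setcolorder(out, c("key", "group"))
  setattr(out, "sizes", sizes)
  out
}

#' piRNA-level expression table with tertile groups
#'
#' Builds the per-reference-piRNA MA table between a control and a
#' knockdown library (both normalized against genome-mapped reads), applies
#' the rRNA and expression filters, and assigns rank tertiles; filtered-out
#' keys keep their M/A values but carry group `"filtered_out"`.
#'
#' @param ctrl_lib,kd_lib `library_counts` objects keyed by pirna_id.
#' @param refs reference annotation table.
#' @param panel panel table (supplies the rRNA-TE flags).
#' @param pseudocount MA offset in RPM.
#' @param min_rpm expression filter threshold.
#' @return data.table(key, ctrl_rpm, kd_rpm, a_value, m_value, group) with
#'   attribute `sizes`.
#' @export
pirna_expression_table <- function(ctrl_lib, kd_lib, refs, panel,
                                   pseudocount = 1, min_rpm = 0) {
  refs <- as.data.table(refs)
  panel <- as.data.table(panel)
  tbl <- data.table(ctrl_rpm = unname(ctrl_lib$rpm[refs$pirna_id]),
                    kd_rpm = unname(kd_lib$rpm[refs$pirna_id]))
  tbl[, key := refs$pirna_id]
  for (col in c("ctrl_rpm", "kd_rpm")) set(tbl, which(is.na(tbl[[col]])), col, 0)
  rrna_tes <- panel[is_rrna_te == TRUE, te_id]
  tbl[, is_rrna := refs$te_id %in% rrna_tes]
  ma <- ma_stats(tbl$ctrl_rpm, tbl$kd_rpm, pseudocount)
  tbl[, `:=`(m_value = ma$m_value, a_value = ma$a_value)]
  kept <- expression_filter(tbl, min_rpm)
  ranked <- tbl[key %in% kept][order(-m_value, key), key]
  groups <- tertile_groups(ranked)
  tbl[, group := "filtered_out"]
  tbl[groups, group := i.group, on = "key"]
  setattr(tbl, "sizes", attr(groups, "sizes"))
  setcolorder(tbl, c("key", "ctrl_rpm", "kd_rpm", "a_value", "m_value",
                     "is_rrna", "group"))
  tbl[]
}

#' TE-level MA table
#'
#' Per-transposon M/A values with the same pseudocount policy; no tertile
#' grouping at the TE level.
#'
#' @param ctrl_lib,kd_lib `library_counts` objects keyed by te_id over the
#'   same panel.
#' @param pseudocount MA offset in RPM.
#' @return data.table(te_id, ctrl_rpm, kd_rpm, a_value, m_value).
#' @export
te_ma_table <- function(ctrl_lib, kd_lib, pseudocount = 1) {
  if (!setequal(names(ctrl_lib$counts), names(kd_lib$counts))) {
    stop("panel mismatch: control and KD libraries were counted over different TE sets",
         call. = FALSE)
  }
  te <- sort(names(ctrl_lib$counts))
  ma <- ma_stats(unname(ctrl_lib$rpm[te]), unname(kd_lib$rpm[te]), pseudocount)
  data.table(te_id = te,
             ctrl_rpm = unname(ctrl_lib$rpm[te]),
             kd_rpm = unname(kd_lib$rpm[te]),
             a_value = ma$a_value, m_value = ma$m_value)
}
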