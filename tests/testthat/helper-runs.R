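# Shared synthetic-pipeline runs, computed once per test session.  The
# default run uses the generator's standard study conditions; the
# noiseless run switches off sequencing errors and uses cognate-only IP
# libraries, the regime in which classification must be perfect.

.run_cache <- new.env(parent = emptyenv())

cached_default_run <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- suppressMessages(
      run_synthetic_pipeline(sim_config(seed = 101L),
                             outdir = file.path(tempdir(), "pp_default")))
  }
  .run_cache$default
}

cached_noiseless_run <- function() {
  if (is.null(.run_cache$noiseless)) {
    cfg <- sim_config(seed = 101L, ip_enrichment = Inf, seq_error_rate = 0,
                      frac_low_count = 0)
    .run_cache$noiseless <- suppressMessages(
      run_synthetic_pipeline(cfg, outdir = file.path(tempdir(), "pp_noiseless")))
  }
  .run_cache$noiseless
}

# a small deterministic panel + annotation used across module tests
tiny_fixture <- function(seed = 42L) {
  set.seed(seed)
  te1 <- random_seq(300)
  te2 <- random_seq(250)
  panel <- data.table::data.table(
    te_id = c("te1", "te2"), sequence = c(te1, te2),
    is_rrna_te = c(FALSE, FALSE), is_decoy = c(FALSE, FALSE))
  refs <- data.table::data.table(
    pirna_id = c("pa", "pb"),
    te_id = c("te1", "te1"),
    strand = c("+", "-"),
    five_prime_pos = c(101L, 110L),
    sequence = c(substr(te1, 101, 128),
                 oracle_revcomp(substr(te1, 110 - 25, 110))))
  list(panel = panel, refs = refs)
}
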