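# Seeded synthetic-data generator: a random transposon panel with planted
# ping-pong pairs (exact 5' 10-nt overlap on opposite strands), 1U/10A
# biases imposed at the shared overlap base pair, an rRNA-like transposon
# carrying excluded piRNAs, a decoy background sequence standing in for the
# rest of the genome, a log-normal/negative-binomial count model for the
# control, knockdown and two IP libraries, and raw FASTQ emission with
# randomized 4-nt ends, 3' adapter, PCR duplication and sequencing errors.
# All randomness flows from the single seed in the configuration.

#' Simulation configuration
#'
#' Within an exact 10-nt-overlap pair the classes of the two members are
#' linked: the Siwi-bound member of a heterotypic pair is an A_to_S piRNA
#' and its BmAgo3-bound partner an S_to_A piRNA, so pairs are configured as
#' heterotypic (one A_to_S + one S_to_A reference piRNA each) or homotypic
#' (two S_to_S piRNAs).
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param n_te number of transposons in the panel (plus one rRNA-flagged
#'   transposon and one decoy background sequence).
#' @param te_length transposon length in nt.
#' @param n_pairs_het,n_pairs_hom planted heterotypic / homotypic pairs.
#' @param n_rrna_pairs heterotypic pairs planted on the rRNA transposon
#'   (their piRNAs are ground-truth exclusions).
#' @param frac_low_count fraction of non-rRNA reference piRNAs planted at
#'   near-zero IP abundance, so that their PIWI call is expected to be
#'   undetermined.
#' @param ip_enrichment fold enrichment of a piRNA in the IP of its bound
#'   PIWI (and depletion in the other); `Inf` gives cognate-only libraries.
#' @param bias_1U probability of forcing U at position 1 of each Siwi-bound
#'   planted piRNA.
#' @param bias_10A probability of forcing A at position 10 of each
#'   BmAgo3-bound planted piRNA.  Within a pair this is the complementary
#'   view of the partner's first base, so both draws act on the same
#'   transposon base pair.
#' @param kd_effects named fold changes applied to the knockdown mean by
#'   true class.
#' @param depth expected molecules per library (before PCR duplication).
#' @param frac_background decoy-derived off-size background molecules,
#'   as a fraction of `depth`.
#' @param pcr_duplication_mean mean reads per molecule (geometric).
#' @param seq_error_rate per-base substitution probability applied after
#'   duplication, so duplicates can disagree at error sites.
#' @param nb_dispersion negative-binomial dispersion of molecule counts.
#' @param count_model `"nb"` or `"poisson"`.
#' @param abundance_sdlog log-normal sd of per-piRNA base abundance.
#' @param low_count_ip_scale IP-mean multiplier for the `frac_low_count`
#'   piRNAs (default leaves them an expected fraction of a read).
#' @param adapter3_core,umi_len read layout used by [emit_fastq()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_te = 20L, te_length = 2000L,
                       n_pairs_het = 90L, n_pairs_hom = 30L,
                       n_rrna_pairs = 6L, frac_low_count = 0.05,
                       ip_enrichment = 8,
                       bias_1U = 0.9, bias_10A = 0.9,
                       kd_effects = c(A_to_S = 0.3, S_to_A = 0.7,
                                      S_to_S = 2.5),
                       depth = 2e5, frac_background = 0.1,
                       pcr_duplication_mean = 3, seq_error_rate = 0.001,
                       nb_dispersion = 0.05,
                       count_model = c("nb", "poisson"),
                       abundance_sdlog = 0.75,
                       low_count_ip_scale = 3e-4,
                       adapter3_core = "TGGAATTCTCGGGTGCCAAGG",
                       umi_len = 4L) {
  stopifnot(bias_1U >= 0, bias_1U <= 1, bias_10A >= 0, bias_10A <= 1,
            all(kd_effects > 0), depth > 0, te_length >= 80L,
            frac_low_count >= 0, frac_low_count < 1,
            ip_enrichment >= 1, pcr_duplication_mean >= 1,
            seq_error_rate >= 0, seq_error_rate < 1, nb_dispersion >= 0,
            frac_background >= 0)
  stopifnot(all(c("A_to_S", "S_to_A", "S_to_S") %in% names(kd_effects)))
  structure(list(seed = as.integer(seed), n_te = as.integer(n_te),
                 te_length = as.integer(te_length),
                 n_pairs_het = as.integer(n_pairs_het),
                 n_pairs_hom = as.integer(n_pairs_hom),
                 n_rrna_pairs = as.integer(n_rrna_pairs),
                 frac_low_count = frac_low_count,
                 ip_enrichment = ip_enrichment,
                 bias_1U = bias_1U, bias_10A = bias_10A,
                 kd_effects = kd_effects, depth = depth,
                 frac_background = frac_background,
                 pcr_duplication_mean = pcr_duplication_mean,
                 seq_error_rate = seq_error_rate,
                 nb_dispersion = nb_dispersion,
                 count_model = match.arg(count_model),
                 abundance_sdlog = abundance_sdlog,
                 low_count_ip_scale = low_count_ip_scale,
                 adapter3_core = normalize_dna(adapter3_core),
                 umi_len = as.integer(umi_len)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

SIM_RRNA_TE <- "te_rrna"
SIM_DECOY <- "decoy_background"

#' Simulate a transposon panel with planted ping-pong pairs
#'
#' Each planted pair consists of two piRNAs on opposite strands of one
#' transposon whose 5' ends are 10 nt apart, i.e. whose 10-nt 5' prefixes
#' base-pair exactly.  The 1U hallmark of each Siwi-bound member and the
#' 10A hallmark of each BmAgo3-bound member are imposed on the (shared)
#' transposon base pair with the configured probabilities before reference
#' sequences are extracted, so reference piRNAs always match their
#' transposon exactly.  Pair windows never overlap, so every planted 5'
#' anchor is unique.
#'
#' @param config a [sim_config()].
#' @return list(panel, refs, truth, config) of class `sim_panel`; `truth`
#'   has one row per planted piRNA with its PIWI identity, true class,
#'   pair id and determinability flag.
#' @export
simulate_panel <- function(config = sim_config()) {
  set.seed(stage_seed(config$seed, 0L))
  te_ids <- c(sprintf("te%02d", seq_len(config$n_te)), SIM_RRNA_TE)
  te_seq <- vapply(te_ids, function(i) random_dna(config$te_length),
                   character(1))
  decoy <- random_dna(2L * config$te_length)
  occupied <- lapply(te_seq, function(s) logical(nchar(s)))

  pair_types <- c(rep("het", config$n_pairs_het),
                  rep("hom", config$n_pairs_hom),
                  rep("rrna", config$n_rrna_pairs))
  n_pairs <- length(pair_types)
  plus_rows <- vector("list", n_pairs)
  minus_rows <- vector("list", n_pairs)
  forced <- vector("list", n_pairs)

  for (i in seq_len(n_pairs)) {
    type <- pair_types[i]
    te <- if (type == "rrna") SIM_RRNA_TE else
      sample(te_ids[te_ids != SIM_RRNA_TE], 1L)
    len <- config$te_length
    l_plus <- sample(23:32, 1L)
    l_minus <- sample(23:32, 1L)
    # plus-strand 5' at p, minus-strand partner 5' at q = p + 9;
    # the pair occupies at most [p - 22, p + 31]
    p_lo <- max(1L, l_minus - 9L, 23L)
    p_hi <- len - max(l_plus - 1L, 9L) - 22L
    placed <- FALSE
    for (try in seq_len(200L)) {
      p <- sample(p_lo:p_hi, 1L)
      win <- max(1L, p - 22L):min(len, p + 31L)
      if (!any(occupied[[te]][win])) {
        occupied[[te]][win] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("panel too small for the requested number of pairs", call. = FALSE)
    }
    q <- p + 9L
    # member identities: heterotypic pairs put BmAgo3 on the plus (sense)
    # strand and Siwi on the minus (antisense) strand; homotypic pairs are
    # Siwi on both
    piwi_plus <- if (type == "hom") "S" else "A"
    piwi_minus <- "S"
    class_plus <- switch(type, het = "S_to_A", hom = "S_to_S",
                         rrna = "excl_rrna")
    class_minus <- switch(type, het = "A_to_S", hom = "S_to_S",
                          rrna = "excl_rrna")
    # impose hallmark bases on the shared overlap base pair(s):
    # 1U of a Siwi member and 10A of its BmAgo3 partner are complementary
    # views of the same transposon position
    f <- character(0)
    # minus member 5' base (TE position q): U1 needs TE[q] == A
    if (piwi_minus == "S" && runif(1) < config$bias_1U) f[as.character(q)] <- "A"
    # plus member position 10 (TE position q): A10 needs TE[q] == A
    if (piwi_plus == "A" && runif(1) < config$bias_10A) f[as.character(q)] <- "A"
    # plus member 5' base (TE position p): U1 needs TE[p] == T
    if (piwi_plus == "S" && runif(1) < config$bias_1U) f[as.character(p)] <- "T"
    # minus member position 10 (TE position p): A10 needs TE[p] == T
    if (piwi_minus == "A" && runif(1) < config$bias_10A) f[as.character(p)] <- "T"
    forced[[i]] <- if (length(f)) data.table(te_id = te,
                                             pos = as.integer(names(f)),
                                             base = unname(f)) else NULL
    plus_rows[[i]] <- data.table(te_id = te, strand = "+",
                                 five_prime_pos = p, length = l_plus,
                                 piwi = piwi_plus, true_class = class_plus,
                                 pair_id = i)
    minus_rows[[i]] <- data.table(te_id = te, strand = "-",
                                  five_prime_pos = q, length = l_minus,
                                  piwi = piwi_minus, true_class = class_minus,
                                  pair_id = i)
  }

  fb <- rbindlist(forced)
  if (nrow(fb)) {
    for (j in seq_len(nrow(fb))) {
      substr(te_seq[[fb$te_id[j]]], fb$pos[j], fb$pos[j]) <- fb$base[j]
    }
  }

  truth <- rbindlist(c(plus_rows, minus_rows))
  setorder(truth, pair_id, strand)
  truth[, pirna_id := sprintf("pi%04d", .I)]
  truth[, sequence := ifelse(
    strand == "+",
    substr(te_seq[te_id], five_prime_pos, five_prime_pos + length - 1L),
    revcomp(substr(te_seq[te_id], five_prime_pos - length + 1L,
                   five_prime_pos)))]
  truth[, expect_determinable := true_class %in% PP_CLASSES]
  n_low <- round(config$frac_low_count * sum(truth$expect_determinable))
  if (n_low > 0) {
    low <- sample(truth[expect_determinable == TRUE, pirna_id], n_low)
    truth[, low_count := pirna_id %in% low]
    # a starved piRNA takes its pair partner down with it: the partner's
    # partner-site has (next to) no IP reads, so neither label is
    # recoverable in principle
    low_pairs <- truth[low_count == TRUE, unique(pair_id)]
    truth[pair_id %in% low_pairs, expect_determinable := FALSE]
  } else {
    truth[, low_count := FALSE]
  }

  panel <- data.table(te_id = c(te_ids, SIM_DECOY),
                      sequence = c(unname(te_seq), decoy),
                      is_rrna_te = c(te_ids == SIM_RRNA_TE, FALSE),
                      is_decoy = c(rep(FALSE, length(te_ids)), TRUE))
  refs <- truth[, .(pirna_id, te_id, strand, five_prime_pos, sequence)]
  setcolorder(truth, c("pirna_id", "te_id", "strand", "five_prime_pos",
                       "length", "sequence", "piwi", "true_class", "pair_id",
                       "low_count", "expect_determinable"))
  structure(list(panel = panel[], refs = refs[], truth = truth[],
                 config = config),
            class = "sim_panel")
}

#' Simulate per-library molecule counts
#'
#' Base abundance per piRNA is log-normal; the control mean is the
#' abundance share times `depth`, the knockdown mean is the control mean
#' times the class fold change, and the IP means weight the base abundance
#' by `ip_enrichment` for the cognate PIWI and its inverse otherwise
#' (cognate-only when infinite).  Counts are drawn negative-binomially
#' (or Poisson).
#'
#' @param sim a `sim_panel` object.
#' @param config a [sim_config()]; defaults to the one inside `sim`.
#' @return list of class `sim_counts`: `libs` (named molecule-count vectors
#'   for control, kd, siwi_ip, ago3_ip), `n_background` (decoy molecules
#'   per library), and `truth` augmented with the per-library means and
#'   drawn counts.
#' @export
simulate_counts <- function(sim, config = sim$config) {
  set.seed(stage_seed(config$seed, 1L))
  truth <- copy(sim$truth)
  n <- nrow(truth)
  base <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  truth[, base_abundance := base]
  fold <- rep(1, n)
  cls <- truth$true_class
  in_kd <- cls %in% names(config$kd_effects)
  fold[in_kd] <- config$kd_effects[cls[in_kd]]

  ctrl_mean <- base / sum(base) * config$depth
  kd_mean <- ctrl_mean * fold
  ip_weight <- function(cognate) {
    w <- if (is.infinite(config$ip_enrichment)) {
      ifelse(cognate, base, 0)
    } else {
      base * ifelse(cognate, config$ip_enrichment, 1 / config$ip_enrichment)
    }
    w[truth$low_count] <- w[truth$low_count] * config$low_count_ip_scale
    w / sum(w) * config$depth
  }
  siwi_mean <- ip_weight(truth$piwi == "S")
  ago3_mean <- ip_weight(truth$piwi == "A")

  draw <- function(mu) {
    if (config$count_model == "nb" && config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      rpois(length(mu), mu)
    }
  }
  libs <- list(control = draw(ctrl_mean), kd = draw(kd_mean),
               siwi_ip = draw(siwi_mean), ago3_ip = draw(ago3_mean))
  libs <- lapply(libs, setNames, truth$pirna_id)
  truth[, `:=`(ctrl_mean = ctrl_mean, kd_mean = kd_mean,
               siwi_mean = siwi_mean, ago3_mean = ago3_mean,
               ctrl_count = libs$control, kd_count = libs$kd,
               siwi_count = libs$siwi_ip, ago3_count = libs$ago3_ip)]
  n_background <- setNames(rep(round(config$frac_background * config$depth), 4L),
                           names(libs))
  structure(list(libs = libs, n_background = n_background, truth = truth[],
                 config = config),
            class = "sim_counts")
}

ALL_4MERS <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                         stringsAsFactors = FALSE)[, 4:1])

random_umis <- function(n, len) {
  if (len == 4L) return(ALL_4MERS[sample.int(256L, n, replace = TRUE)])
  vapply(seq_len(n), function(i) random_dna(len), character(1))
}

inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  len <- nchar(reads)
  n_err <- rbinom(length(reads), len, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  reads
}

#' Emit raw FASTQ libraries from simulated counts
#'
#' Each molecule is laid out as 4-nt UMI + piRNA + 4-nt UMI + 3'-adapter
#' core, duplicated a geometric number of times (PCR), then hit by
#' independent per-base substitution errors, so duplicates can disagree at
#' error sites.  Background molecules are off-size (18-22 / 33-38 nt)
#' windows of the decoy sequence on either strand.  Identical seeds give
#' byte-identical output.
#'
#' @param counts a `sim_counts` object.
#' @param sim the `sim_panel` the counts were drawn from.
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()]; defaults to the one inside `counts`.
#' @param write_manifest also write per-library read_id -> species TSVs.
#' @return list of class `sim_dataset` with the paths of the panel FASTA,
#'   reference TSV, truth TSV and the four FASTQ files.
#' @export
emit_fastq <- function(counts, sim, outdir, config = counts$config,
                       write_manifest = FALSE) {
  set.seed(stage_seed(config$seed, 2L))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  decoy <- sim$panel[is_decoy == TRUE, sequence][1]
  fastq <- character(0)
  manifest_paths <- character(0)
  for (lib in names(counts$libs)) {
    cnt <- counts$libs[[lib]]
    core <- rep(sim$truth$sequence, cnt)
    species <- rep(sim$truth$pirna_id, cnt)
    nb <- counts$n_background[[lib]]
    if (nb > 0L) {
      blen <- sample(c(18:22, 33:38), nb, replace = TRUE)
      bstart <- floor(runif(nb, 1, nchar(decoy) - blen + 1))
      bg <- substring(decoy, bstart, bstart + blen - 1L)
      flip <- runif(nb) < 0.5
      bg[flip] <- revcomp(bg[flip])
      core <- c(core, bg)
      species <- c(species, rep("background", nb))
    }
    n <- length(core)
    reads <- paste0(random_umis(n, config$umi_len), core,
                    random_umis(n, config$umi_len), config$adapter3_core)
    dup <- rgeom(n, prob = 1 / config$pcr_duplication_mean) + 1L
    reads <- rep(reads, dup)
    species <- rep(species, dup)
    molecule <- reads  # pre-error layout, for audit / round-trip checks
    reads <- inject_errors(reads, config$seq_error_rate)
    ids <- sprintf("%s_%07d", lib, seq_along(reads))
    path <- file.path(outdir, paste0(lib, ".fastq"))
    write_small_rna_fastq(data.table(read_id = ids, sequence = reads,
                                     quality = NA_character_), path)
    fastq[lib] <- path
    if (write_manifest) {
      mpath <- file.path(outdir, paste0(lib, "_manifest.tsv"))
      fwrite(data.table(read_id = ids, species = species,
                        molecule = molecule), mpath, sep = "\t")
      manifest_paths[lib] <- mpath
    }
  }
  panel_path <- file.path(outdir, "panel.fa")
  write_te_panel(sim$panel, panel_path)
  refs_path <- file.path(outdir, "reference_pirnas.tsv")
  write_reference_pirnas(sim$refs, refs_path)
  truth_path <- file.path(outdir, "truth.tsv")
  fwrite(counts$truth, truth_path, sep = "\t")
  structure(list(fastq = as.list(fastq), panel = panel_path,
                 refs = refs_path, truth = truth_path,
                 manifests = as.list(manifest_paths), outdir = outdir,
                 config = config),
            class = "sim_dataset")
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_panel()] then [simulate_counts()] then
#' [emit_fastq()].
#'
#' @inheritParams simulate_panel
#' @inheritParams emit_fastq
#' @return list(sim, counts, dataset).
#' @export
simulate_dataset <- function(config = sim_config(), outdir,
                             write_manifest = FALSE) {
  sim <- simulate_panel(config)
  counts <- simulate_counts(sim, config)
  dataset <- emit_fastq(counts, sim, outdir, config,
                        write_manifest = write_manifest)
  list(sim = sim, counts = counts, dataset = dataset)
}
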