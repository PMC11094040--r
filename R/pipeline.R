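# Orchestration: one call runs preprocess -> map -> normalize ->
# (TE & piRNA expression, 1U/10A bias, ping-pong classification) on four
# FASTQ libraries and writes deterministic TSV tables plus a JSON summary;
# a second entry point drives the whole thing from the synthetic generator
# and scores recovery against ground truth.

#' Pipeline run configuration
#'
#' @param panel_fasta FASTA transposon panel.
#' @param refs_tsv reference piRNA annotation TSV.
#' @param fastq named list with elements control, kd, siwi_ip, ago3_ip
#'   (paths to FASTQ files).
#' @param outdir output directory.
#' @param preprocess a [preprocess_config()].
#' @param mapper a [mapper_config()].
#' @param pseudocount MA offset in RPM.
#' @param min_rpm piRNA expression filter threshold.
#' @param low_count_threshold IP raw-count floor for PIWI calls.
#' @param rrna_te_ids,decoy_te_ids panel annotations (see
#'   [read_te_panel()]).
#' @param report_a_to_a report A/A configurations as a class instead of
#'   excluding them.
#' @return object of class `run_config`.
#' @export
run_config <- function(panel_fasta, refs_tsv, fastq, outdir,
                       preprocess = preprocess_config(),
                       mapper = mapper_config(),
                       pseudocount = 1, min_rpm = 1,
                       low_count_threshold = 1,
                       rrna_te_ids = character(),
                       decoy_te_ids = character(),
                       report_a_to_a = FALSE) {
  cfg <- structure(list(panel_fasta = panel_fasta, refs_tsv = refs_tsv,
                        fastq = fastq, outdir = outdir,
                        preprocess = preprocess, mapper = mapper,
                        pseudocount = pseudocount, min_rpm = min_rpm,
                        low_count_threshold = low_count_threshold,
                        rrna_te_ids = rrna_te_ids,
                        decoy_te_ids = decoy_te_ids,
                        report_a_to_a = report_a_to_a),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(config) {
  stage_of <- c(control = "expression", kd = "expression",
                siwi_ip = "pingpong", ago3_ip = "pingpong")
  need <- names(stage_of)
  miss <- setdiff(need, names(config$fastq))
  if (length(miss)) {
    stop(sprintf("%s stage: missing %s library", stage_of[miss[1]], miss[1]),
         call. = FALSE)
  }
  for (lib in need) {
    if (!file.exists(config$fastq[[lib]])) {
      stop(sprintf("%s stage: missing %s library file '%s'",
                   stage_of[lib], lib, config$fastq[[lib]]), call. = FALSE)
    }
  }
  for (p in c(config$panel_fasta, config$refs_tsv)) {
    if (!file.exists(p)) stop("mapping stage: missing input file '", p, "'",
                              call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `preprocess`
#' and `mapper` sub-maps are passed to their constructors.
#'
#' @param path YAML file.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  args$preprocess <- do.call(preprocess_config, y$preprocess %||% list())
  args$mapper <- do.call(mapper_config, y$mapper %||% list())
  do.call(run_config, args)
}

plog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# preprocess + map one library once; everything downstream reuses the hits
library_analysis <- function(lib, path, config, index, refs) {
  reads <- read_small_rna_fastq(path)
  pp <- preprocess_reads(reads, config$preprocess)
  plog("preprocess", "%s: %d reads -> %d molecules -> %d cores (%d species)",
       lib, pp$report$n_input, pp$report$n_molecules,
       pp$report$n_core_molecules, pp$report$n_core_species)
  cores <- pp$cores
  hits <- map_sequences(cores$sequence, index, config$mapper)
  len <- nchar(cores$sequence)
  pirna_cores <- cores[len >= 23L & len <= 32L]
  pirna_hits <- hits[sequence %in% pirna_cores$sequence]
  list(report = pp$report,
       cores = cores,
       mapped_total = genome_mapped_denominator(cores, index, config$mapper,
                                                hits = hits),
       ref_counts = count_reference_pirnas(pirna_cores, index, refs,
                                           config$mapper, hits = pirna_hits),
       tally = five_prime_site_tally(pirna_cores, index, config$mapper,
                                     hits = pirna_hits),
       te_counts = te_counts_best_single(pirna_cores, pirna_hits, index))
}

# TE-level counts: one placement per read (deterministic tie-break),
# decoy excluded
te_counts_best_single <- function(cores, hits, index) {
  te_ids <- index$panel[is_decoy == FALSE, te_id]
  counts <- setNames(numeric(length(te_ids)), te_ids)
  if (!nrow(hits)) return(counts)
  best <- hits[hits[, .I[1L], by = sequence]$V1]
  m <- best[cores, on = "sequence", nomatch = 0L]
  agg <- m[te_id %in% te_ids, .(count = sum(count)), by = te_id]
  counts[agg$te_id] <- agg$count
  counts
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> map -> normalize -> (TE and piRNA expression,
#' 1U/10A bias, ping-pong classification) and writes TSV tables, a JSON
#' summary and the resolved configuration into `outdir`.  The run is fully
#' deterministic: rerunning with the same inputs reproduces every table
#' byte for byte.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with elements expr_table, te_table, bias_table,
#'   records, class_change, summary, libraries, reports, paths.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  plog("load", "panel %s, references %s", config$panel_fasta, config$refs_tsv)
  panel <- read_te_panel(config$panel_fasta, config$rrna_te_ids,
                         config$decoy_te_ids)
  refs <- read_reference_pirnas(config$refs_tsv, panel)
  index <- build_te_index(panel)

  libs <- names(config$fastq)
  ana <- lapply(setNames(libs, libs), function(lib) {
    library_analysis(lib, config$fastq[[lib]], config, index, refs)
  })

  # KD-experiment libraries: RPM against genome-mapped reads
  norm <- list()
  for (lib in c("control", "kd")) {
    norm[[lib]] <- normalize_library(ana[[lib]]$ref_counts,
                                     ana[[lib]]$mapped_total,
                                     "genome_mapped", lib, lib)
  }
  # IP libraries: RPM against the total read count over the reference set
  for (lib in c("siwi_ip", "ago3_ip")) {
    norm[[lib]] <- normalize_library(ana[[lib]]$ref_counts,
                                     sum(ana[[lib]]$ref_counts),
                                     "reference_matched", lib, lib)
  }
  plog("normalize", "denominators: %s",
       paste(sprintf("%s=%.0f", libs,
                     vapply(norm, `[[`, numeric(1), "denominator")),
             collapse = ", "))

  expr_table <- pirna_expression_table(norm$control, norm$kd, refs, panel,
                                       config$pseudocount, config$min_rpm)
  sizes <- attr(expr_table, "sizes")
  plog("expression", "groups: increased=%d unchanged=%d decreased=%d",
       sizes["increased"], sizes["unchanged"], sizes["decreased"])
  bias_table <- bias_fraction_table(
    expr_table[group != "filtered_out", .(key, group)],
    setNames(refs$sequence, refs$pirna_id))

  te_ctrl <- normalize_library(ana$control$te_counts, ana$control$mapped_total,
                               "genome_mapped", "control", "control")
  te_kd <- normalize_library(ana$kd$te_counts, ana$kd$mapped_total,
                             "genome_mapped", "kd", "kd")
  te_table <- te_ma_table(te_ctrl, te_kd, config$pseudocount)

  assignments <- assign_piwi(norm$siwi_ip, norm$ago3_ip, refs,
                             config$low_count_threshold)
  coords <- partner_coordinate(refs, panel)
  partner_sites <- partner_abundance(coords, ana$siwi_ip$tally,
                                     ana$ago3_ip$tally,
                                     norm$siwi_ip$denominator,
                                     norm$ago3_ip$denominator,
                                     config$low_count_threshold)
  records <- classify_pingpong(assignments, partner_sites, refs, panel,
                               config$report_a_to_a)
  summ <- pingpong_summary(records)
  plog("pingpong", "categories: %s",
       paste(sprintf("%s=%d", names(summ$category_counts),
                     unlist(summ$category_counts)), collapse = ", "))
  class_change <- class_expression_change(records, expr_table)

  paths <- list(
    expr_table = file.path(config$outdir, "pirna_expression.tsv"),
    te_table = file.path(config$outdir, "te_expression.tsv"),
    bias_table = file.path(config$outdir, "bias_fractions.tsv"),
    records = file.path(config$outdir, "pingpong_records.tsv"),
    class_change = file.path(config$outdir, "class_expression_change.tsv"),
    summary = file.path(config$outdir, "summary.json"),
    config = file.path(config$outdir, "run_config.yaml"))
  write_result_table(expr_table, paths$expr_table)
  write_result_table(te_table, paths$te_table)
  write_result_table(bias_table, paths$bias_table)
  write_result_table(records, paths$records)
  write_result_table(class_change, paths$class_change)
  summary <- list(
    category_counts = summ$category_counts,
    n_reference_pirnas = summ$n,
    partition_ok = summ$partition_ok,
    group_sizes = as.list(sizes),
    denominators = lapply(norm, `[[`, "denominator"),
    class_change = as.data.frame(class_change),
    preprocess = lapply(ana, `[[`, "report"))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  yaml::write_yaml(serialize_run_config(config), paths$config)

  invisible(list(expr_table = expr_table, te_table = te_table,
                 bias_table = bias_table, assignments = assignments,
                 partner_sites = partner_sites, records = records,
                 class_change = class_change, summary = summary,
                 libraries = norm, reports = lapply(ana, `[[`, "report"),
                 paths = paths))
}

serialize_run_config <- function(config) {
  out <- config
  out$preprocess <- unclass(config$preprocess)
  out$mapper <- unclass(config$mapper)
  out$kd_effects <- as.list(out$kd_effects %||% NULL)
  unclass(out)
}

#' Simulate a dataset and run the pipeline on it
#'
#' @param sim_cfg a [sim_config()].
#' @param outdir output directory (the synthetic FASTQ files go to
#'   `outdir/sim`, the analysis tables to `outdir/analysis`).
#' @param ... further arguments to [run_config()] (e.g. `min_rpm`).
#' @return list(sim, counts, results, recovery).
#' @export
run_synthetic_pipeline <- function(sim_cfg = sim_config(), outdir = tempfile(),
                                   ...) {
  sims <- simulate_dataset(sim_cfg, file.path(outdir, "sim"))
  cfg <- run_config(panel_fasta = sims$dataset$panel,
                    refs_tsv = sims$dataset$refs,
                    fastq = sims$dataset$fastq,
                    outdir = file.path(outdir, "analysis"),
                    rrna_te_ids = SIM_RRNA_TE,
                    decoy_te_ids = SIM_DECOY, ...)
  results <- run_pipeline(cfg)
  recovery <- evaluate_recovery(results$records, sims$sim$truth)
  plog("recovery", "%d/%d planted determinable piRNAs recovered (%.1f%%)",
       recovery$n_correct, recovery$n_evaluated, 100 * recovery$recovery)
  list(sim = sims$sim, counts = sims$counts, results = results,
       recovery = recovery)
}

#' Write summary figures
#'
#' An MA scatter colored by expression group, stacked 1U/10A bias bars per
#' group, and box plots of per-class expression change.  Plot failures are
#' downgraded to warnings and never alter tables.
#'
#' @param results list returned by [run_pipeline()].
#' @param outdir output directory.
#' @param format "pdf", "png" or "svg".
#' @return named list of written figure paths (invisibly).
#' @export
make_figures <- function(results, outdir, format = c("pdf", "png", "svg")) {
  format <- match.arg(format)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  group_cols <- c(increased = "#d62728", unchanged = "#2ca02c",
                  decreased = "#1f77b4", filtered_out = "grey80")
  figs <- list(
    ma_plot = ggplot2::ggplot(results$expr_table,
                              ggplot2::aes(a_value, m_value, colour = group)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.8) +
      ggplot2::scale_colour_manual(values = group_cols) +
      ggplot2::labs(x = "A (mean log2 RPM)", y = "M (log2 KD / control)") +
      ggplot2::theme_bw(),
    bias_bars = ggplot2::ggplot(results$bias_table,
                                ggplot2::aes(group, fraction, fill = bias_class)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "fraction of piRNAs") +
      ggplot2::theme_bw(),
    class_boxes = local({
      dt <- merge(results$records[klass %in% PP_CLASSES,
                                  .(pirna_id, klass)],
                  results$expr_table[, .(pirna_id = key, m_value)],
                  by = "pirna_id")
      ggplot2::ggplot(dt, ggplot2::aes(klass, m_value)) +
        ggplot2::geom_boxplot(outlier.size = 0.5) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2) +
        ggplot2::labs(x = NULL, y = "M (log2 KD / control)") +
        ggplot2::theme_bw()
    }))
  paths <- list()
  for (nm in names(figs)) {
    path <- file.path(outdir, paste0(nm, ".", format))
    ok <- tryCatch({
      ggplot2::ggsave(path, figs[[nm]], width = 5, height = 4)
      TRUE
    }, error = function(e) {
      warning("figure '", nm, "' could not be rendered: ",
              conditionMessage(e), call. = FALSE)
      FALSE
    })
    if (ok) paths[[nm]] <- path
  }
  invisible(paths)
}
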