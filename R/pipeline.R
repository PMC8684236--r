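# End-to-end orchestration over a synthetic cohort: generate -> emulate
# callers -> panel -> consensus filter -> annotate -> spectra -> signature
# refit -> kataegis / terminal enrichment -> cohort report bundle.

#' Compare a filtered call set against the planted truth
#'
#' Calls and truth are matched on (sample, chrom, pos, ref, alt).
#'
#' @param final data.frame of retained calls (`retained == TRUE` rows of
#'   [filter_cohort()] output, or any call table).
#' @param truth A `truth_set`.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_filter <- function(final, truth) {
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
  fk <- key(final); tk <- key(truth$variants)
  tp <- sum(fk %in% tk)
  fp <- length(fk) - tp
  fn <- length(tk) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a synthetic reference and truth cohort, emulates per-caller
#' call sets and the normal panel, applies consensus and threshold
#' filtering, annotates the final set, computes spectra, refits signature
#' exposures, detects kataegis, tests terminal enrichment and assembles
#' the cohort report. Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory for the report bundle (`summary.json`,
#'   `per_sample.tsv`, `proportions.tsv`, `exposures.tsv`,
#'   `kataegis.bed`, `kataegis.tsv`, `log.txt`); NULL to skip writing.
#' @param seed Optional integer overriding `config$seed`.
#' @param write_vcfs If TRUE also write the reference, truth and emulated
#'   VCF inputs under `out_dir/inputs`.
#' @param n_perm Permutations for the terminal enrichment test.
#' @return A `pipeline_result` list with every stage's object.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         seed = NULL, write_vcfs = FALSE, n_perm = 1000) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  genome <- stage("reference", generate_reference(config))
  genome_mb <- sum(Biostrings::width(genome$chromosomes)) / 1e6
  say("reference: %d chromosomes, %.2f Mb, %d mask tracts",
      length(genome$chromosomes), genome_mb, nrow(genome$mask))

  truth <- stage("truth", plant_somatic_mutations(genome, config))
  say("truth: %d variants in %d samples", nrow(truth$variants),
      nrow(truth$samples))

  emu <- stage("callers", emulate_caller_outputs(
    truth, genome, dir = if (write_vcfs && !is.null(out_dir)) {
      file.path(out_dir, "inputs")
    } else NULL))
  say("callers: %d tumor records (%d injected FPs), %d normal records",
      nrow(emu$calls), sum(emu$calls$is_fp), nrow(emu$normal_calls))

  panel <- stage("panel", build_normal_panel(
    emu$normal_calls, min_supporting_normals = 1))
  say("panel of normals: %d sites from %d normals", nrow(panel$sites),
      panel$n_normals)

  merged <- stage("merge", {
    do.call(rbind, lapply(split(emu$calls, emu$calls$sample_id),
                          consensus_merge))
  })
  filtered <- stage("filter", filter_cohort(merged, panel, genome$mask))
  final <- filtered[filtered$retained, , drop = FALSE]
  rownames(final) <- NULL
  say("filter: %d merged calls -> %d retained", nrow(filtered), nrow(final))

  annotated <- stage("annotate", annotate_cohort(final, genome$model,
                                                 genome$chromosomes))
  say("annotate: %d exonic / %d intronic / %d intergenic",
      sum(annotated$region_class == "exonic"),
      sum(annotated$region_class == "intronic"),
      sum(annotated$region_class == "intergenic"))

  snvs <- annotated[annotated$type == "SNV", , drop = FALSE]
  spectra <- stage("spectrum", lapply(truth$samples$sample_id, function(sid) {
    sample_spectrum(snvs[snvs$sample_id == sid, , drop = FALSE],
                    genome, sample_id = sid)
  }))
  say("spectrum: %d sample spectra, %d pooled SNVs", length(spectra),
      sum(vapply(spectra, function(s) sum(s$counts96), 0)))

  sigs <- synthetic_signature_matrix()
  contrib <- stage("signatures", cohort_contributions(spectra, sigs))
  say("signatures: fitted %d samples against %d signatures",
      sum(!contrib$contributions$low_count), ncol(sigs))

  kat <- stage("kataegis", {
    evs <- lapply(truth$samples$sample_id, function(sid) {
      v <- annotated[annotated$sample_id == sid, , drop = FALSE]
      ev <- detect_kataegis(v)
      if (nrow(ev)) ev$sample_id <- sid
      ev
    })
    do.call(rbind, evs[vapply(evs, nrow, 0L) > 0])
  })
  n_kat <- if (is.null(kat)) 0L else nrow(kat)
  say("kataegis: %d events", n_kat)

  term <- stage("terminal", terminal_enrichment(
    annotated, genome, terminal_fraction = config$terminal_fraction,
    n_perm = n_perm, seed = child_seed(config$seed, "terminal")))
  say("terminal enrichment: observed %.3f vs expected %.3f (p = %.4g)",
      term$observed_fraction, term$expected_fraction, term$permutation_p)

  summary <- stage("report", summarize_cohort(
    annotated, truth$samples, genome_mb,
    driver_defs = list(exon3_driver = genome$driver_sites$exon3,
                       v600e_driver = genome$driver_sites$v600e)))
  corr <- tryCatch(
    pearson_age_correlation(summary$per_sample$age,
                            summary$per_sample$n_snv +
                              summary$per_sample$n_indel),
    error = function(e) structure(list(r = NA_real_, p = NA_real_,
                                       n = nrow(summary$per_sample)),
                                  class = "correlation_result"))
  excl <- driver_exclusivity(summary$genotypes)
  perf <- evaluate_filter(final, truth)
  say("report: mean TMB %.3f SNV / %.3f InDel per Mb; filter F1 %.3f",
      summary$mean_tmb_snv, summary$mean_tmb_indel, perf$f1)

  result <- structure(list(
    config = config, genome = genome, truth = truth, emulation = emu,
    panel = panel, filtered = filtered, final = final,
    annotated = annotated, spectra = spectra, contributions = contrib,
    kataegis = kat, terminal = term, summary = summary,
    correlation = corr, exclusivity = excl, filter_performance = perf,
    log = log_lines), class = "pipeline_result")

  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  invisible(result)
}

#' Write the report bundle of a pipeline run
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- result$summary
  excl <- result$exclusivity
  drivers <- setdiff(names(excl), "n_both_drivers")
  summary_json <- list(
    n_samples = nrow(s$per_sample),
    genome_mb = s$genome_mb,
    mean_tmb_snv = s$mean_tmb_snv,
    mean_tmb_indel = s$mean_tmb_indel,
    mean_snv_per_sample = mean(s$per_sample$n_snv),
    mean_indel_per_sample = mean(s$per_sample$n_indel),
    region_percent = stats::setNames(as.list(s$region_proportions$percent),
                                     s$region_proportions$class),
    effect_percent = stats::setNames(as.list(s$effect_proportions$percent),
                                     s$effect_proportions$class),
    coding_percent = s$coding_fraction$percent[1],
    age_correlation = list(r = result$correlation$r,
                           p = result$correlation$p,
                           n = result$correlation$n),
    driver = stats::setNames(lapply(drivers, function(d) {
      list(percent_by_subtype = as.list(excl[[d]]$percent_by_subtype),
           fisher_p = excl[[d]]$fisher_p)
    }), drivers),
    n_kataegis_events = if (is.null(result$kataegis)) 0L
                        else nrow(result$kataegis),
    terminal_enrichment = list(
      observed = result$terminal$observed_fraction,
      expected = result$terminal$expected_fraction,
      p = result$terminal$permutation_p),
    filter = result$filter_performance)
  paths <- list(
    summary = file.path(out_dir, "summary.json"),
    per_sample = file.path(out_dir, "per_sample.tsv"),
    proportions = file.path(out_dir, "proportions.tsv"),
    exposures = file.path(out_dir, "exposures.tsv"),
    kataegis_bed = file.path(out_dir, "kataegis.bed"),
    kataegis_tsv = file.path(out_dir, "kataegis.tsv"),
    log = file.path(out_dir, "log.txt"))
  jsonlite::write_json(summary_json, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(s$per_sample, paths$per_sample, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  props <- rbind(cbind(table = "region", s$region_proportions),
                 cbind(table = "effect", s$effect_proportions))
  utils::write.table(props, paths$proportions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$contributions$contributions, paths$exposures,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kat <- if (is.null(result$kataegis)) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_mutations = integer(), mean_imd = numeric())
  } else result$kataegis
  write_kataegis(kat, bed_path = paths$kataegis_bed,
                 tsv_path = paths$kataegis_tsv)
  writeLines(result$log, paths$log)
  invisible(paths)
}
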