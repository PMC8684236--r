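# Cohort-level summaries: tumor mutational burden, class proportion
# tables, age-burden correlation and driver mutual exclusivity.

#' Tumor mutational burden
#'
#' Mutations per megabase of interrogated genome, reported to 3 decimals
#' (half-up rounding, matching how such values are conventionally
#' printed). The default denominator is the non-gap length of a human
#' whole genome in megabases; synthetic runs pass their own genome size.
#'
#' @param n_mutations Mutation count.
#' @param callable_megabases Interrogated genome size in Mb (default
#'   3088.27, the non-gap span of a human reference genome).
#' @return Mutations per megabase, rounded to 3 decimals.
#' @export
#' @examples
#' tmb(760)  # 0.246
#' tmb(39)   # 0.013
tmb <- function(n_mutations, callable_megabases = 3088.27) {
  if (callable_megabases <= 0) stop("callable_megabases must be positive")
  round_half_up(n_mutations / callable_megabases, 3)
}

#' Class proportion table
#'
#' Counts and percentages over an explicit denominator, percentages
#' half-up rounded to 2 decimals.
#'
#' @param counts Named numeric vector of per-class counts.
#' @param denominator Total to divide by (default `sum(counts)`).
#' @return data.frame with `class`, `count`, `percent` plus the
#'   denominator as an attribute.
#' @export
#' @examples
#' class_proportions(c(missense = 164, silent = 62, nonsense = 9,
#'                     indel = 10), denominator = 243)
class_proportions <- function(counts, denominator = sum(counts)) {
  if (length(counts) == 0) {
    out <- data.frame(class = character(), count = numeric(),
                      percent = numeric())
    attr(out, "denominator") <- denominator
    return(out)
  }
  if (denominator <= 0) stop("denominator must be positive")
  out <- data.frame(class = names(counts),
                    count = as.numeric(counts),
                    percent = round_half_up(100 * as.numeric(counts) /
                                              denominator, 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "denominator") <- denominator
  out
}

#' Pearson correlation between age and mutation burden
#'
#' Standard Pearson r with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param age Numeric vector of ages.
#' @param counts Numeric vector of per-sample mutation counts (same
#'   order).
#' @return List of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_age_correlation <- function(age, counts) {
  if (length(age) != length(counts)) stop("age and counts lengths differ")
  if (length(age) < 3) stop("need at least 3 samples")
  if (stats::var(age) == 0 || stats::var(counts) == 0) {
    stop("undefined result: zero variance in age or counts")
  }
  ct <- stats::cor.test(age, counts, method = "pearson",
                        alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(age)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.4g (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Two-sided Fisher exact p-value by hypergeometric enumeration
#'
#' Enumerates all 2x2 tables with the observed margins and sums the
#' probabilities of those no more likely than the observed table
#' (two-sided, no continuity tricks).
#'
#' @param tab 2x2 integer matrix.
#' @return The exact two-sided p-value.
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  a_range <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(a_range, m, n, k)
  p_obs <- stats::dhyper(a_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Driver mutual exclusivity across histological subtypes
#'
#' Builds the subtype-by-driver-mutant 2x2 table for each driver, reports
#' per-subtype driver percentages (2-decimal, half-up) and the exact
#' two-sided Fisher p for association between subtype and driver status.
#' Samples carrying both drivers are reported, never suppressed:
#' exclusivity is a finding, not an assumption.
#'
#' @param genotypes data.frame with columns `sample_id`, `subtype` (two
#'   levels, e.g. ACP/PCP) and one logical column per driver (e.g.
#'   `exon3_driver`, `v600e_driver`).
#' @param drivers Character vector naming the driver columns.
#' @return List of class `exclusivity_result`: per-driver list with the
#'   2x2 `table`, `percent_by_subtype` and `fisher_p`; plus
#'   `n_both_drivers`.
#' @export
driver_exclusivity <- function(genotypes,
                               drivers = c("exon3_driver", "v600e_driver")) {
  stopifnot(all(c("sample_id", "subtype") %in% names(genotypes)))
  stopifnot(all(drivers %in% names(genotypes)))
  subtypes <- sort(unique(genotypes$subtype))
  if (length(subtypes) != 2) stop("exactly two subtypes expected")
  res <- list()
  for (d in drivers) {
    flag <- as.logical(genotypes[[d]])
    if (anyNA(flag)) stop("driver flags must be TRUE/FALSE for all samples")
    tab <- matrix(0L, 2, 2,
                  dimnames = list(subtype = subtypes,
                                  driver = c("mutant", "wildtype")))
    for (s in subtypes) {
      k <- genotypes$subtype == s
      tab[s, "mutant"] <- sum(flag & k)
      tab[s, "wildtype"] <- sum(!flag & k)
    }
    pct <- round_half_up(100 * tab[, "mutant"] / rowSums(tab), 2)
    res[[d]] <- list(table = tab, percent_by_subtype = pct,
                     fisher_p = fisher_exact_p(tab))
  }
  both <- rowSums(vapply(drivers, function(d) as.logical(genotypes[[d]]),
                         logical(nrow(genotypes)))) == length(drivers)
  structure(c(res, list(n_both_drivers = sum(both))),
            class = "exclusivity_result")
}

#' @export
print.exclusivity_result <- function(x, ...) {
  for (d in setdiff(names(x), "n_both_drivers")) {
    cat(d, ": ", paste(sprintf("%s %.2f%%", names(x[[d]]$percent_by_subtype),
                               x[[d]]$percent_by_subtype), collapse = ", "),
        sprintf(" (Fisher p = %.3g)\n", x[[d]]$fisher_p), sep = "")
  }
  if (x$n_both_drivers > 0) {
    cat("samples carrying both drivers:", x$n_both_drivers, "\n")
  }
  invisible(x)
}

#' Cohort summary from an annotated final call set
#'
#' Per-sample SNV/InDel counts and TMB, region and effect proportion
#' tables, driver genotype flags.
#'
#' @param annotated data.frame of final retained variants with annotation
#'   columns (`sample_id`, `type`, `region_class`, `effect_class`,
#'   `gene`).
#' @param samples Sample metadata data.frame (`sample_id`, `age`, `sex`,
#'   `subtype`).
#' @param genome_mb Interrogated genome size in megabases.
#' @param driver_defs Named list of driver definitions; each element has a
#'   `region` (data.frame with `chrom`, `start`, `end`) any non-silent
#'   coding variant must overlap, and optionally a `protein_change` the
#'   variant must match exactly (e.g. a V600E-like hotspot).
#' @return List of class `cohort_summary`.
#' @export
summarize_cohort <- function(annotated, samples, genome_mb,
                             driver_defs = NULL) {
  per_sample <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    v <- annotated[annotated$sample_id == sid, , drop = FALSE]
    data.frame(sample_id = sid,
               n_snv = sum(v$type == "SNV"),
               n_indel = sum(v$type != "SNV"),
               tmb_snv = tmb(sum(v$type == "SNV"), genome_mb),
               tmb_indel = tmb(sum(v$type != "SNV"), genome_mb))
  }))
  per_sample <- merge(samples, per_sample, by = "sample_id", sort = FALSE)

  region_counts <- table(factor(annotated$region_class,
                                levels = c("exonic", "intronic",
                                           "intergenic")))
  region_tab <- class_proportions(c(region_counts))

  coding <- annotated[annotated$region_class == "exonic", , drop = FALSE]
  eff <- ifelse(coding$type == "SNV", coding$effect_class, "indel")
  effect_counts <- table(factor(eff, levels = c("missense", "silent",
                                                "nonsense", "indel")))
  effect_tab <- class_proportions(c(effect_counts))

  genotypes <- samples[, c("sample_id", "subtype")]
  for (d in names(driver_defs)) {
    def <- driver_defs[[d]]
    hit <- annotated$chrom == def$region$chrom &
      annotated$pos + nchar(annotated$ref) - 1L >= def$region$start &
      annotated$pos <= def$region$end &
      !(annotated$effect_class %in% c("none", "silent"))
    if (!is.null(def$protein_change)) {
      hit <- hit & !is.na(annotated$protein_change) &
        annotated$protein_change == def$protein_change
    }
    genotypes[[d]] <- vapply(samples$sample_id, function(sid) {
      any(hit & annotated$sample_id == sid)
    }, logical(1), USE.NAMES = FALSE)
  }

  structure(list(per_sample = per_sample,
                 mean_tmb_snv = tmb(mean(per_sample$n_snv), genome_mb),
                 mean_tmb_indel = tmb(mean(per_sample$n_indel), genome_mb),
                 region_proportions = region_tab,
                 effect_proportions = effect_tab,
                 coding_fraction = class_proportions(
                   c(coding = nrow(coding)), denominator = max(1, nrow(annotated))),
                 genotypes = genotypes,
                 genome_mb = genome_mb),
            class = "cohort_summary")
}
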