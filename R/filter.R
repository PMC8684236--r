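# Consensus and threshold filtering of multi-caller somatic calls.
#
# Rules (defaults follow the strict reading of the published criteria):
#   VAF            reported variant allele fraction >= 0.10
#   BQ             mean base quality >= 20
#   DEPTH_NORMAL   SNVs: normal depth strictly > 14
#   DEPTH_TUMOR    SNVs: tumor depth strictly > 8
#   INDEL_DEPTH    InDels: tumor depth strictly > 10
#   INDEL_P        InDels called by caller C: p-value <= 0.001
#   PON            (chrom, pos, alt) not in the panel of normals
#   MASK           footprint does not overlap the low-complexity mask
#   CALLER_CONSENSUS  SNVs: caller A called it with PASS;
#                     InDels: both caller B and caller C called it
# All failures are enumerated, never short-circuited.

#' Default filter thresholds
#'
#' @return Named list of the threshold knobs used by
#'   [apply_threshold_filters()], all overridable.
#' @export
filter_thresholds <- function(min_vaf = 0.10, min_bq = 20,
                              min_normal_depth = 14, min_tumor_depth = 8,
                              min_indel_depth = 10, max_indel_p = 0.001) {
  list(min_vaf = min_vaf, min_bq = min_bq,
       min_normal_depth = min_normal_depth,
       min_tumor_depth = min_tumor_depth,
       min_indel_depth = min_indel_depth, max_indel_p = max_indel_p)
}

#' Build a panel of normals from normal call files
#'
#' A site (chrom, pos, alt) enters the panel when it is observed in at
#' least `min_supporting_normals` distinct normal samples. The default of 1
#' is the conservative choice: any observation in any normal removes the
#' site from somatic consideration.
#'
#' @param normal_call_files Character vector of normal VCF paths, or a
#'   data.frame of normal calls with `normal_id`, `chrom`, `pos`, `ref`,
#'   `alt` columns.
#' @param min_supporting_normals Minimum number of distinct normals
#'   supporting a site.
#' @return A `panel_of_normals` object (list with `sites` data.frame and
#'   `n_normals`).
#' @export
build_normal_panel <- function(normal_call_files, min_supporting_normals = 1) {
  if (is.data.frame(normal_call_files)) {
    df <- normal_call_files
    stopifnot(all(c("normal_id", "chrom", "pos", "alt") %in% names(df)))
  } else {
    if (length(normal_call_files) < 1) stop("need at least one normal file")
    dfs <- lapply(normal_call_files, function(p) {
      x <- read_caller_vcf(p)
      if (nrow(x) == 0) return(NULL)
      data.frame(normal_id = if (is.na(x$sample_id[1])) p else x$sample_id[1],
                 chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt)
    })
    df <- do.call(rbind, dfs)
  }
  if (is.null(df) || nrow(df) == 0) {
    return(structure(list(sites = data.frame(chrom = character(),
                                             pos = integer(),
                                             alt = character(),
                                             n_support = integer()),
                          n_normals = length(unique(character(0)))),
                     class = "panel_of_normals"))
  }
  if (!is.null(df$ref)) {
    refs <- tapply(df$ref, paste0(df$chrom, ":", df$pos),
                   function(r) length(unique(r)))
    if (any(refs > 1)) {
      bad <- names(refs)[refs > 1][1]
      stop("input error: contradictory reference alleles at site ", bad)
    }
  }
  key <- paste0(df$chrom, ":", df$pos, ":", df$alt)
  support <- tapply(df$normal_id, key, function(x) length(unique(x)))
  keep <- names(support)[support >= min_supporting_normals]
  parts <- do.call(rbind, strsplit(keep, ":", fixed = TRUE))
  sites <- if (length(keep)) {
    data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
               alt = parts[, 3],
               n_support = as.integer(support[keep]))
  } else {
    data.frame(chrom = character(), pos = integer(), alt = character(),
               n_support = integer())
  }
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 n_normals = length(unique(df$normal_id))),
            class = "panel_of_normals")
}

#' @export
print.panel_of_normals <- function(x, ...) {
  cat(sprintf("panel_of_normals: %d sites from %d normals\n",
              nrow(x$sites), x$n_normals))
  invisible(x)
}

#' Serialize a panel of normals to a sites-only VCF
#'
#' @param panel A `panel_of_normals`.
#' @param path Output path.
#' @export
write_panel_vcf <- function(panel, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Supporting normals\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\tN\t%s\t.\t.\tNS=%d",
                  panel$sites$chrom, panel$sites$pos, panel$sites$alt,
                  panel$sites$n_support)
  writeLines(c(header, body), path)
  invisible(path)
}

.panel_keys <- function(panel) {
  if (is.null(panel) || nrow(panel$sites) == 0) return(character(0))
  paste0(panel$sites$chrom, ":", panel$sites$pos, ":", panel$sites$alt)
}

# Footprint-overlap test against the mask (1-based closed data.frame).
.in_mask <- function(chrom, start, end, mask) {
  out <- logical(length(chrom))
  if (is.null(mask) || nrow(mask) == 0) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  m <- df_to_granges(mask)
  IRanges::overlapsAny(q, m)
}

#' Apply threshold filters to raw calls
#'
#' Evaluates every rule on every record (failures are enumerated, not
#' short-circuited) and returns the filter decision. An SNV carrying an
#' InDel p-value is a schema violation and raises an error.
#'
#' @param calls data.frame of raw calls (columns `chrom`, `pos`, `ref`,
#'   `alt`, `type`, `callers`, `normal_depth`, `tumor_depth`, `vaf`,
#'   `mean_base_quality`, `indel_pvalue`).
#' @param panel A `panel_of_normals` (or NULL).
#' @param mask Low-complexity intervals as a data.frame (`chrom`, `start`,
#'   `end`, 1-based closed) or NULL. InDel footprints use the full REF
#'   interval.
#' @param thresholds A [filter_thresholds()] list.
#' @return data.frame with one row per call: `retained` (logical) and
#'   `failed_rules` (comma-separated rule ids, "" when retained).
#' @export
apply_threshold_filters <- function(calls, panel = NULL, mask = NULL,
                                    thresholds = filter_thresholds()) {
  n <- nrow(calls)
  if (n == 0) {
    return(data.frame(retained = logical(0), failed_rules = character(0)))
  }
  is_snv <- calls$type == "SNV"
  if (any(is_snv & !is.na(calls$indel_pvalue))) {
    stop("input error: SNV record carries an InDel p-value (schema violation)")
  }
  th <- thresholds
  fails <- matrix(FALSE, n, 8,
                  dimnames = list(NULL, c("VAF", "BQ", "DEPTH_NORMAL",
                                          "DEPTH_TUMOR", "INDEL_DEPTH",
                                          "INDEL_P", "PON", "MASK")))
  fails[, "VAF"] <- calls$vaf < th$min_vaf
  fails[, "BQ"] <- calls$mean_base_quality < th$min_bq
  fails[, "DEPTH_NORMAL"] <- is_snv & !(calls$normal_depth > th$min_normal_depth)
  fails[, "DEPTH_TUMOR"] <- is_snv & !(calls$tumor_depth > th$min_tumor_depth)
  fails[, "INDEL_DEPTH"] <- !is_snv & !(calls$tumor_depth > th$min_indel_depth)
  called_c <- grepl("C", calls$callers)
  fails[, "INDEL_P"] <- !is_snv & called_c &
    !is.na(calls$indel_pvalue) & calls$indel_pvalue > th$max_indel_p
  keys <- paste0(calls$chrom, ":", calls$pos, ":", calls$alt)
  fails[, "PON"] <- keys %in% .panel_keys(panel)
  fails[, "MASK"] <- .in_mask(calls$chrom, calls$pos,
                              calls$pos + nchar(calls$ref) - 1L, mask)
  failed <- apply(fails, 1, function(r) paste(colnames(fails)[r], collapse = ","))
  data.frame(retained = !apply(fails, 1, any), failed_rules = failed,
             stringsAsFactors = FALSE)
}

#' Merge per-caller call sets for one tumor into unified raw calls
#'
#' Records are keyed by (chrom, pos, ref, alt); the `callers` field is the
#' union of provenance and evidence fields are taken from caller A when
#' present, else B, else C (the source is recorded). Caller C's p-value is
#' carried onto the merged record whenever C called the variant.
#'
#' @param per_caller_calls data.frame of per-caller records as returned by
#'   [read_caller_vcf()] or [emulate_caller_outputs()] (`caller` in
#'   `A`/`B`/`C`), all from one tumor/normal pair.
#' @return data.frame of merged raw calls with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `type`, `callers`, `passed_primary`,
#'   `normal_depth`, `tumor_depth`, `tumor_alt_reads`, `vaf`,
#'   `mean_base_quality`, `indel_pvalue`, `evidence_source`.
#' @export
consensus_merge <- function(per_caller_calls) {
  df <- per_caller_calls
  if (nrow(df) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      type = character(), callers = character(),
                      passed_primary = logical(), normal_depth = integer(),
                      tumor_depth = integer(), tumor_alt_reads = integer(),
                      vaf = numeric(), mean_base_quality = numeric(),
                      indel_pvalue = numeric(), evidence_source = character()))
  }
  if (length(unique(df$sample_id)) > 1) {
    stop("consensus_merge expects records from a single tumor/normal pair")
  }
  if (!"passed_primary" %in% names(df)) {
    df$passed_primary <- !is.null(df$filter) & df$filter == "PASS"
  }
  pos_key <- paste0(df$chrom, ":", df$pos, ":", df$alt)
  full_key <- paste0(pos_key, ":", df$ref)
  # callers reporting the same (chrom, pos, alt) must agree on REF
  by_site <- split(df$ref, pos_key)
  if (any(vapply(by_site, function(r) length(unique(r)), 0L) > 1)) {
    bad <- names(by_site)[vapply(by_site, function(r) length(unique(r)), 0L) > 1][1]
    stop("input error: conflicting reference alleles at ", bad)
  }
  rows <- lapply(split(seq_len(nrow(df)), full_key), function(i) {
    sub <- df[i, , drop = FALSE]
    ord <- order(match(sub$caller, c("A", "B", "C")))
    sub <- sub[ord, , drop = FALSE]
    ev <- sub[1, ]
    vp <- if (any(sub$caller == "C")) sub$VP[sub$caller == "C"][1] else NA_real_
    data.frame(sample_id = ev$sample_id, chrom = ev$chrom, pos = ev$pos,
               ref = ev$ref, alt = ev$alt, type = ev$type,
               callers = paste(sort(unique(sub$caller)), collapse = ","),
               passed_primary = any(sub$caller == "A" & sub$passed_primary),
               normal_depth = ev$NDP, tumor_depth = ev$TDP,
               tumor_alt_reads = ev$TAD, vaf = ev$VAF,
               mean_base_quality = ev$MBQ, indel_pvalue = vp,
               evidence_source = ev$caller, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Filter a merged cohort to the final somatic set
#'
#' Applies the caller-consensus rule (SNVs: caller A with PASS; InDels:
#' callers B and C) on top of the threshold filters. Returns all records
#' with their decisions; the final set is `retained == TRUE`.
#'
#' @param merged data.frame of merged raw calls (possibly several samples;
#'   output of [consensus_merge()] per sample, row-bound).
#' @param panel A `panel_of_normals` or NULL.
#' @param mask Mask intervals data.frame or NULL.
#' @param thresholds A [filter_thresholds()] list.
#' @return The input data.frame with `retained` and `failed_rules`
#'   appended (rule `CALLER_CONSENSUS` included).
#' @export
filter_cohort <- function(merged, panel = NULL, mask = NULL,
                          thresholds = filter_thresholds()) {
  if (nrow(merged) == 0) {
    merged$retained <- logical(0)
    merged$failed_rules <- character(0)
    return(merged)
  }
  dec <- apply_threshold_filters(merged, panel, mask, thresholds)
  is_snv <- merged$type == "SNV"
  has <- function(cl) grepl(cl, merged$callers)
  consensus_ok <- ifelse(is_snv,
                         has("A") & merged$passed_primary,
                         has("B") & has("C"))
  dec$failed_rules <- ifelse(consensus_ok, dec$failed_rules,
                             ifelse(dec$failed_rules == "",
                                    "CALLER_CONSENSUS",
                                    paste0(dec$failed_rules,
                                           ",CALLER_CONSENSUS")))
  merged$retained <- dec$retained & consensus_ok
  merged$failed_rules <- dec$failed_rules
  merged
}

#' Write the final somatic set of one sample as VCF
#'
#' @param final data.frame of retained calls for one sample.
#' @param genome `synthetic_genome` (for contig headers) or NULL.
#' @param path Output path.
#' @export
write_somatic_vcf <- function(final, genome, path) {
  header <- if (!is.null(genome)) {
    .vcf_header(genome, sample = final$sample_id[1])
  } else {
    c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  }
  df <- final[order(final$chrom, final$pos), ]
  info <- sprintf("NDP=%d;TDP=%d;TAD=%d;VAF=%s;MBQ=%d",
                  df$normal_depth, df$tumor_depth, df$tumor_alt_reads,
                  formatC(df$vaf, format = "g"), df$mean_base_quality)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  df$chrom, df$pos, df$ref, df$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}
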