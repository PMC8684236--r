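# Emulated multi-caller somatic call sets. Three callers are modelled on
# the common WGS tumor-normal trio: caller A (Mutect2-like) emits SNVs with
# PASS flags, caller B (Strelka2-like) emits SNVs and InDels, caller C
# (Varscan2-like) emits InDels with a p-value. Evidence (depths, alt reads,
# VAF, mean base quality) is drawn once per true variant and shared across
# callers; false positives are caller-specific and injected at recurrent
# artifact sites, inside the low-complexity mask, and at low-VAF positions.
#
# True variants are drawn from the detectable region of threshold space
# (depths, VAF and base quality clear the filter thresholds), so that the
# caller false-negative rate is the single source of missed true calls and
# a zero-noise configuration round-trips exactly.

CALLERS <- c(A = "A_mutect2like", B = "B_strelka2like", C = "C_varscan2like")

.rtrunc_pois <- function(n, lambda, min) {
  x <- stats::rpois(n, lambda)
  pmax(x, min)
}

# Evidence for true somatic variants: guaranteed to clear the default
# thresholds (VAF >= 0.12, BQ >= 22, normal depth >= 16, tumor depth >= 15).
.true_evidence <- function(n, config) {
  tdp <- .rtrunc_pois(n, config$depth_mean, 15L)
  ndp <- .rtrunc_pois(n, config$depth_mean, 16L)
  tv <- stats::runif(n, config$vaf_range[1], config$vaf_range[2])
  tad <- stats::rbinom(n, tdp, tv)
  floor_ad <- ceiling(0.12 * tdp)
  tad <- pmax(tad, floor_ad)
  mbq <- pmin(40L, pmax(22L, as.integer(round(stats::rnorm(n, 32, 4)))))
  data.frame(NDP = ndp, TDP = tdp, TAD = tad,
             VAF = round(tad / tdp, 4), MBQ = mbq)
}

# Evidence for false-positive records; vaf supplied per FP class.
.fp_evidence <- function(n, config, vaf) {
  tdp <- .rtrunc_pois(n, config$depth_mean, 8L)
  ndp <- .rtrunc_pois(n, config$depth_mean, 8L)
  tad <- pmax(1L, as.integer(round(vaf * tdp)))
  mbq <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(n, 28, 6)))))
  data.frame(NDP = ndp, TDP = tdp, TAD = tad,
             VAF = round(tad / tdp, 4), MBQ = mbq)
}

# Uniform random non-gap positions with their reference base, avoiding a
# set of excluded positions (chrom:pos keys).
.random_sites <- function(genome, n, exclude_keys = character(),
                          within_mask = FALSE) {
  seqs <- genome$chromosomes
  lens <- Biostrings::width(seqs)
  out <- list(); got <- 0L; guard <- 0L
  while (got < n && guard < 50L) {
    guard <- guard + 1L
    need <- n - got
    if (within_mask) {
      m <- genome$mask
      if (nrow(m) == 0) break
      w <- m$end - m$start + 1L
      ridx <- sample.int(nrow(m), need, replace = TRUE, prob = w)
      pos <- m$start[ridx] +
        as.integer(floor(stats::runif(need) * w[ridx]))
      chrom <- m$chrom[ridx]
    } else {
      cidx <- sample.int(length(lens), need, replace = TRUE, prob = lens)
      chrom <- names(seqs)[cidx]
      pos <- as.integer(floor(stats::runif(need) * lens[cidx])) + 1L
    }
    ref <- character(need)
    for (cn in unique(chrom)) {
      k <- which(chrom == cn)
      ref[k] <- vapply(pos[k], function(p) {
        as.character(Biostrings::extractAt(seqs[[cn]],
                                           IRanges::IRanges(p, p)))
      }, "")
    }
    keep <- ref %in% BASES & !(paste0(chrom, ":", pos) %in% exclude_keys)
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(chrom = chrom[keep],
                                            pos = pos[keep],
                                            ref = ref[keep])
      got <- got + sum(keep)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(data.frame(chrom = character(), pos = integer(),
                                     ref = character()))
  utils::head(df, n)
}

.random_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(BASES, r), 1), "",
         USE.NAMES = FALSE)
}

#' Emulate per-caller tumor call sets and the normal panel
#'
#' Produces three call sets per tumor and one call set per matched normal,
#' written as single-sample VCF v4.2 files with caller evidence in INFO
#' keys (`NDP`, `TDP`, `TAD`, `VAF`, `MBQ`, and `VP` for caller C's
#' InDels). Artifact background sites are shared across at least two
#' normal-panel files by construction.
#'
#' @param truth A `truth_set` from [plant_somatic_mutations()].
#' @param genome The matching `synthetic_genome`.
#' @param dir Output directory for VCFs (`calls/` and `normals/`
#'   subdirectories); `NULL` to skip writing.
#' @return A `caller_emulation` list: `calls` (data.frame of all tumor
#'   records with caller, evidence and an `is_fp` diagnostic flag),
#'   `normal_calls` (data.frame), `artifact_sites` (data.frame of the
#'   planted recurrent background sites) and `paths` (when written).
#' @export
emulate_caller_outputs <- function(truth, genome, dir = NULL) {
  config <- truth$config
  set.seed(child_seed(config$seed, "callers"))
  tv <- truth$variants
  truth_keys <- unique(paste0(tv$chrom, ":", tv$pos))
  genome_mb <- sum(Biostrings::width(genome$chromosomes)) / 1e6

  # shared artifact background: recurrent across normals
  n_art <- round(config$artifact_site_rate * genome_mb)
  art <- .random_sites(genome, n_art, exclude_keys = truth_keys)
  if (nrow(art) > 0) art$alt <- .random_alt(art$ref)

  ids <- truth$samples$sample_id
  n_norm <- length(ids)
  normal_rows <- list()
  if (nrow(art) > 0) {
    for (i in seq_len(nrow(art))) {
      k <- 2L + stats::rbinom(1, n_norm - 2L, 0.15)
      carriers <- ids[sample.int(n_norm, k)]
      ev <- .fp_evidence(k, config, stats::runif(k, 0.02, 0.08))
      normal_rows[[i]] <- data.frame(
        normal_id = carriers, chrom = art$chrom[i], pos = art$pos[i],
        ref = art$ref[i], alt = art$alt[i], ev)
    }
  }
  # a little private per-normal noise (never entering a >=2-support panel)
  for (sid in ids) {
    pv <- .random_sites(genome, 10L,
                        exclude_keys = c(truth_keys,
                                         paste0(art$chrom, ":", art$pos)))
    if (nrow(pv) == 0) next
    pv$alt <- .random_alt(pv$ref)
    ev <- .fp_evidence(nrow(pv), config, stats::runif(nrow(pv), 0.02, 0.08))
    normal_rows[[length(normal_rows) + 1L]] <-
      data.frame(normal_id = sid, chrom = pv$chrom, pos = pv$pos,
                 ref = pv$ref, alt = pv$alt, ev)
  }
  normal_calls <- do.call(rbind, normal_rows)

  fn <- config$caller_error$fn
  fp_lambda <- config$caller_error$fp
  call_rows <- list()
  for (sid in ids) {
    mine <- tv[tv$sample_id == sid, , drop = FALSE]
    if (nrow(mine) > 0) {
      ev <- .true_evidence(nrow(mine), config)
      vp <- ifelse(mine$type == "SNV", NA_real_,
                   signif(stats::runif(nrow(mine), 1e-6, 5e-4), 3))
      base <- data.frame(sample_id = sid, chrom = mine$chrom, pos = mine$pos,
                         ref = mine$ref, alt = mine$alt, type = mine$type,
                         ev, VP = vp, is_fp = FALSE)
      for (cl in names(CALLERS)) {
        emit <- switch(cl, A = base$type == "SNV",
                       B = rep(TRUE, nrow(base)),
                       C = base$type != "SNV")
        keep <- emit & stats::runif(nrow(base)) >= fn[[cl]]
        if (!any(keep)) next
        rec <- base[keep, , drop = FALSE]
        rec$caller <- cl
        rec$filter <- if (cl == "A") "PASS" else "."
        if (cl != "C") rec$VP <- NA_real_
        call_rows[[length(call_rows) + 1L]] <- rec
      }
    }
    # caller-specific false positives
    for (cl in names(CALLERS)) {
      n_fp <- stats::rpois(1, fp_lambda[[cl]])
      if (n_fp == 0) next
      n_art_fp <- round(0.4 * n_fp)
      n_mask_fp <- round(0.3 * n_fp)
      n_lv_fp <- n_fp - n_art_fp - n_mask_fp
      fps <- list()
      if (n_art_fp > 0 && nrow(art) > 0) {
        ai <- sample.int(nrow(art), min(n_art_fp, nrow(art)))
        fps$art <- data.frame(chrom = art$chrom[ai], pos = art$pos[ai],
                              ref = art$ref[ai], alt = art$alt[ai],
                              vaf = stats::runif(length(ai), 0.05, 0.20))
      }
      if (n_mask_fp > 0) {
        mk <- .random_sites(genome, n_mask_fp, exclude_keys = truth_keys,
                            within_mask = TRUE)
        if (nrow(mk) > 0) {
          mk$alt <- .random_alt(mk$ref)
          mk$vaf <- stats::runif(nrow(mk), 0.15, 0.40)
          fps$mask <- mk
        }
      }
      if (n_lv_fp > 0) {
        lv <- .random_sites(genome, n_lv_fp, exclude_keys = truth_keys)
        if (nrow(lv) > 0) {
          lv$alt <- .random_alt(lv$ref)
          lv$vaf <- stats::runif(nrow(lv), 0.02, 0.09)
          fps$lv <- lv
        }
      }
      fpdf <- do.call(rbind, lapply(fps, function(x) {
        x[, c("chrom", "pos", "ref", "alt", "vaf")]
      }))
      if (is.null(fpdf) || nrow(fpdf) == 0) next
      ev <- .fp_evidence(nrow(fpdf), config, fpdf$vaf)
      is_snv_fp <- cl != "C"
      rec <- data.frame(sample_id = sid, chrom = fpdf$chrom, pos = fpdf$pos,
                        ref = fpdf$ref, alt = fpdf$alt,
                        type = if (is_snv_fp) "SNV" else "DEL",
                        ev,
                        VP = if (cl == "C") {
                          signif(stats::runif(nrow(fpdf), 1e-6, 0.01), 3)
                        } else NA_real_,
                        is_fp = TRUE, caller = cl,
                        filter = if (cl == "A") "PASS" else ".")
      if (cl == "C") {
        # FP "deletions": extend ref by one base so type is consistent
        rec$ref <- paste0(rec$ref, "A")
        rec$alt <- substr(rec$ref, 1, 1)
      }
      call_rows[[length(call_rows) + 1L]] <- rec
    }
  }
  calls <- do.call(rbind, call_rows)
  rownames(calls) <- NULL

  paths <- NULL
  if (!is.null(dir)) {
    paths <- write_caller_vcfs(calls, normal_calls, genome, dir)
    utils::write.table(truth$samples, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(calls = calls, normal_calls = normal_calls,
                 artifact_sites = art, paths = paths),
            class = "caller_emulation")
}

.vcf_header <- function(genome, caller = NULL, sample = NULL) {
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(genome$chromosomes),
                 Biostrings::width(genome$chromosomes)),
         "##INFO=<ID=NDP,Number=1,Type=Integer,Description=\"Read depth in matched normal\">",
         "##INFO=<ID=TDP,Number=1,Type=Integer,Description=\"Read depth in tumor\">",
         "##INFO=<ID=TAD,Number=1,Type=Integer,Description=\"Alt-supporting reads in tumor\">",
         "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction in tumor\">",
         "##INFO=<ID=MBQ,Number=1,Type=Integer,Description=\"Mean base quality at locus\">",
         "##INFO=<ID=VP,Number=1,Type=Float,Description=\"InDel p-value (caller C)\">")
  if (!is.null(caller)) h <- c(h, sprintf("##caller=%s", CALLERS[[caller]]))
  if (!is.null(sample)) h <- c(h, sprintf("##sample=%s", sample))
  c(h, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

.format_info <- function(df) {
  info <- sprintf("NDP=%d;TDP=%d;TAD=%d;VAF=%s;MBQ=%d",
                  df$NDP, df$TDP, df$TAD,
                  formatC(df$VAF, format = "g"), df$MBQ)
  has_vp <- !is.na(df$VP)
  info[has_vp] <- paste0(info[has_vp],
                         sprintf(";VP=%s", formatC(df$VP[has_vp], format = "g")))
  info
}

# One VCF per tumor per caller plus one per normal.
write_caller_vcfs <- function(calls, normal_calls, genome, dir) {
  calls_dir <- file.path(dir, "calls")
  norm_dir <- file.path(dir, "normals")
  dir.create(calls_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(norm_dir, showWarnings = FALSE, recursive = TRUE)
  tumor_paths <- list()
  for (sid in unique(calls$sample_id)) {
    tumor_paths[[sid]] <- list()
    for (cl in unique(calls$caller[calls$sample_id == sid])) {
      df <- calls[calls$sample_id == sid & calls$caller == cl, ]
      df <- df[order(df$chrom, df$pos), ]
      path <- file.path(calls_dir, sprintf("%s.%s.vcf", sid, cl))
      body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                      df$chrom, df$pos, df$ref, df$alt, df$filter,
                      .format_info(df))
      writeLines(c(.vcf_header(genome, caller = cl, sample = sid), body),
                 path)
      tumor_paths[[sid]][[cl]] <- path
    }
  }
  normal_paths <- character(0)
  for (nid in unique(normal_calls$normal_id)) {
    df <- normal_calls[normal_calls$normal_id == nid, ]
    df <- df[order(df$chrom, df$pos), ]
    path <- file.path(norm_dir, sprintf("%s.normal.vcf", nid))
    df$VP <- NA_real_
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                    df$chrom, df$pos, df$ref, df$alt, .format_info(df))
    writeLines(c(.vcf_header(genome, sample = nid), body), path)
    normal_paths[nid] <- path
  }
  list(tumor = tumor_paths, normal = normal_paths)
}

#' Read an emulated caller VCF into a call data.frame
#'
#' @param path VCF path written by [emulate_caller_outputs()] (or any VCF
#'   carrying the `NDP/TDP/TAD/VAF/MBQ[/VP]` INFO keys).
#' @return data.frame with identity, evidence, `caller` (from the
#'   `##caller` header line when present) and `passed_primary` columns.
#' @export
read_caller_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  caller_line <- grep("^##caller=", meta, value = TRUE)
  caller_full <- if (length(caller_line)) sub("^##caller=", "", caller_line[1]) else NA
  caller <- if (!is.na(caller_full)) names(CALLERS)[match(caller_full, CALLERS)] else NA
  sample_line <- grep("^##sample=", meta, value = TRUE)
  sid <- if (length(sample_line)) sub("^##sample=", "", sample_line[1]) else NA
  fx <- v@fix
  if (is.null(fx) || nrow(fx) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      type = character(), NDP = integer(), TDP = integer(),
                      TAD = integer(), VAF = numeric(), MBQ = numeric(),
                      VP = numeric(), caller = character(),
                      passed_primary = logical()))
  }
  getn <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                 ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
  data.frame(sample_id = sid, chrom = fx[, "CHROM"],
             pos = as.integer(fx[, "POS"]), ref = ref, alt = alt,
             type = type,
             NDP = as.integer(getn("NDP")), TDP = as.integer(getn("TDP")),
             TAD = as.integer(getn("TAD")), VAF = getn("VAF"),
             MBQ = getn("MBQ"), VP = getn("VP"),
             caller = caller,
             passed_primary = fx[, "FILTER"] == "PASS",
             stringsAsFactors = FALSE)
}
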