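# Planting somatic truth mutations into a synthetic genome: SNVs drawn from
# a signature mixture and placed at positions whose reference trinucleotide
# matches the drawn channel (either strand), plus InDels, kataegis
# clusters, chromosome-terminal bias and subtype-specific driver events.

# Per-chromosome index of plantable positions by pyrimidine-collapsed
# context. Positions are signed: positive when the pyrimidine of the
# context sits on the plus strand, negative when it is the complement (the
# planted genomic alt must then be complemented).
.context_index <- function(genome) {
  terminal <- terminal_windows(genome, genome$config$terminal_fraction)
  idx <- list()
  for (cn in names(genome$chromosomes)) {
    s <- as.character(genome$chromosomes[[cn]])
    L <- nchar(s)
    b <- match(strsplit(s, "")[[1]], BASES)       # N -> NA
    f5 <- b[1:(L - 2L)]; c0 <- b[2:(L - 1L)]; f3 <- b[3:L]
    pos <- 2:(L - 1L)
    ok <- !is.na(f5) & !is.na(c0) & !is.na(f3)
    m <- genome$mask[genome$mask$chrom == cn, c("start", "end")]
    # driver-defining regions are reserved for planted driver events
    for (ds in genome$driver_sites) {
      if (!is.null(ds$region) && ds$region$chrom == cn) {
        m <- rbind(m, ds$region[, c("start", "end")])
      }
    }
    if (nrow(m)) {
      inmask <- logical(L)
      for (i in seq_len(nrow(m))) inmask[m$start[i]:m$end[i]] <- TRUE
      ok <- ok & !inmask[pos]
    }
    pyr <- c0 %in% c(2L, 4L)
    cf5 <- ifelse(pyr, f5, 5L - f3)
    cc <- ifelse(pyr, c0, 5L - c0)
    cf3 <- ifelse(pyr, f3, 5L - f5)
    code <- (cf5 - 1L) * 8L + (match(cc, c(2L, 4L)) - 1L) * 4L + cf3
    spos <- ifelse(pyr, pos, -pos)
    tw <- terminal[terminal$chrom == cn, ]
    in_term <- (pos >= tw$start[1] & pos <= tw$end[1]) |
      (pos >= tw$start[2] & pos <= tw$end[2])
    idx[[cn]] <- list(
      all = split(spos[ok], code[ok]),
      term = split(spos[ok & in_term], code[ok & in_term]))
  }
  idx
}

# Context code (1..32) and pyrimidine-strand alt base of each channel.
.channel_context_code <- function() {
  ch <- context_channels()
  f5 <- match(substr(ch, 1, 1), BASES)
  rr <- substr(ch, 3, 3)
  f3 <- match(substr(ch, 7, 7), BASES)
  code <- (f5 - 1L) * 8L + (match(rr, c("C", "T")) - 1L) * 4L + f3
  list(code = code, alt = substr(ch, 5, 5))
}

# Sample n signed positions for one context code, pooling chromosomes
# (restricted to terminal windows when terminal = TRUE).
.sample_context_positions <- function(idx, code, n, terminal = FALSE) {
  key <- as.character(code)
  pools <- lapply(idx, function(ci) {
    p <- (if (terminal) ci$term else ci$all)[[key]]
    if (is.null(p)) integer(0) else p
  })
  sizes <- vapply(pools, length, 0L)
  if (sum(sizes) == 0) return(NULL)
  chrom_pick <- sample(rep(names(pools), sizes), n, replace = TRUE)
  out_chrom <- character(n); out_pos <- integer(n)
  for (cn in unique(chrom_pick)) {
    k <- which(chrom_pick == cn)
    out_chrom[k] <- cn
    pool <- pools[[cn]]
    out_pos[k] <- pool[sample.int(length(pool), length(k), replace = TRUE)]
  }
  data.frame(chrom = out_chrom, spos = out_pos)
}

.sample_ids <- function(config) {
  c(sprintf("ACP%02d", seq_len(config$n_acp)),
    sprintf("PCP%02d", seq_len(config$n_pcp)))
}

.default_ages <- function(config) {
  n_a <- config$n_acp; n_p <- config$n_pcp
  # ACP is bimodal (pediatric and adult peaks), PCP essentially adult
  n_kid <- round(n_a / 2)
  acp <- c(sample(5:15, n_kid, replace = TRUE),
           sample(35:65, n_a - n_kid, replace = TRUE))
  pcp <- sample(30:70, n_p, replace = TRUE)
  as.integer(c(acp, pcp))
}

#' Plant somatic truth mutations into a synthetic genome
#'
#' Per sample, the SNV count is Poisson around an age-scaled mean; each
#' SNV's 96-context channel is drawn from the sample's signature-mixture
#' profile and the variant placed at a uniformly chosen unmasked, non-gap
#' position whose reference trinucleotide matches the channel on either
#' strand. A configured fraction of SNVs is forced into chromosome-terminal
#' windows; configured kataegis clusters are planted as tight runs; InDels
#' are placed uniformly; driver events are assigned mutually exclusively
#' (exon-3-like events to ACP-like samples, V600E-like to PCP-like).
#'
#' @param genome A `synthetic_genome` from [generate_reference()].
#' @param config The [cohort_config()] used to generate it.
#' @return A `truth_set` object: list with `variants` (data.frame of
#'   planted variants with channel, kataegis flag, driver label and true
#'   region/effect annotation) and `samples` (metadata data.frame).
#' @export
plant_somatic_mutations <- function(genome, config) {
  set.seed(child_seed(config$seed, "plant"))
  sigs <- synthetic_signature_matrix()
  w <- config$signature_mixture
  profile <- mixture_profile(sigs, w)
  idx <- .context_index(genome)
  chinfo <- .channel_context_code()
  seqs <- genome$chromosomes

  ids <- .sample_ids(config)
  subtype <- rep(c("ACP", "PCP"), c(config$n_acp, config$n_pcp))
  ages <- if (is.null(config$ages)) .default_ages(config) else as.integer(config$ages)
  sex <- rep_len(c("F", "M"), length(ids))
  samples <- data.frame(sample_id = ids, age = ages, sex = sex,
                        subtype = subtype, stringsAsFactors = FALSE)

  # age-scaled expected burden with lognormal per-sample overdispersion
  # (somatic burdens are overdispersed relative to Poisson in real cohorts)
  disp <- if (is.null(config$burden_dispersion)) 0.3 else config$burden_dispersion
  lam <- config$mean_snv *
    ((1 - config$age_effect) + config$age_effect * ages / mean(ages)) *
    exp(stats::rnorm(length(ages), 0, disp) - disp^2 / 2)

  # driver carriers: deterministic counts, seeded choice of carriers
  n_drv_a <- round(config$driver_rate_acp * config$n_acp)
  n_drv_p <- round(config$driver_rate_pcp * config$n_pcp)
  acp_idx <- which(subtype == "ACP")
  pcp_idx <- which(subtype == "PCP")
  drv_a <- sort(sample(acp_idx, n_drv_a))
  drv_p <- sort(sample(pcp_idx, n_drv_p))
  combo_sample <- if (n_drv_a > 0) drv_a[length(drv_a)] else NA_integer_

  ks <- config$kataegis_spec
  if (!is.null(ks) && nrow(ks) > 0 && is.null(ks$sample)) {
    ks$sample <- ids[((seq_len(nrow(ks)) - 1L) %% length(ids)) + 1L]
  }

  all_rows <- list()
  for (si in seq_along(ids)) {
    sid <- ids[si]
    rows <- list()

    # --- driver events -------------------------------------------------
    if (si %in% drv_a) {
      ds <- genome$driver_sites$exon3
      tx <- genome$model$transcripts[[ds$tx_id]]
      if (identical(si, combo_sample)) {
        # transversion at codon 43 (GCT -> GGT, p.A43G) plus 39-nt
        # in-frame deletion of codons 44-56
        p1 <- cds_to_genome(tx, 128L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, chrom = ds$chrom, pos = p1, ref = "C", alt = "G",
          type = "SNV", kataegis = FALSE, driver = "exon3_driver")
        anchor <- cds_to_genome(tx, 129L)
        refdel <- as.character(Biostrings::extractAt(
          seqs[[ds$chrom]], IRanges::IRanges(anchor, anchor + 39L)))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, chrom = ds$chrom, pos = anchor, ref = refdel,
          alt = substr(refdel, 1, 1), type = "DEL",
          kataegis = FALSE, driver = "exon3_driver")
      } else {
        # T41A-like transition at codon 41 position 1 (ACC -> GCC)
        p1 <- cds_to_genome(tx, 121L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, chrom = ds$chrom, pos = p1, ref = "A", alt = "G",
          type = "SNV", kataegis = FALSE, driver = "exon3_driver")
      }
    }
    if (si %in% drv_p) {
      ds <- genome$driver_sites$v600e
      tx <- genome$model$transcripts[[ds$tx_id]]
      p1 <- cds_to_genome(tx, 1799L)   # GTG -> GAG, p.V600E
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = ds$chrom, pos = p1, ref = "T", alt = "A",
        type = "SNV", kataegis = FALSE, driver = "v600e_driver")
    }

    # --- background SNVs ------------------------------------------------
    n_snv <- stats::rpois(1, lam[si])
    if (n_snv > 0) {
      channels <- sample.int(96, n_snv, replace = TRUE, prob = profile)
      n_term <- round(config$terminal_bias * n_snv)
      is_term <- c(rep(TRUE, n_term), rep(FALSE, n_snv - n_term))
      for (term in unique(is_term)) {
        sub <- channels[is_term == term]
        tab <- table(sub)
        for (chname in names(tab)) {
          chn <- as.integer(chname)
          got <- .sample_context_positions(idx, chinfo$code[chn],
                                           as.integer(tab[[chname]]),
                                           terminal = term)
          if (is.null(got)) {
            stop("generation error: no genomic position available for ",
                 "channel ", context_channels()[chn])
          }
          plus <- got$spos > 0
          pos <- abs(got$spos)
          alt_p <- chinfo$alt[chn]
          alt <- ifelse(plus, alt_p, .complement(alt_p))
          ref <- ifelse(plus, substr(context_channels()[chn], 3, 3),
                        .complement(substr(context_channels()[chn], 3, 3)))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, chrom = got$chrom, pos = pos, ref = ref,
            alt = alt, type = "SNV", kataegis = FALSE, driver = "none")
        }
      }
    }

    # --- kataegis clusters ---------------------------------------------
    if (!is.null(ks) && nrow(ks) > 0) {
      mine <- ks[ks$sample == sid, , drop = FALSE]
      for (ci in seq_len(nrow(mine))) {
        k <- mine[ci, ]
        half <- k$span %/% 2L
        lo <- k$center - half; hi <- k$center + half
        pool_all <- idx[[k$chrom]]$all
        cand <- abs(unlist(pool_all, use.names = FALSE))
        sgn <- sign(unlist(pool_all, use.names = FALSE))
        codes <- rep(as.integer(names(pool_all)),
                     vapply(pool_all, length, 0L))
        inwin <- cand >= lo & cand <= hi
        if (sum(inwin) < k$n) {
          stop("generation error: kataegis window ", k$chrom, ":", lo, "-",
               hi, " has too few plantable positions")
        }
        inwin_idx <- which(inwin)
        pick <- inwin_idx[sample.int(length(inwin_idx), k$n)]
        for (j in pick) {
          code <- codes[j]
          # conditional channel draw given the context at this position
          chans <- which(chinfo$code == code)
          pr <- profile[chans]
          chn <- chans[sample.int(3, 1, prob = pr / sum(pr))]
          plus <- sgn[j] > 0
          alt_p <- chinfo$alt[chn]
          ref_p <- substr(context_channels()[chn], 3, 3)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, chrom = k$chrom, pos = cand[j],
            ref = if (plus) ref_p else .complement(ref_p),
            alt = if (plus) alt_p else .complement(alt_p),
            type = "SNV", kataegis = TRUE, driver = "none")
        }
      }
    }

    # --- InDels ---------------------------------------------------------
    n_ind <- stats::rpois(1, config$mean_indel)
    if (n_ind > 0) {
      pool <- lapply(idx, function(ci) abs(unlist(ci$all, use.names = FALSE)))
      sizes <- vapply(pool, length, 0L)
      cpick <- sample(rep(names(pool), sizes), n_ind, replace = TRUE)
      for (j in seq_len(n_ind)) {
        cn <- cpick[j]
        pos <- pool[[cn]][sample.int(length(pool[[cn]]), 1)]
        len <- sample(1:10, 1)
        is_del <- stats::runif(1) < 0.5
        s <- seqs[[cn]]
        if (is_del && pos + len <= length(s)) {
          refb <- as.character(Biostrings::extractAt(
            s, IRanges::IRanges(pos, pos + len)))
          if (grepl("N", refb)) next
          m <- genome$mask[genome$mask$chrom == cn, ]
          if (nrow(m) && any(pos <= m$end & pos + len >= m$start)) next
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, chrom = cn, pos = pos, ref = refb,
            alt = substr(refb, 1, 1), type = "DEL",
            kataegis = FALSE, driver = "none")
        } else {
          refb <- as.character(Biostrings::extractAt(
            s, IRanges::IRanges(pos, pos)))
          ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, chrom = cn, pos = pos, ref = refb,
            alt = paste0(refb, ins), type = "INS",
            kataegis = FALSE, driver = "none")
        }
      }
    }

    df <- do.call(rbind, rows)
    if (is.null(df)) next
    # position collisions resolved in favour of drivers, then kataegis
    prio <- order(df$driver == "none", !df$kataegis)
    df <- df[prio, , drop = FALSE]
    df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
    all_rows[[sid]] <- df
  }

  variants <- if (length(all_rows)) {
    do.call(rbind, all_rows)
  } else {
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), type = character(),
               kataegis = logical(), driver = character())
  }
  rownames(variants) <- NULL

  # recorded true channel (SNVs), by construction equal to the collapsed
  # reference context
  variants$channel <- rep(NA_character_, nrow(variants))
  snv <- variants$type == "SNV"
  if (any(snv)) {
    trip <- genome_triplets(seqs, variants$chrom[snv], variants$pos[snv])
    variants$channel[snv] <- collapse_to_context96(
      variants$ref[snv], variants$alt[snv], trip$flank5, trip$flank3)
  }

  variants <- annotate_cohort(variants, genome$model, seqs)
  variants <- variants[order(variants$sample_id, variants$chrom, variants$pos), ]
  rownames(variants) <- NULL
  structure(list(variants = variants, samples = samples, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d samples, %d variants (%d SNV, %d InDel)\n",
              nrow(x$samples), nrow(x$variants),
              sum(x$variants$type == "SNV"),
              sum(x$variants$type != "SNV")))
  invisible(x)
}

#' Dump a truth set to JSON and its sample sheet to TSV
#'
#' @param truth A `truth_set`.
#' @param json_path Output JSON path for the planted variants.
#' @param tsv_path Optional output TSV for sample metadata.
#' @export
write_truth <- function(truth, json_path, tsv_path = NULL) {
  jsonlite::write_json(truth$variants, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(tsv_path)) {
    utils::write.table(truth$samples, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
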