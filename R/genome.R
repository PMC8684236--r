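# Synthetic reference generation: chromosomes, telomere/centromere-like N
# gaps, low-complexity tracts, and an embedded protein-coding gene model
# with designated driver loci. Scales are desk-sized (0.2-2 Mb
# chromosomes); all downstream rates are per-genome so the analysis math is
# scale-free.

#' Cohort simulation configuration
#'
#' Defaults emulate the structure of a 26-pair craniopharyngioma-like WGS
#' cohort: 16 ACP-like and 10 PCP-like tumors, ~760 SNVs and ~39 InDels per
#' tumor, trinucleotide contexts driven by a signature mixture dominated by
#' a broad clock-like process, mutation burden increasing with age,
#' localized hypermutation clusters, enrichment toward chromosome ends, and
#' caller-specific false calls plus artifact sites recurrent across the
#' matched normals.
#'
#' @param n_acp,n_pcp Numbers of ACP-like / PCP-like tumor-normal pairs.
#' @param ages Optional integer vector of patient ages (length
#'   `n_acp + n_pcp`); by default drawn once from a bimodal (pediatric +
#'   adult) distribution for ACP and an adult one for PCP.
#' @param mean_snv,mean_indel Expected per-tumor SNV / InDel counts
#'   (per-sample counts are Poisson around an age-scaled mean).
#' @param signature_mixture Named non-negative weights over columns of
#'   [synthetic_signature_matrix()], summing to at most 1; unassigned mass
#'   is a flat background.
#' @param kataegis_spec data.frame with columns `chrom`, `center`, `n`,
#'   `span` describing clustered-mutation events to plant (assigned to
#'   samples round-robin; an optional `sample` column overrides).
#' @param terminal_bias Fraction of each sample's SNVs forced into the
#'   terminal windows of chromosomes.
#' @param terminal_fraction Terminal window size as a fraction of each
#'   chromosome's non-gap span (per end); must be < 0.5.
#' @param caller_error List with `fn` (named per-caller false-negative
#'   probabilities) and `fp` (named per-caller expected false-positive
#'   record counts per tumor).
#' @param artifact_site_rate Shared-normal artifact background sites per
#'   megabase.
#' @param age_effect Strength in \[0,1\] of the age-burden scaling
#'   (`lambda_i = mean_snv * ((1-age_effect) + age_effect * age_i/mean(age))`).
#' @param burden_dispersion Lognormal sigma of per-sample burden
#'   overdispersion around the age-scaled mean (0 = pure Poisson).
#' @param driver_rate_acp,driver_rate_pcp Fractions of ACP-like samples
#'   carrying the exon-3 driver and PCP-like samples carrying the
#'   V600E-like driver (mutually exclusive by construction).
#' @param chrom_lengths Named integer vector of chromosome lengths (at
#'   least 2 chromosomes of >= 200 kb).
#' @param low_complexity_per_mb Low-complexity tracts planted per megabase.
#' @param depth_mean Mean sequencing depth for emulated tumor and normal
#'   evidence.
#' @param vaf_range Range of true somatic variant allele fractions.
#' @param seed Integer master seed; every stage derives its own stream.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_acp = 16, n_pcp = 10,
                          ages = NULL,
                          mean_snv = 760, mean_indel = 39,
                          signature_mixture = c(sigB_flat = 0.65,
                                                sigA_clock = 0.18),
                          kataegis_spec = data.frame(
                            chrom = c("chr1", "chr2"),
                            center = c(520000, 300000),
                            n = c(8L, 6L),
                            span = c(3000L, 2000L)),
                          terminal_bias = 0.3,
                          terminal_fraction = 0.05,
                          caller_error = list(
                            fn = c(A = 0.02, B = 0.02, C = 0.02),
                            fp = c(A = 60, B = 60, C = 40)),
                          artifact_site_rate = 40,
                          age_effect = 0.5,
                          burden_dispersion = 0.3,
                          driver_rate_acp = 11 / 16,
                          driver_rate_pcp = 7 / 10,
                          chrom_lengths = c(chr1 = 1000000L,
                                            chr2 = 800000L,
                                            chr3 = 600000L),
                          low_complexity_per_mb = 40,
                          depth_mean = 30,
                          vaf_range = c(0.2, 0.5),
                          seed = 1L) {
  cfg <- list(n_acp = n_acp, n_pcp = n_pcp, ages = ages,
              mean_snv = mean_snv, mean_indel = mean_indel,
              signature_mixture = signature_mixture,
              kataegis_spec = kataegis_spec,
              terminal_bias = terminal_bias,
              terminal_fraction = terminal_fraction,
              caller_error = caller_error,
              artifact_site_rate = artifact_site_rate,
              age_effect = age_effect,
              burden_dispersion = burden_dispersion,
              driver_rate_acp = driver_rate_acp,
              driver_rate_pcp = driver_rate_pcp,
              chrom_lengths = chrom_lengths,
              low_complexity_per_mb = low_complexity_per_mb,
              depth_mean = depth_mean,
              vaf_range = vaf_range,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$chrom_lengths) < 2 || any(cfg$chrom_lengths < 200000)) {
    stop("configuration error: need at least 2 chromosomes of >= 200 kb")
  }
  if (cfg$terminal_fraction >= 0.5) {
    stop("configuration error: terminal_fraction must be < 0.5 ",
         "(a chromosome cannot be shorter than twice its terminal window)")
  }
  rates <- c(cfg$terminal_bias, cfg$caller_error$fn,
             cfg$driver_rate_acp, cfg$driver_rate_pcp, cfg$age_effect)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(cfg$burden_dispersion) && cfg$burden_dispersion < 0) {
    stop("burden_dispersion must be non-negative")
  }
  w <- cfg$signature_mixture
  if (any(w < 0) || sum(w) > 1 + 1e-9) {
    stop("signature_mixture weights must be >= 0 and sum to <= 1")
  }
  if (!is.null(cfg$ages) &&
      length(cfg$ages) != cfg$n_acp + cfg$n_pcp) {
    stop("ages must have length n_acp + n_pcp")
  }
  invisible(cfg)
}

# Fixed gene architecture: tx-order CDS piece widths and intron lengths.
# Planted codons pin down known protein positions: DRV1 is the exon-3
# driver locus (Ser/Thr-rich N-terminal degron, 39-nt deletable codon
# block), DRV2 carries the Val codon whose middle-base transversion gives
# the V600E-like change, TSG1 carries a Trp codon whose middle-base
# transition creates a stop (W425X-like) and an Arg codon giving R463Q-like.
.gene_defs <- function(chrom_names) {
  defs <- list(
    list(gene = "DRV1", tx_id = "DRV1.t1", chrom_i = 1, strand = "+",
         frac = 0.22, codons = 780, pieces = c(60, 60, 280, 1940),
         introns = c(1800, 1200, 2500),
         planted = c("33" = "TCT", "37" = "TCT", "41" = "ACC",
                     "43" = "GCT", "44" = "CCT", "45" = "TCT",
                     "56" = "GAT"),
         role = "exon3_driver"),
    list(gene = "HKG1", tx_id = "HKG1.t1", chrom_i = 1, strand = "-",
         frac = 0.62, codons = 450, pieces = c(400, 500, 450),
         introns = c(1500, 2000), planted = NULL, role = "none"),
    list(gene = "DRV2", tx_id = "DRV2.t1", chrom_i = 2, strand = "+",
         frac = 0.20, codons = 640, pieces = c(600, 900, 420),
         introns = c(2100, 1700), planted = c("600" = "GTG"),
         role = "v600e_driver"),
    list(gene = "TSG1", tx_id = "TSG1.t1", chrom_i = 2, strand = "-",
         frac = 0.60, codons = 480, pieces = c(360, 360, 360, 360),
         introns = c(1300, 900, 1100),
         planted = c("425" = "TGG", "463" = "CGG"), role = "none"),
    list(gene = "HKG2", tx_id = "HKG2.t1", chrom_i = 3, strand = "+",
         frac = 0.25, codons = 350, pieces = c(500, 550),
         introns = c(1600), planted = NULL, role = "none"),
    list(gene = "HKG3", tx_id = "HKG3.t1", chrom_i = 3, strand = "-",
         frac = 0.60, codons = 300, pieces = c(300, 300, 300),
         introns = c(1000, 1200), planted = NULL, role = "none"))
  Filter(function(d) d$chrom_i <= length(chrom_names), defs)
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                    c("T","C","A","G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.build_cds <- function(n_codons, planted) {
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  if (!is.null(planted)) {
    codons[as.integer(names(planted))] <- planted
  }
  codons[n_codons] <- "TAA"  # terminal stop; all interior codons are sense
  paste(codons, collapse = "")
}

.revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a synthetic reference genome, mask and gene model
#'
#' Builds random chromosomes with telomere-like N gaps at both ends and one
#' interior gap, planted low-complexity tracts (homopolymers and
#' dinucleotide repeats), and a multi-exon protein-coding gene model on
#' both strands including designated driver loci. Deterministic for a fixed
#' seed.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_genome` object: list with `chromosomes`
#'   ([Biostrings::DNAStringSet]), `gaps` and `mask` (data.frames of
#'   1-based closed intervals), `model` (a [gene_model]), `driver_sites`
#'   and `config`.
#' @export
generate_reference <- function(config) {
  validate_cohort_config(config)
  set.seed(child_seed(config$seed, "reference"))
  lens <- as.integer(config$chrom_lengths)
  cnames <- names(config$chrom_lengths)
  if (is.null(cnames)) cnames <- paste0("chr", seq_along(lens))

  seqs <- vector("list", length(lens))
  gaps <- list(); masks <- list()
  base_prob <- c(0.295, 0.205, 0.205, 0.295)

  for (i in seq_along(lens)) {
    L <- lens[i]
    s <- paste(sample(BASES, L, replace = TRUE, prob = base_prob),
               collapse = "")
    # telomere-like end gaps + one centromere-like interior gap
    gi <- data.frame(chrom = cnames[i],
                     start = c(1L, as.integer(floor(0.45 * L)) + 1L, L - 1999L),
                     end = c(2000L, as.integer(floor(0.45 * L)) + 5000L, L))
    for (g in seq_len(nrow(gi))) {
      substr(s, gi$start[g], gi$end[g]) <-
        strrep("N", gi$end[g] - gi$start[g] + 1L)
    }
    seqs[[i]] <- s
    gaps[[i]] <- gi
  }
  gaps <- do.call(rbind, gaps)

  # gene placement (fixed architecture), writing CDS sequence into genome
  defs <- .gene_defs(cnames)
  txs <- list(); gene_foot <- list(); driver_sites <- list()
  for (d in defs) {
    L <- lens[d$chrom_i]
    start <- as.integer(floor(d$frac * L))
    widths_tx <- d$pieces
    stopifnot(sum(widths_tx) == 3 * d$codons)
    widths_asc <- if (d$strand == "+") widths_tx else rev(widths_tx)
    introns_asc <- if (d$strand == "+") d$introns else rev(d$introns)
    exon_start <- integer(length(widths_asc))
    exon_end <- integer(length(widths_asc))
    p <- start
    for (e in seq_along(widths_asc)) {
      exon_start[e] <- p
      exon_end[e] <- p + widths_asc[e] - 1L
      p <- exon_end[e] + 1L +
        (if (e < length(widths_asc)) introns_asc[e] else 0L)
    }
    cds_seq <- .build_cds(d$codons, d$planted)
    gseq <- if (d$strand == "+") cds_seq else .revcomp_str(cds_seq)
    off <- 0L
    for (e in seq_along(widths_asc)) {
      piece <- substr(gseq, off + 1L, off + widths_asc[e])
      substr(seqs[[d$chrom_i]], exon_start[e], exon_end[e]) <- piece
      off <- off + widths_asc[e]
    }
    iv <- data.frame(start = exon_start, end = exon_end)
    txs[[d$tx_id]] <- list(tx_id = d$tx_id, gene = d$gene,
                           chrom = cnames[d$chrom_i], strand = d$strand,
                           exons = iv, cds = iv)
    gene_foot[[d$tx_id]] <- data.frame(chrom = cnames[d$chrom_i],
                                       start = start, end = p - 1L)
    if (d$role == "exon3_driver") {
      driver_sites$exon3 <- list(tx_id = d$tx_id, gene = d$gene,
                                 chrom = cnames[d$chrom_i])
    }
    if (d$role == "v600e_driver") {
      driver_sites$v600e <- list(tx_id = d$tx_id, gene = d$gene,
                                 chrom = cnames[d$chrom_i])
    }
  }
  model <- gene_model(txs)
  # precise driver definitions: the mutational hotspot region of the
  # exon-3-like locus (codons 30-60) and the exact V600-like codon
  if (!is.null(driver_sites$exon3)) {
    tx <- model$transcripts[[driver_sites$exon3$tx_id]]
    g <- cds_to_genome(tx, c((30L - 1L) * 3L + 1L, 60L * 3L))
    driver_sites$exon3$region <- data.frame(
      chrom = driver_sites$exon3$chrom, start = min(g), end = max(g))
  }
  if (!is.null(driver_sites$v600e)) {
    tx <- model$transcripts[[driver_sites$v600e$tx_id]]
    g <- cds_to_genome(tx, c((600L - 1L) * 3L + 1L, 600L * 3L))
    driver_sites$v600e$region <- data.frame(
      chrom = driver_sites$v600e$chrom, start = min(g), end = max(g))
    driver_sites$v600e$protein_change <- "p.V600E"
  }
  gene_foot <- do.call(rbind, gene_foot)

  # low-complexity tracts, avoiding gaps and gene footprints
  n_mask <- round(config$low_complexity_per_mb * lens / 1e6)
  for (i in seq_along(lens)) {
    if (n_mask[i] == 0) { masks[[i]] <- NULL; next }
    L <- lens[i]
    forbidden <- rbind(
      gaps[gaps$chrom == cnames[i], c("start", "end")],
      gene_foot[gene_foot$chrom == cnames[i], c("start", "end")])
    forbidden$start <- pmax(1L, forbidden$start - 300L)
    forbidden$end <- pmin(L, forbidden$end + 300L)
    got <- 0L; tries <- 0L; rows <- list()
    while (got < n_mask[i] && tries < n_mask[i] * 50L) {
      tries <- tries + 1L
      tl <- sample(50:200, 1)
      ts <- sample.int(L - tl - 1L, 1)
      te <- ts + tl - 1L
      if (any(ts <= forbidden$end & te >= forbidden$start)) next
      unit <- if (stats::runif(1) < 0.5) {
        sample(BASES, 1)
      } else {
        paste(sample(BASES, 2), collapse = "")
      }
      tract <- substr(strrep(unit, ceiling(tl / nchar(unit))), 1, tl)
      substr(seqs[[i]], ts, te) <- tract
      rows[[length(rows) + 1L]] <- data.frame(chrom = cnames[i],
                                              start = ts, end = te)
      forbidden <- rbind(forbidden,
                         data.frame(start = ts - 300L, end = te + 300L))
      got <- got + 1L
    }
    masks[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  mask <- if (length(masks) && !all(vapply(masks, is.null, TRUE))) {
    m <- do.call(rbind, masks)
    m[order(m$chrom, m$start), ]
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  rownames(mask) <- NULL

  chromosomes <- Biostrings::DNAStringSet(unlist(seqs))
  names(chromosomes) <- cnames
  structure(list(chromosomes = chromosomes, gaps = gaps, mask = mask,
                 model = model, driver_sites = driver_sites,
                 config = config),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic_genome: %d chromosomes (%.2f Mb), %d gap intervals, %d low-complexity tracts, %d transcripts\n",
    length(x$chromosomes), sum(Biostrings::width(x$chromosomes)) / 1e6,
    nrow(x$gaps), nrow(x$mask), length(x$model$transcripts)))
  invisible(x)
}

#' Terminal windows of a genome
#'
#' The outermost `fraction` of each chromosome's non-gap span (the interval
#' from the first to the last non-N base), at both ends.
#'
#' @param genome A `synthetic_genome`.
#' @param fraction Window size as a fraction of the non-gap span per end.
#' @return data.frame with `chrom`, `start`, `end` (1-based closed).
#' @export
terminal_windows <- function(genome, fraction = 0.05) {
  if (fraction >= 0.5) stop("configuration error: fraction must be < 0.5")
  out <- list()
  for (cn in names(genome$chromosomes)) {
    L <- Biostrings::width(genome$chromosomes[cn])
    g <- genome$gaps[genome$gaps$chrom == cn, ]
    lead <- g[g$start == 1L, ]
    trail <- g[g$end == L, ]
    s <- if (nrow(lead)) max(lead$end) + 1L else 1L
    e <- if (nrow(trail)) min(trail$start) - 1L else L
    w <- as.integer(floor(fraction * (e - s + 1L)))
    out[[cn]] <- data.frame(chrom = cn,
                            start = c(s, e - w + 1L),
                            end = c(s + w - 1L, e))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic reference to disk
#'
#' Emits `ref.fa` (FASTA), `gaps.bed` and `mask.bed` (0-based half-open
#' BED) and `genes.gff3` under `dir`.
#'
#' @param genome A `synthetic_genome`.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_reference <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "ref.fa"),
                gaps = file.path(dir, "gaps.bed"),
                mask = file.path(dir, "mask.bed"),
                gff3 = file.path(dir, "genes.gff3"))
  Biostrings::writeXStringSet(genome$chromosomes, paths$fasta)
  write_bed(genome$gaps, paths$gaps)
  write_bed(genome$mask, paths$mask)
  write_gff3(genome$model, paths$gff3)
  invisible(paths)
}
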