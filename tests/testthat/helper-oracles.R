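# Shared fixtures and independent oracles used across the suite.

BASES4 <- c("A", "C", "G", "T")

small_config <- function(seed = 1, ...) {
  args <- list(
    n_acp = 3, n_pcp = 2, mean_snv = 60, mean_indel = 8,
    chrom_lengths = c(chr1 = 400000L, chr2 = 300000L),
    kataegis_spec = data.frame(chrom = "chr1", center = 320000L,
                               n = 8L, span = 3000L),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

zero_noise_config <- function(seed = 1, ...) {
  small_config(seed = seed,
               caller_error = list(fn = c(A = 0, B = 0, C = 0),
                                   fp = c(A = 0, B = 0, C = 0)),
               artifact_site_rate = 0, ...)
}

# --- gene fixture: embed a given CDS into a random chromosome ------------

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_cds <- function(n_codons, seed = 1) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(BASES4, BASES4, BASES4), 1,
                         paste, collapse = ""), c("TAA", "TAG", "TGA"))
  codons <- sample(sense, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  codons
}

# Returns list(genome = DNAStringSet, model = gene_model, tx, cds_seq).
# `pieces` are CDS widths in translation order.
embed_gene <- function(cds_codons, strand = "+", pieces = NULL,
                       intron_len = 80, flank = 150, seed = 99,
                       planted = NULL) {
  if (!is.null(planted)) cds_codons[as.integer(names(planted))] <- planted
  cds_seq <- paste(cds_codons, collapse = "")
  L_cds <- nchar(cds_seq)
  if (is.null(pieces)) {
    half <- (L_cds %/% 6) * 3
    pieces <- c(half, L_cds - half)
  }
  stopifnot(sum(pieces) == L_cds)
  widths_asc <- if (strand == "+") pieces else rev(pieces)
  set.seed(seed)
  total <- sum(widths_asc) + intron_len * (length(widths_asc) - 1)
  L <- 2 * flank + total
  s <- paste(sample(BASES4, L, replace = TRUE), collapse = "")
  exon_start <- integer(length(widths_asc))
  exon_end <- integer(length(widths_asc))
  p <- flank + 1L
  for (e in seq_along(widths_asc)) {
    exon_start[e] <- p
    exon_end[e] <- p + widths_asc[e] - 1L
    p <- exon_end[e] + 1L + (if (e < length(widths_asc)) intron_len else 0L)
  }
  gseq <- if (strand == "+") cds_seq else revcomp_chr(cds_seq)
  off <- 0L
  for (e in seq_along(widths_asc)) {
    substr(s, exon_start[e], exon_end[e]) <-
      substr(gseq, off + 1L, off + widths_asc[e])
    off <- off + widths_asc[e]
  }
  iv <- data.frame(start = exon_start, end = exon_end)
  tx <- list(tx_id = "TST.t1", gene = "TST", chrom = "chrT",
             strand = strand, exons = iv, cds = iv)
  genome <- Biostrings::DNAStringSet(s)
  names(genome) <- "chrT"
  list(genome = genome, model = gene_model(list(tx)), tx = tx,
       cds_seq = cds_seq)
}

# Genomic position of a spliced-CDS coordinate for an embed_gene fixture
# (independent of the package's own coordinate mapping).
fixture_cds_to_genome <- function(fx, cds_pos) {
  cds <- fx$tx$cds
  if (fx$tx$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
  w <- cds$end - cds$start + 1L
  ends <- cumsum(w)
  i <- which(cds_pos <= ends)[1]
  within <- cds_pos - (ends[i] - w[i] + 1L) + 1L
  if (fx$tx$strand == "+") cds$start[i] + within - 1L else cds$end[i] - within + 1L
}

# --- filter oracle: plain rule-by-rule re-implementation -----------------

oracle_filter <- function(calls, panel_sites, mask, th = filter_thresholds(),
                          consensus = TRUE) {
  pk <- if (is.null(panel_sites) || nrow(panel_sites) == 0) character(0)
        else paste(panel_sites$chrom, panel_sites$pos, panel_sites$alt)
  res <- logical(nrow(calls))
  rules <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    f <- character(0)
    if (x$vaf < th$min_vaf) f <- c(f, "VAF")
    if (x$mean_base_quality < th$min_bq) f <- c(f, "BQ")
    if (x$type == "SNV") {
      if (!(x$normal_depth > th$min_normal_depth)) f <- c(f, "DEPTH_NORMAL")
      if (!(x$tumor_depth > th$min_tumor_depth)) f <- c(f, "DEPTH_TUMOR")
    } else {
      if (!(x$tumor_depth > th$min_indel_depth)) f <- c(f, "INDEL_DEPTH")
      if (grepl("C", x$callers) && !is.na(x$indel_pvalue) &&
          x$indel_pvalue > th$max_indel_p) f <- c(f, "INDEL_P")
    }
    if (paste(x$chrom, x$pos, x$alt) %in% pk) f <- c(f, "PON")
    if (!is.null(mask) && nrow(mask) > 0) {
      fe <- x$pos + nchar(x$ref) - 1L
      hit <- any(mask$chrom == x$chrom & mask$start <= fe & mask$end >= x$pos)
      if (hit) f <- c(f, "MASK")
    }
    if (consensus) {
      ok <- if (x$type == "SNV") grepl("A", x$callers) && isTRUE(x$passed_primary)
            else grepl("B", x$callers) && grepl("C", x$callers)
      if (!ok) f <- c(f, "CALLER_CONSENSUS")
    }
    res[i] <- length(f) == 0
    rules[i] <- paste(f, collapse = ",")
  }
  data.frame(retained = res, failed_rules = rules, stringsAsFactors = FALSE)
}

random_raw_calls <- function(n, seed = 1) {
  set.seed(seed)
  type <- sample(c("SNV", "DEL", "INS"), n, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  callers <- ifelse(type == "SNV",
                    sample(c("A", "A,B", "B", "A,B,C"), n, replace = TRUE),
                    sample(c("B", "C", "B,C"), n, replace = TRUE))
  ref <- ifelse(type == "DEL",
                vapply(seq_len(n), function(i) paste(
                  sample(BASES4, sample(2:6, 1), TRUE), collapse = ""), ""),
                sample(BASES4, n, replace = TRUE))
  alt <- vapply(seq_len(n), function(i) {
    if (type[i] == "SNV") sample(setdiff(BASES4, ref[i]), 1)
    else if (type[i] == "DEL") substr(ref[i], 1, 1)
    else paste(c(ref[i], sample(BASES4, sample(1:5, 1), TRUE)), collapse = "")
  }, "")
  data.frame(
    sample_id = "T1",
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(100000, n, replace = TRUE),
    ref = ref, alt = alt, type = type, callers = callers,
    passed_primary = stats::runif(n) < 0.7,
    normal_depth = sample(5:40, n, replace = TRUE),
    tumor_depth = sample(5:40, n, replace = TRUE),
    tumor_alt_reads = 0L,
    vaf = round(stats::runif(n, 0, 0.6), 3),
    mean_base_quality = sample(10:40, n, replace = TRUE),
    indel_pvalue = ifelse(type != "SNV" & grepl("C", callers),
                          signif(stats::runif(n, 0, 0.01), 3), NA_real_),
    stringsAsFactors = FALSE)
}

# --- kataegis oracle: explicit double-loop window scan -------------------

oracle_kataegis <- function(points, min_n = 6, max_mean_imd = 1000) {
  df <- points[order(points$chrom, points$pos), , drop = FALSE]
  events <- list()
  for (cn in unique(df$chrom)) {
    p <- df$pos[df$chrom == cn]
    n <- length(p)
    member <- logical(n)
    if (n >= min_n) {
      for (i in seq_len(n - min_n + 1L)) {
        for (j in (i + min_n - 1L):n) {
          if ((p[j] - p[i]) / (j - i) <= max_mean_imd) member[i:j] <- TRUE
        }
      }
    }
    if (!any(member)) next
    r <- rle(member)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    for (q in which(r$values)) {
      a <- s[q]; b <- e[q]
      events[[length(events) + 1L]] <- data.frame(
        chrom = cn, start = p[a], end = p[b], n_mutations = b - a + 1L,
        mean_imd = (p[b] - p[a]) / (b - a))
    }
  }
  if (length(events) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_mutations = integer(),
                      mean_imd = numeric()))
  }
  out <- do.call(rbind, events)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# --- refit grid oracle: exact optimum over a weight grid -----------------

# SSE as a quadratic form so millions of grid points are cheap.
grid_search_sse <- function(spectrum, S, step = 0.001) {
  K <- ncol(S)
  A <- crossprod(S)
  b <- as.vector(crossprod(S, spectrum))
  c0 <- sum(spectrum^2)
  g <- seq(0, 1, by = step)
  if (K == 2) {
    w1 <- rep(g, each = length(g))
    w2 <- rep(g, times = length(g))
    ok <- w1 + w2 <= 1 + 1e-12
    w1 <- w1[ok]; w2 <- w2[ok]
    sse <- c0 - 2 * (w1 * b[1] + w2 * b[2]) +
      w1^2 * A[1, 1] + w2^2 * A[2, 2] + 2 * w1 * w2 * A[1, 2]
    return(min(sse))
  }
  if (K == 3) {
    best <- Inf
    for (w1 in g) {
      w2 <- g[g <= 1 - w1 + 1e-12]
      # conditional optimum in w3 is quadratic; the grid minimum sits at
      # the grid neighbours of the clipped continuous optimum
      w3_star <- (b[3] - w1 * A[1, 3] - w2 * A[2, 3]) / A[3, 3]
      w3_max <- 1 - w1 - w2
      cand <- cbind(pmin(pmax(floor(w3_star / step) * step, 0), w3_max),
                    pmin(pmax(ceiling(w3_star / step) * step, 0), w3_max),
                    0, w3_max)
      for (k in seq_len(ncol(cand))) {
        w3 <- cand[, k]
        sse <- c0 - 2 * (w1 * b[1] + w2 * b[2] + w3 * b[3]) +
          w1^2 * A[1, 1] + w2^2 * A[2, 2] + w3^2 * A[3, 3] +
          2 * (w1 * w2 * A[1, 2] + w1 * w3 * A[1, 3] + w2 * w3 * A[2, 3])
        best <- min(best, min(sse))
      }
    }
    return(best)
  }
  stop("grid oracle supports K = 2 or 3")
}
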