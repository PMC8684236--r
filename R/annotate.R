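# Gene-model handling and coding-effect annotation.
#
# The model is deliberately minimal: transcripts with exon and CDS intervals
# (1-based, closed). Region taxonomy is exonic (overlaps any CDS) >
# intronic (within a transcript span) > intergenic; UTR-like exon sequence
# therefore folds into "intronic", since only CDS effects are analysed
# downstream.

#' Construct a gene model
#'
#' @param transcripts List of transcript descriptions; each element is a
#'   list with `tx_id`, `gene`, `chrom`, `strand` ("+"/"-"), `exons` and
#'   `cds` (data.frames with `start`, `end`, 1-based closed, ascending).
#' @return A `gene_model` object.
#' @export
gene_model <- function(transcripts) {
  for (tx in transcripts) {
    stopifnot(all(c("tx_id", "gene", "chrom", "strand", "exons", "cds")
                  %in% names(tx)))
    if (!tx$strand %in% c("+", "-")) stop("strand must be + or -")
    cl <- sum(tx$cds$end - tx$cds$start + 1)
    if (cl %% 3 != 0) {
      stop(sprintf("CDS length of %s (%d) is not a multiple of 3",
                   tx$tx_id, cl))
    }
    if (is.unsorted(tx$cds$start) || any(tx$cds$start > tx$cds$end)) {
      stop("CDS intervals must be ascending and well-formed")
    }
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "tx_id")
  structure(list(transcripts = transcripts), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model with %d transcripts: %s\n",
              length(x$transcripts),
              paste(vapply(x$transcripts, `[[`, "", "gene"), collapse = ", ")))
  invisible(x)
}

# CDS intervals of a transcript in translation (5'->3') order.
.cds_translation_order <- function(tx) {
  cds <- tx$cds
  if (tx$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  cds
}

# Map a genomic position to its 1-based coordinate in the spliced CDS.
# NA when the position is not inside any CDS interval.
genome_to_cds <- function(tx, pos) {
  cds <- .cds_translation_order(tx)
  off <- 0L
  for (i in seq_len(nrow(cds))) {
    w <- cds$end[i] - cds$start[i] + 1L
    if (pos >= cds$start[i] && pos <= cds$end[i]) {
      within <- if (tx$strand == "+") pos - cds$start[i] else cds$end[i] - pos
      return(as.integer(off + within + 1))
    }
    off <- off + w
  }
  NA_integer_
}

# Map a spliced-CDS coordinate (vectorised) back to genomic positions.
cds_to_genome <- function(tx, cds_pos) {
  cds <- .cds_translation_order(tx)
  widths <- cds$end - cds$start + 1L
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  as.integer(vapply(cds_pos, function(p) {
    i <- which(p >= starts & p <= ends)[1]
    if (is.na(i)) stop("CDS position out of range: ", p)
    within <- p - starts[i]
    as.numeric(if (tx$strand == "+") cds$start[i] + within
               else cds$end[i] - within)
  }, numeric(1)))
}

.tx_cds_len <- function(tx) as.numeric(sum(tx$cds$end - tx$cds$start + 1))

# Transcripts whose CDS (or span) contain the interval [start, end];
# returns the winner under the longest-CDS / alphabetical-gene rule.
.pick_cds_transcript <- function(model, chrom, start, end = start) {
  cand <- Filter(function(tx) {
    tx$chrom == chrom &&
      any(tx$cds$start <= end & tx$cds$end >= start)
  }, model$transcripts)
  if (length(cand) == 0) return(NULL)
  lens <- vapply(cand, .tx_cds_len, numeric(1))
  genes <- vapply(cand, `[[`, "", "gene")
  cand[[order(-lens, genes)[1]]]
}

#' Classify variants by genomic region
#'
#' A variant is `exonic` if its footprint overlaps any CDS interval of any
#' transcript, else `intronic` if it lies within any transcript span, else
#' `intergenic`. Variants on chromosomes absent from the model are
#' `intergenic` (with a warning).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref` (footprint is
#'   `pos .. pos + nchar(ref) - 1`).
#' @param model A [gene_model].
#' @return Character vector in `{exonic, intronic, intergenic}`.
#' @export
classify_region <- function(variants, model) {
  txs <- model$transcripts
  cds_gr <- GenomicRanges::GRanges(
    rep(vapply(txs, `[[`, "", "chrom"),
        vapply(txs, function(t) nrow(t$cds), 0L)),
    IRanges::IRanges(unlist(lapply(txs, function(t) t$cds$start)),
                     unlist(lapply(txs, function(t) t$cds$end))))
  span_gr <- GenomicRanges::GRanges(
    vapply(txs, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(txs, function(t) min(t$exons$start), 0),
                     vapply(txs, function(t) max(t$exons$end), 0)))
  model_chroms <- unique(vapply(txs, `[[`, "", "chrom"))
  missing_chrom <- setdiff(unique(variants$chrom), model_chroms)
  if (length(missing_chrom)) {
    warning("chromosome(s) absent from gene model, classified intergenic: ",
            paste(missing_chrom, collapse = ", "))
  }
  v_gr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L))
  out <- rep("intergenic", nrow(variants))
  # disjoint seqlevels are expected (warned above), not an error
  out[suppressWarnings(IRanges::overlapsAny(v_gr, span_gr))] <- "intronic"
  out[suppressWarnings(IRanges::overlapsAny(v_gr, cds_gr))] <- "exonic"
  out
}

AA1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon: ", codon)
  aa
}

# Reference amino acid at a given codon of a transcript.
.codon_ref <- function(tx, codon_num, seqs) {
  gpos <- cds_to_genome(tx, ((codon_num - 1L) * 3L + 1L):(codon_num * 3L))
  b <- vapply(gpos, function(p) {
    as.character(Biostrings::extractAt(seqs[[tx$chrom]], IRanges::IRanges(p, p)))
  }, "")
  if (tx$strand == "-") b <- .complement(b)
  codon <- paste(b, collapse = "")
  list(codon = codon, aa = .translate_codon(codon), gpos = gpos)
}

#' Classify the coding effect of an exonic variant
#'
#' For SNVs the reference codon is rebuilt strand-aware from CDS
#' coordinates, the alternate base substituted, and both codons translated
#' with the standard genetic code: identical amino acid gives `silent`, a
#' gained stop gives `nonsense` (named with `X`), anything else `missense`.
#' Protein changes are named `p.<ref><codon><alt>`.
#'
#' InDels whose length change is a multiple of 3 are in-frame (`indel`
#' effect, named `p.<aa><start>_<aa><end>del` / `ins`); others are
#' frameshifts, named `p.<aa><codon>fs`.
#'
#' When several transcripts cover the site, the one with the longest CDS
#' wins (ties broken by alphabetical gene name).
#'
#' @param variant One-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param model A [gene_model].
#' @param genome Reference genome (see [sample_spectrum()] for accepted
#'   forms).
#' @return List with `effect_class` (`missense`, `silent`, `nonsense`,
#'   `indel`, or `none` if the variant does not touch CDS), `protein_change`
#'   (NA for `none`), `gene` and `tx_id`.
#' @export
classify_effect <- function(variant, model, genome) {
  seqs <- as_dna_stringset(genome)
  chrom <- variant$chrom; pos <- variant$pos
  ref <- variant$ref; alt <- variant$alt
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  none <- list(effect_class = "none", protein_change = NA_character_,
               gene = NA_character_, tx_id = NA_character_)

  if (is_snv) {
    tx <- .pick_cds_transcript(model, chrom, pos)
    if (is.null(tx)) return(none)
    cdspos <- genome_to_cds(tx, pos)
    if (is.na(cdspos)) return(none)
    codon_num <- (cdspos - 1L) %/% 3L + 1L
    codon_off <- (cdspos - 1L) %% 3L + 1L
    rc <- .codon_ref(tx, codon_num, seqs)
    genomic_ref <- as.character(
      Biostrings::extractAt(seqs[[chrom]], IRanges::IRanges(pos, pos)))
    if (genomic_ref != ref) {
      stop(sprintf("reference mismatch at %s:%d (expected %s, genome has %s)",
                   chrom, pos, ref, genomic_ref))
    }
    alt_cds <- if (tx$strand == "-") .complement(alt) else alt
    alt_codon <- rc$codon
    substr(alt_codon, codon_off, codon_off) <- alt_cds
    aa_ref <- rc$aa
    aa_alt <- .translate_codon(alt_codon)
    aa_ref_lbl <- if (aa_ref == "*") "X" else aa_ref
    if (aa_alt == aa_ref) {
      eff <- "silent"; pch <- sprintf("p.%s%d%s", aa_ref_lbl, codon_num, aa_ref_lbl)
    } else if (aa_alt == "*") {
      eff <- "nonsense"; pch <- sprintf("p.%s%dX", aa_ref_lbl, codon_num)
    } else {
      eff <- "missense"; pch <- sprintf("p.%s%d%s", aa_ref_lbl, codon_num, aa_alt)
    }
    return(list(effect_class = eff, protein_change = pch,
                gene = tx$gene, tx_id = tx$tx_id))
  }

  # InDel (VCF-style anchored): deleted bases are pos+1 .. pos+len for
  # deletions; insertions sit after pos.
  len_change <- abs(nchar(ref) - nchar(alt))
  if (len_change == 0) stop("indel with equal ref/alt lengths unsupported")
  is_del <- nchar(ref) > nchar(alt)
  foot_start <- if (is_del) pos + 1L else pos
  foot_end <- if (is_del) pos + nchar(ref) - 1L else pos + 1L
  tx <- .pick_cds_transcript(model, chrom, foot_start, foot_end)
  if (is.null(tx)) return(none)
  affected <- if (is_del) foot_start:foot_end else c(pos, pos + 1L)
  cdspos <- vapply(affected, function(p) genome_to_cds(tx, p), integer(1))
  cdspos <- cdspos[!is.na(cdspos)]
  if (length(cdspos) == 0) return(none)
  codons <- sort(unique((cdspos - 1L) %/% 3L + 1L))
  c1 <- min(codons); c2 <- max(codons)
  aa1 <- .codon_ref(tx, c1, seqs)$aa
  aa1 <- if (aa1 == "*") "X" else aa1
  if (len_change %% 3 == 0) {
    if (is_del) {
      if (c2 > c1) {
        aa2 <- .codon_ref(tx, c2, seqs)$aa
        aa2 <- if (aa2 == "*") "X" else aa2
        pch <- sprintf("p.%s%d_%s%ddel", aa1, c1, aa2, c2)
      } else {
        pch <- sprintf("p.%s%ddel", aa1, c1)
      }
    } else {
      pch <- sprintf("p.%s%dins", aa1, c1)
    }
  } else {
    pch <- sprintf("p.%s%dfs", aa1, c1)
  }
  list(effect_class = "indel", protein_change = pch,
       gene = tx$gene, tx_id = tx$tx_id)
}

#' Annotate a cohort of variants
#'
#' Adds `region_class`, `effect_class`, `protein_change` and `gene` columns.
#' Effects are computed only for exonic variants; others get `none` / NA.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param model A [gene_model].
#' @param genome Reference genome.
#' @return The input data.frame with annotation columns appended.
#' @export
annotate_cohort <- function(variants, model, genome) {
  if (nrow(variants) == 0) {
    variants$region_class <- character(0)
    variants$effect_class <- character(0)
    variants$protein_change <- character(0)
    variants$gene <- character(0)
    return(variants)
  }
  seqs <- as_dna_stringset(genome)
  variants$region_class <- classify_region(variants, model)
  eff <- rep("none", nrow(variants))
  pch <- rep(NA_character_, nrow(variants))
  gene <- rep(NA_character_, nrow(variants))
  ex <- which(variants$region_class == "exonic")
  for (i in ex) {
    r <- classify_effect(variants[i, ], model, seqs)
    eff[i] <- r$effect_class
    pch[i] <- r$protein_change
    gene[i] <- r$gene
  }
  # an "exonic" overlap that touches no CDS base after fine mapping is
  # demoted (can happen for anchored indels whose anchor precedes the CDS)
  variants$region_class[ex][eff[ex] == "none"] <- "intronic"
  variants$effect_class <- eff
  variants$protein_change <- pch
  variants$gene <- gene
  variants
}

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based, closed), with CDS
#' phase computed in translation order.
#'
#' @param model A [gene_model].
#' @param path Output path.
#' @export
write_gff3 <- function(model, path) {
  lines <- "##gff-version 3"
  for (tx in model$transcripts) {
    span <- c(min(tx$exons$start), max(tx$exons$end))
    gid <- paste0("gene:", tx$gene)
    lines <- c(lines,
               sprintf("%s\tsomacohort\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       tx$chrom, span[1], span[2], tx$strand, gid, tx$gene),
               sprintf("%s\tsomacohort\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       tx$chrom, span[1], span[2], tx$strand, tx$tx_id, gid))
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines, sprintf(
        "%s\tsomacohort\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        tx$chrom, tx$exons$start[i], tx$exons$end[i], tx$strand, tx$tx_id))
    }
    cds_tr <- .cds_translation_order(tx)
    w <- cds_tr$end - cds_tr$start + 1L
    phase <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
    for (i in seq_len(nrow(cds_tr))) {
      lines <- c(lines, sprintf(
        "%s\tsomacohort\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
        tx$chrom, cds_tr$start[i], cds_tr$end[i], tx$strand, phase[i], tx$tx_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Reconstructs a [gene_model] from gene/mRNA/exon/CDS features written by
#' [write_gff3()] (or any GFF3 using `Parent` attributes in that layout).
#'
#' @param path GFF3 path.
#' @return A [gene_model].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  mrna <- df[df$type == "mRNA", ]
  txs <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    parent <- as.character(unlist(mrna$Parent[i]))
    gene <- sub("^gene:", "", parent)
    kids <- df[vapply(df$Parent, function(p) tid %in% unlist(p), logical(1)), ]
    ex <- kids[kids$type == "exon", c("start", "end")]
    cds <- kids[kids$type == "CDS", c("start", "end")]
    list(tx_id = tid, gene = gene,
         chrom = as.character(mrna$seqnames[i]),
         strand = as.character(mrna$strand[i]),
         exons = ex[order(ex$start), ],
         cds = cds[order(cds$start), ])
  })
  gene_model(txs)
}
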