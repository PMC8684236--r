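# Base-pair substitution classes as conventionally printed, pyrimidine first.
SIX_CLASSES <- c("C:G>A:T", "C:G>G:C", "C:G>T:A",
                 "T:A>A:T", "T:A>C:G", "T:A>G:C")

# Pyrimidine-strand substitution pairs underlying the six classes, in
# canonical order (C>A, C>G, C>T, T>A, T>C, T>G).
SUB_PAIRS <- matrix(c("C", "A", "C", "G", "C", "T",
                      "T", "A", "T", "C", "T", "G"),
                    ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("ref", "alt")))

BASES <- c("A", "C", "G", "T")

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.check_base <- function(x, what) {
  bad <- !(x %in% BASES)
  if (any(bad)) {
    stop(sprintf("%s must be one of A,C,G,T; got: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Canonical 96 trinucleotide-context channel labels
#'
#' Channels are strings of the form `"X[R>A]Y"` where the mutated base `R`
#' is a pyrimidine (C or T), `A` is the alternate base and `X`, `Y` are the
#' 5' and 3' flanking reference bases. The order is the conventional one used
#' for spectrum interchange: six substitution groups (C>A, C>G, C>T, T>A,
#' T>C, T>G), each expanded over the 16 flank combinations in lexicographic
#' order.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(context_channels())
context_channels <- function() {
  out <- character(96)
  k <- 1L
  for (s in seq_len(6)) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out[k] <- sprintf("%s[%s>%s]%s", f5, SUB_PAIRS[s, 1], SUB_PAIRS[s, 2], f3)
        k <- k + 1L
      }
    }
  }
  out
}

#' Map channel labels to canonical indices
#'
#' @param channel Character vector of channel labels (see
#'   [context_channels()]).
#' @return Integer vector of indices in 1..96.
#' @export
channel_index <- function(channel) {
  idx <- match(channel, context_channels())
  if (anyNA(idx)) {
    stop("invalid 96-context channel label(s): ",
         paste(unique(channel[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Classify a single-base substitution into the six base-pair classes
#'
#' Purine reference bases are collapsed onto the complementary pyrimidine
#' strand, so e.g. G>A and C>T both map to `"C:G>T:A"`.
#'
#' @param ref,alt Single reference and alternate bases (vectorised).
#' @return Character vector of class labels among
#'   `C:G>A:T, C:G>G:C, C:G>T:A, T:A>A:T, T:A>C:G, T:A>G:C`.
#' @export
#' @examples
#' six_class("C", "T")  # "C:G>T:A"
#' six_class("G", "A")  # same class, complement collapse
six_class <- function(ref, alt) {
  .check_base(ref, "ref")
  .check_base(alt, "alt")
  if (length(alt) != length(ref)) stop("ref and alt lengths differ")
  if (any(ref == alt)) stop("ref and alt must differ")
  pur <- ref %in% c("A", "G")
  ref[pur] <- .complement(ref[pur])
  alt[pur] <- .complement(alt[pur])
  grp <- match(paste0(ref, ">", alt),
               paste0(SUB_PAIRS[, 1], ">", SUB_PAIRS[, 2]))
  SIX_CLASSES[grp]
}

#' Collapse a substitution with its flanks to a 96-context channel
#'
#' Flanking bases are taken from the reference strand of the call; when the
#' mutated base is a purine the whole triplet is reverse-complemented (which
#' swaps the flanks) so that the channel is always expressed on the
#' pyrimidine strand.
#'
#' @param ref,alt Single mutated/alternate bases (vectorised).
#' @param flank5,flank3 5' and 3' flanking reference bases.
#' @return Character vector of channel labels.
#' @export
#' @examples
#' collapse_to_context96("C", "T", "A", "G")  # "A[C>T]G"
#' collapse_to_context96("G", "A", "C", "T")  # reverse complement, same channel
collapse_to_context96 <- function(ref, alt, flank5, flank3) {
  .check_base(ref, "ref")
  .check_base(alt, "alt")
  .check_base(flank5, "flank5")
  .check_base(flank3, "flank3")
  pur <- ref %in% c("A", "G")
  new5 <- ifelse(pur, .complement(flank3), flank5)
  new3 <- ifelse(pur, .complement(flank5), flank3)
  r <- ifelse(pur, .complement(ref), ref)
  a <- ifelse(pur, .complement(alt), alt)
  sprintf("%s[%s>%s]%s", new5, r, a, new3)
}

#' Per-sample mutational spectrum
#'
#' Tallies the 6-class and 96-channel substitution spectrum of a set of SNVs
#' against a reference genome. Reference alleles are checked against the
#' genome; mismatches are a consistency error. Variants whose immediate
#' flank contains an N are excluded and counted in `n_excluded_N`.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; SNVs only (single-base ref and alt).
#' @param genome A [Biostrings::DNAStringSet] or `synthetic_genome` object.
#' @param sample_id Optional sample label stored on the result.
#' @return An object of class `spectrum_vector`: list with `sample_id`,
#'   `counts6` (named length-6 integer), `counts96` (named length-96
#'   integer), `proportions6`, `proportions96` (NA when the total is zero)
#'   and `n_excluded_N`.
#' @export
sample_spectrum <- function(variants, genome, sample_id = NA_character_) {
  seqs <- as_dna_stringset(genome)
  counts96 <- stats::setNames(integer(96), context_channels())
  n_excl <- 0L
  if (nrow(variants) > 0) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
    if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)) {
      stop("sample_spectrum expects SNVs only (single-base ref and alt)")
    }
    bad_chrom <- setdiff(unique(variants$chrom), names(seqs))
    if (length(bad_chrom)) {
      stop("chromosome(s) absent from genome: ", paste(bad_chrom, collapse = ", "))
    }
    lens <- Biostrings::width(seqs)[match(variants$chrom, names(seqs))]
    if (any(variants$pos < 1 | variants$pos > lens)) {
      stop("variant position beyond chromosome end")
    }
    trip <- genome_triplets(seqs, variants$chrom, variants$pos)
    mism <- trip$ref != variants$ref
    if (any(mism)) {
      off <- utils::head(paste0(variants$chrom[mism], ":", variants$pos[mism],
                                " expected ", variants$ref[mism], " found ",
                                trip$ref[mism]), 10)
      stop("reference allele mismatch at: ", paste(off, collapse = "; "))
    }
    has_n <- trip$flank5 == "N" | trip$flank3 == "N" | trip$ref == "N"
    n_excl <- sum(has_n)
    keep <- !has_n
    if (any(keep)) {
      ch <- collapse_to_context96(variants$ref[keep], variants$alt[keep],
                                  trip$flank5[keep], trip$flank3[keep])
      tab <- table(factor(ch, levels = context_channels()))
      counts96 <- counts96 + as.integer(tab)
      names(counts96) <- context_channels()
    }
  }
  structure(list(sample_id = sample_id,
                 counts6 = counts6_from_96(counts96),
                 counts96 = counts96,
                 proportions6 = .safe_prop(counts6_from_96(counts96)),
                 proportions96 = .safe_prop(counts96),
                 n_excluded_N = n_excl),
            class = "spectrum_vector")
}

.safe_prop <- function(x) {
  tot <- sum(x)
  if (tot == 0) return(stats::setNames(rep(NA_real_, length(x)), names(x)))
  x / tot
}

#' Marginalise a 96-channel count vector over flanks to the six classes
#'
#' @param counts96 Named numeric vector in canonical channel order.
#' @return Named length-6 vector in canonical class order.
#' @export
counts6_from_96 <- function(counts96) {
  stopifnot(length(counts96) == 96)
  grp <- rep(seq_len(6), each = 16)
  stats::setNames(as.vector(tapply(as.numeric(counts96), grp, sum)), SIX_CLASSES)
}

# Reference base and flanks at 1-based positions; positions at a chromosome
# edge get "N" flanks.
genome_triplets <- function(seqs, chrom, pos) {
  n <- length(pos)
  ref <- flank5 <- flank3 <- character(n)
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    s <- seqs[[cn]]
    L <- length(s)
    p <- pos[i]
    ref[i] <- as.character(Biostrings::extractAt(s, IRanges::IRanges(p, p)))
    f5 <- rep("N", length(p)); f3 <- rep("N", length(p))
    ok5 <- p > 1; ok3 <- p < L
    if (any(ok5)) {
      f5[ok5] <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(p[ok5] - 1L, p[ok5] - 1L)))
    }
    if (any(ok3)) {
      f3[ok3] <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(p[ok3] + 1L, p[ok3] + 1L)))
    }
    flank5[i] <- f5; flank3[i] <- f3
  }
  list(ref = ref, flank5 = flank5, flank3 = flank3)
}

#' Pool or average spectra across a cohort
#'
#' @param spectra List of `spectrum_vector` objects.
#' @param method `"pooled"` (sum counts, default) or `"mean"` (average
#'   per-sample proportions, ignoring zero-count samples).
#' @return A `spectrum_vector` (pooled) or list of proportion vectors (mean).
#' @export
cohort_spectrum <- function(spectra, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (method == "pooled") {
    counts96 <- Reduce(`+`, lapply(spectra, `[[`, "counts96"))
    structure(list(sample_id = "cohort",
                   counts6 = counts6_from_96(counts96),
                   counts96 = counts96,
                   proportions6 = .safe_prop(counts6_from_96(counts96)),
                   proportions96 = .safe_prop(counts96),
                   n_excluded_N = sum(vapply(spectra, `[[`, 0L, "n_excluded_N"))),
              class = "spectrum_vector")
  } else {
    p6 <- lapply(spectra, `[[`, "proportions6")
    p96 <- lapply(spectra, `[[`, "proportions96")
    ok <- !vapply(p96, function(x) anyNA(x), logical(1))
    list(proportions6 = Reduce(`+`, p6[ok]) / sum(ok),
         proportions96 = Reduce(`+`, p96[ok]) / sum(ok))
  }
}

#' Write a cohort spectrum table
#'
#' Rows are the 96 channels in canonical order; columns are samples.
#'
#' @param spectra List of `spectrum_vector` objects.
#' @param path Output TSV path.
#' @export
write_spectrum_tsv <- function(spectra, path) {
  m <- vapply(spectra, `[[`, numeric(96), "counts96")
  colnames(m) <- vapply(spectra, `[[`, "", "sample_id")
  df <- data.frame(channel = context_channels(), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
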