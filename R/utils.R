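# Small shared helpers.

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds up in magnitude, matching how
#' percentages are conventionally printed (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Coerce the genome argument accepted across the package (a
# synthetic_genome, a DNAStringSet, or a FASTA path) to a DNAStringSet.
as_dna_stringset <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$chromosomes)
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  stop("genome must be a synthetic_genome, DNAStringSet or FASTA path")
}

# data.frame of (chrom, start, end) -> GRanges (1-based closed input).
df_to_granges <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

# Write intervals as 0-based half-open BED.
write_bed <- function(df, path) {
  if (is.null(df) || nrow(df) == 0) {
    file.create(path)
    return(invisible(path))
  }
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Read a BED file (0-based half-open) into a 1-based closed data.frame.
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]))
}

# Deterministic child seed for a named sub-stream of a master seed.
child_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483629L
}
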