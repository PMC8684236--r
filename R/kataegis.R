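# Rainfall (inter-mutation distance) computation, kataegis detection and
# chromosome-terminal enrichment testing.
#
# Kataegis here follows the community operational definition: a run of at
# least `min_n` consecutive mutations whose mean inter-mutation distance is
# at most `max_mean_imd` (1 kb by default). Detection scans all windows of
# qualifying size per chromosome; mutations belonging to any qualifying
# window are cluster members, and maximal runs of consecutive members form
# the reported events.

#' Inter-mutation distances (rainfall points)
#'
#' Per chromosome, each mutation's distance to the previous one in
#' position order; the first mutation per chromosome has no distance.
#' Input order is irrelevant (sorting is internal); ties at the same
#' position are kept with distance 0.
#'
#' @param variants data.frame with `chrom`, `pos`, and optionally `ref`,
#'   `alt`, `type` (used for the 6-class / indel labelling).
#' @return data.frame sorted by (chrom, pos) with `distance_to_previous`
#'   (NA for the first point per chromosome) and `class` (a 6-class label
#'   or "indel").
#' @export
intermutation_distances <- function(variants) {
  if (nrow(variants) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      distance_to_previous = numeric(), class = character()))
  }
  df <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  cls <- if (all(c("ref", "alt") %in% names(df))) {
    is_snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1
    out <- rep("indel", nrow(df))
    if (any(is_snv)) out[is_snv] <- six_class(df$ref[is_snv], df$alt[is_snv])
    out
  } else {
    rep(NA_character_, nrow(df))
  }
  d <- c(NA, diff(df$pos))
  first <- !duplicated(df$chrom)
  d[first] <- NA
  data.frame(chrom = df$chrom, pos = df$pos,
             distance_to_previous = d, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect kataegis events
#'
#' Scans, per chromosome, all windows of `min_n` or more consecutive
#' mutations whose mean inter-mutation distance (window span divided by
#' window gap count) is at most `max_mean_imd`. Mutations covered by any
#' qualifying window are cluster members; maximal runs of consecutive
#' members are merged into the reported events.
#'
#' @param points data.frame with `chrom` and `pos` (e.g. from
#'   [intermutation_distances()] or any variant table).
#' @param min_n Minimum mutations per event (default 6).
#' @param max_mean_imd Maximum mean inter-mutation distance in bases
#'   (default 1000).
#' @return data.frame of events: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_mutations`, `mean_imd`.
#' @export
detect_kataegis <- function(points, min_n = 6, max_mean_imd = 1000) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_mutations = integer(),
                      mean_imd = numeric())
  if (nrow(points) == 0) return(empty)
  df <- points[order(points$chrom, points$pos), , drop = FALSE]
  events <- list()
  for (cn in unique(df$chrom)) {
    p <- df$pos[df$chrom == cn]
    n <- length(p)
    if (n < min_n) next
    member <- logical(n)
    # vectorised scan over window sizes k: mean IMD of window [i, i+k-1]
    # is (p[i+k-1] - p[i]) / (k-1); a window of one size can qualify even
    # when no window of a smaller size does, so every size is scanned
    for (k in min_n:n) {
      i <- seq_len(n - k + 1L)
      ok <- (p[i + k - 1L] - p[i]) / (k - 1L) <= max_mean_imd
      if (!any(ok)) next
      r <- rle(ok)
      re <- cumsum(r$lengths)
      rs <- re - r$lengths + 1L
      for (q in which(r$values)) {
        member[rs[q]:(re[q] + k - 1L)] <- TRUE
      }
    }
    if (!any(member)) next
    runs <- rle(member)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      a <- starts[r]; b <- ends[r]
      events[[length(events) + 1L]] <- data.frame(
        chrom = cn, start = p[a], end = p[b],
        n_mutations = b - a + 1L,
        mean_imd = (p[b] - p[a]) / (b - a))
    }
  }
  if (length(events) == 0) return(empty)
  out <- do.call(rbind, events)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write kataegis events as BED and TSV
#'
#' @param events data.frame from [detect_kataegis()].
#' @param bed_path,tsv_path Output paths (either may be NULL).
#' @export
write_kataegis <- function(events, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    write_bed(events, bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(events, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(events)
}

#' Chromosome-terminal enrichment test
#'
#' Compares the observed fraction of mutations falling in the terminal
#' windows of chromosomes (the outermost `terminal_fraction` of each
#' chromosome's non-gap span, both ends) against placements drawn
#' uniformly over the non-gap genome. The permutation p-value is
#' `(1 + #[perm >= observed]) / (n_perm + 1)`.
#'
#' The published observation this formalizes was descriptive; the test
#' itself is this package's addition.
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param genome A `synthetic_genome` (gap intervals are taken from it).
#' @param terminal_fraction Terminal window fraction per end (< 0.5).
#' @param n_perm Number of uniform placements (default 1000).
#' @param seed Optional seed for the permutation stream.
#' @return List of class `terminal_enrichment`: `observed_fraction`,
#'   `expected_fraction`, `permutation_p`, `n_permutations`,
#'   `window_definition`.
#' @export
terminal_enrichment <- function(variants, genome, terminal_fraction = 0.05,
                                n_perm = 1000, seed = NULL) {
  if (terminal_fraction >= 0.5) {
    stop("configuration error: terminal_fraction must be < 0.5")
  }
  if (!is.null(seed)) set.seed(seed)
  tw <- terminal_windows(genome, terminal_fraction)
  n <- nrow(variants)
  if (n == 0) stop("no variants to test")

  # non-gap bases per chromosome for the uniform null
  cnames <- names(genome$chromosomes)
  nongap <- stats::setNames(numeric(length(cnames)), cnames)
  for (cn in cnames) {
    L <- Biostrings::width(genome$chromosomes[cn])
    g <- genome$gaps[genome$gaps$chrom == cn, ]
    nongap[cn] <- L - sum(g$end - g$start + 1L)
  }
  # fraction of non-gap genome covered by terminal windows (windows are
  # gap-free by construction: they sit inside the non-gap span ends)
  term_bases <- stats::setNames(numeric(length(cnames)), cnames)
  for (cn in cnames) {
    w <- tw[tw$chrom == cn, ]
    term_bases[cn] <- sum(w$end - w$start + 1L)
  }
  expected <- sum(term_bases) / sum(nongap)

  in_term <- function(chrom, pos) {
    hit <- logical(length(pos))
    for (cn in unique(chrom)) {
      w <- tw[tw$chrom == cn, ]
      k <- chrom == cn
      hit[k] <- (pos[k] >= w$start[1] & pos[k] <= w$end[1]) |
        (pos[k] >= w$start[2] & pos[k] <= w$end[2])
    }
    hit
  }
  observed <- mean(in_term(variants$chrom, variants$pos))

  # permutation: n positions uniform over terminal-vs-not is a Bernoulli
  # draw with probability `expected` per position; we draw real positions
  # to stay faithful to the stated null (uniform over non-gap bases)
  perm_frac <- numeric(n_perm)
  chrom_prob <- nongap / sum(nongap)
  for (b in seq_len(n_perm)) {
    ci <- sample.int(length(cnames), n, replace = TRUE, prob = chrom_prob)
    u <- floor(stats::runif(n) * nongap[ci]) + 1
    # map the u-th non-gap base to a genomic coordinate: offset past any
    # leading gap; interior gaps shift positions upward
    pos <- integer(n)
    for (cn in unique(cnames[ci])) {
      k <- which(cnames[ci] == cn)
      g <- genome$gaps[genome$gaps$chrom == cn, ]
      g <- g[order(g$start), ]
      pk <- u[k]
      for (gi in seq_len(nrow(g))) {
        w <- g$end[gi] - g$start[gi] + 1L
        pk <- ifelse(pk >= g$start[gi], pk + w, pk)
      }
      pos[k] <- pk
    }
    perm_frac[b] <- mean(in_term(cnames[ci], pos))
  }
  p <- (1 + sum(perm_frac >= observed)) / (n_perm + 1)
  structure(list(observed_fraction = observed,
                 expected_fraction = expected,
                 permutation_p = p,
                 n_permutations = n_perm,
                 window_definition = sprintf(
                   "outermost %.1f%% of non-gap span per chromosome end",
                   100 * terminal_fraction)),
            class = "terminal_enrichment")
}

#' @export
print.terminal_enrichment <- function(x, ...) {
  cat(sprintf(
    "terminal enrichment: observed %.3f vs expected %.3f (p = %.4g, %d permutations)\n",
    x$observed_fraction, x$expected_fraction, x$permutation_p,
    x$n_permutations))
  invisible(x)
}
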