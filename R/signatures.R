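# Reference signature matrices: user-supplied TSVs plus a bundled synthetic
# catalogue used by the simulator and the test-suite.

#' Bundled synthetic mutational signatures
#'
#' A deterministic set of five synthetic 96-channel signatures with
#' well-separated shapes, used by the cohort simulator and as a stand-in
#' catalogue where a proprietary reference matrix cannot be shipped:
#'
#' * `sigA_clock` — deamination-like, strongly peaked at N\[C>T\]G channels
#'   (the classic CpG transition motif, giving ACG>ATG-type dominance).
#' * `sigB_flat` — broad, dominated by C:G>T:A and T:A>C:G mass with flat
#'   flanks; plays the role of the "featureless" dominant signature.
#' * `sigC_ca` — C>A / C>G heavy.
#' * `sigD_ta` — T>A peaked with T>G side mass.
#' * `sigE_tg` — T>G peaked at T\[T>G\]T.
#'
#' @param k Number of signatures to return (1..5, default 5).
#' @return Numeric matrix, 96 rows (canonical channel order, rownames set)
#'   by `k` columns; each column sums to 1.
#' @export
#' @examples
#' S <- synthetic_signature_matrix()
#' colSums(S)
synthetic_signature_matrix <- function(k = 5) {
  stopifnot(k >= 1, k <= 5)
  ch <- context_channels()
  grp <- rep(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), each = 16)
  f5 <- substr(ch, 1, 1)
  f3 <- substr(ch, 7, 7)

  # span-limited shapes: each signature puts mass only on its own
  # substitution groups, so exposures stay identifiable under refitting
  mk <- function(spec_fun) {
    v <- spec_fun()
    v / sum(v)
  }
  sigA <- mk(function() {
    v <- numeric(96)
    v[grp == "C>T"] <- 0.25 / 12
    v[grp == "C>T" & f3 == "G"] <- 0.75 / 4   # NpCpG deamination peaks
    v
  })
  sigB <- mk(function() {
    v <- numeric(96)
    v[grp == "C>T"] <- 0.60 / 16
    v[grp == "T>C"] <- 0.40 / 16
    v
  })
  sigC <- mk(function() {
    v <- numeric(96)
    v[grp == "C>A"] <- 0.70 / 16
    v[grp == "C>G"] <- 0.30 / 16
    v
  })
  sigD <- mk(function() {
    v <- numeric(96)
    v[grp == "T>A"] <- 0.45 / 15
    v[grp == "T>A" & f5 == "A" & f3 == "A"] <- 0.25
    v[grp == "T>G"] <- 0.30 / 16
    v
  })
  sigE <- mk(function() {
    v <- numeric(96)
    v[grp == "T>G"] <- 0.45 / 15
    v[grp == "T>G" & f5 == "T" & f3 == "T"] <- 0.40
    v[grp == "T>C"] <- 0.15 / 16
    v
  })
  m <- cbind(sigA_clock = sigA, sigB_flat = sigB, sigC_ca = sigC,
             sigD_ta = sigD, sigE_tg = sigE)[, seq_len(k), drop = FALSE]
  rownames(m) <- ch
  m
}

#' Read a reference signature matrix from TSV
#'
#' Expects 96 rows labelled with canonical channel strings (first column)
#' and one column per signature (header row of signature names). Rows are
#' reordered to canonical channel order; columns must each sum to 1 within
#' 1e-6 (they are renormalised to machine precision).
#'
#' @param path TSV path.
#' @return Numeric 96 x K matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ch <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != 96) stop("signature matrix must have 96 channel rows")
  idx <- channel_index(ch)
  m <- m[order(idx), , drop = FALSE]
  rownames(m) <- context_channels()
  cs <- colSums(m)
  if (any(m < 0) || any(abs(cs - 1) > 1e-6)) {
    stop("signature columns must be non-negative and sum to 1")
  }
  sweep(m, 2, cs, "/")
}

#' Write a signature matrix to TSV
#'
#' @param sigs 96 x K matrix with channel rownames.
#' @param path Output path.
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- data.frame(channel = rownames(sigs), sigs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand per-sample signature weights into a 96-channel sampling profile
#'
#' Weights must be non-negative and sum to at most 1. Unassigned mass
#' models mutational processes not tracked by the named weights: by
#' default it is spread equally over the *unnamed* catalogue signatures
#' (each then individually small, below the usual reporting cutoff), or
#' spread flat over the 96 channels when `background = "flat"` or no
#' unnamed signatures remain.
#'
#' @param sigs 96 x K signature matrix.
#' @param weights Named non-negative weights over columns of `sigs`,
#'   `sum(weights) <= 1`.
#' @param background How unassigned mass is distributed: `"catalogue"`
#'   (default) or `"flat"`.
#' @return Numeric length-96 probability vector.
#' @export
mixture_profile <- function(sigs, weights,
                            background = c("catalogue", "flat")) {
  background <- match.arg(background)
  if (is.null(names(weights)) || !all(names(weights) %in% colnames(sigs))) {
    stop("weights must be named by signatures present in the matrix")
  }
  if (any(weights < 0) || sum(weights) > 1 + 1e-9) {
    stop("mixture weights must be >= 0 and sum to <= 1")
  }
  rest <- 1 - sum(weights)
  unnamed <- setdiff(colnames(sigs), names(weights))
  p <- as.vector(sigs[, names(weights), drop = FALSE] %*% weights)
  if (rest > 0) {
    if (background == "catalogue" && length(unnamed) > 0) {
      p <- p + as.vector(sigs[, unnamed, drop = FALSE] %*%
                           rep(rest / length(unnamed), length(unnamed)))
    } else {
      p <- p + rest / 96
    }
  }
  stats::setNames(p / sum(p), rownames(sigs))
}
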