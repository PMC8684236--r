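# Non-negative refitting of reference mutational signatures to an observed
# 96-channel spectrum by iterative forward selection with a golden-section
# line search, mirroring the behaviour of the widely used per-sample
# refitting approach: at each round the single-signature weight change that
# most reduces the squared reconstruction error is applied; after
# convergence, weights below a discard cutoff are zeroed and the search is
# re-run restricted to the survivors.

#' Normalize a 96-channel count vector to frequencies
#'
#' Samples below `min_mutations` total are refused (too few mutations for a
#' stable refit).
#'
#' @param counts96 Numeric vector of 96 channel counts.
#' @param min_mutations Minimum total count (default 50).
#' @return Numeric vector summing to 1.
#' @export
normalize_spectrum <- function(counts96, min_mutations = 50) {
  stopifnot(length(counts96) == 96)
  if (any(!is.finite(counts96)) || any(counts96 < 0)) {
    stop("counts must be finite and non-negative")
  }
  tot <- sum(counts96)
  if (tot < min_mutations) {
    stop(sprintf("low-count sample: %d mutations < minimum %d",
                 as.integer(tot), as.integer(min_mutations)))
  }
  counts96 / tot
}

# Golden-section search for the minimum of f on [lo, hi].
.golden_section <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Reconstruct a spectrum from exposures and score the fit
#'
#' @param sigs 96 x K signature matrix.
#' @param exposures Named weight vector over (a subset of) the columns.
#' @param spectrum Observed frequency vector of length 96.
#' @return List with `reconstructed` (length-96 vector) and `sse`.
#' @export
reconstruct_and_score <- function(sigs, exposures, spectrum) {
  w <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
  if (length(exposures)) w[names(exposures)] <- exposures
  recon <- stats::setNames(as.vector(sigs %*% w), rownames(sigs))
  list(reconstructed = recon, sse = sum((spectrum - recon)^2))
}

.sse_for <- function(sigs_mat, w, spectrum) {
  sum((spectrum - as.vector(sigs_mat %*% w))^2)
}

# Forward selection over `allowed`: each round finds, by golden-section
# line search, the single-weight change that most reduces the SSE; the
# change is accepted while the improvement exceeds `tol`, and after each
# acceptance the weights of the selected signatures are refined by
# coordinate descent (repeated exact line searches) to convergence. `tol`
# therefore governs which signatures enter the model, not how precisely
# the selected ones are fitted.
.forward_select <- function(spectrum, sigs, allowed, tol, search_tol = 1e-4) {
  w <- stats::setNames(numeric(length(allowed)), allowed)
  S <- sigs[, allowed, drop = FALSE]
  sse <- .sse_for(S, w, spectrum)

  line_search <- function(w, s) {
    hi <- 1 - sum(w) + w[[s]]
    if (hi <= 0) return(NULL)
    f <- function(x) {
      w2 <- w; w2[[s]] <- x
      .sse_for(S, w2, spectrum)
    }
    .golden_section(f, 0, hi, tol = search_tol)
  }
  refine <- function(w, active, sse) {
    repeat {
      improved <- FALSE
      for (s in active) {
        opt <- line_search(w, s)
        if (!is.null(opt) && sse - opt$value > 1e-10) {
          w[[s]] <- opt$x
          sse <- opt$value
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(weights = w, sse = sse)
  }

  active <- character(0)
  repeat {
    best <- NULL
    for (s in allowed) {
      opt <- line_search(w, s)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- list(sig = s, x = opt$x, value = opt$value)
      }
    }
    if (is.null(best) || sse - best$value <= tol) break
    w[[best$sig]] <- best$x
    sse <- best$value
    active <- union(active, best$sig)
    r <- refine(w, active, sse)
    w <- r$weights
    sse <- r$sse
  }
  list(weights = w, sse = sse)
}

#' Refit signature exposures to an observed spectrum
#'
#' Greedy forward selection: at each round, for every allowed signature the
#' single-weight value in \[0, 1\] minimizing the squared reconstruction
#' error is found by golden-section search; the best change is accepted
#' while the error improvement exceeds `tol`. After convergence, weights
#' below `cutoff` are zeroed and the search is re-run restricted to the
#' survivors. Weights are non-negative and constrained to sum to at most 1;
#' optionally they are renormalized to sum to exactly 1.
#'
#' @param spectrum Frequency vector of length 96 (see
#'   [normalize_spectrum()]).
#' @param sigs 96 x K signature matrix with named columns.
#' @param allowed Character vector of signature names to consider
#'   (default: all columns).
#' @param cutoff Minimum retained weight (default 0.06).
#' @param tol Minimum SSE improvement to continue (default 1e-3).
#' @param renormalize If TRUE, rescale final nonzero weights to sum to 1.
#' @return An `exposure_vector`: list with `weights` (named, length K,
#'   zeros for unused signatures), `residual_sse`, and `reconstructed`.
#' @export
refit_exposures <- function(spectrum, sigs, allowed = colnames(sigs),
                            cutoff = 0.06, tol = 1e-3,
                            renormalize = FALSE) {
  if (any(!is.finite(spectrum))) stop("input error: non-finite spectrum entries")
  stopifnot(length(spectrum) == 96)
  if (length(allowed) == 0) stop("allowed signature set is empty")
  unknown <- setdiff(allowed, colnames(sigs))
  if (length(unknown)) {
    stop("configuration error: unknown signature name(s): ",
         paste(unknown, collapse = ", "))
  }
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")

  fit <- .forward_select(spectrum, sigs, allowed, tol)
  survivors <- names(fit$weights)[fit$weights >= cutoff]
  if (length(survivors) > 0 && length(survivors) < sum(fit$weights > 0)) {
    fit <- .forward_select(spectrum, sigs, survivors, tol)
  }
  w <- fit$weights[fit$weights >= cutoff]
  if (renormalize && length(w) > 0 && sum(w) > 0) w <- w / sum(w)
  full <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
  full[names(w)] <- w
  rs <- reconstruct_and_score(sigs, full, spectrum)
  structure(list(weights = full, residual_sse = rs$sse,
                 reconstructed = rs$reconstructed),
            class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat("exposure_vector:",
      if (length(nz)) paste(sprintf("%s=%.3f", names(nz), nz), collapse = ", ")
      else "(all zero)",
      sprintf(" [SSE %.3g]\n", x$residual_sse))
  invisible(x)
}

#' Per-sample signature contributions across a cohort
#'
#' Refits every sample's spectrum against an allowed signature set and
#' tabulates the weights, with per-signature mean and range summaries.
#' Samples below the minimum mutation count are skipped with a flag.
#'
#' @param spectra List of `spectrum_vector` objects (see
#'   [sample_spectrum()]).
#' @param sigs 96 x K signature matrix.
#' @param allowed Signature names to fit (default all).
#' @param min_mutations Minimum SNV count per sample (default 50).
#' @param cutoff,tol,renormalize Passed to [refit_exposures()].
#' @return List with `contributions` (data.frame: sample x signature
#'   weights plus `residual_sse`, `n_mutations`, `low_count`), and
#'   `summary` (data.frame: per-signature mean, min, max over fitted
#'   samples).
#' @export
cohort_contributions <- function(spectra, sigs, allowed = colnames(sigs),
                                 min_mutations = 50, cutoff = 0.06,
                                 tol = 1e-3, renormalize = FALSE) {
  if (length(spectra) == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, length(allowed),
                                  dimnames = list(NULL, allowed)))
    empty$sample_id <- character(0)
    return(list(contributions = empty,
                summary = data.frame(signature = character(),
                                     mean = numeric(), min = numeric(),
                                     max = numeric())))
  }
  rows <- lapply(spectra, function(sp) {
    n <- sum(sp$counts96)
    row <- as.list(stats::setNames(rep(NA_real_, length(allowed)), allowed))
    low <- n < min_mutations
    sse <- NA_real_
    if (!low) {
      fit <- refit_exposures(normalize_spectrum(sp$counts96, min_mutations),
                             sigs, allowed, cutoff = cutoff, tol = tol,
                             renormalize = renormalize)
      row <- as.list(fit$weights[allowed])
      sse <- fit$residual_sse
    }
    c(list(sample_id = sp$sample_id), row,
      list(residual_sse = sse, n_mutations = n, low_count = low))
  })
  contrib <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  fitted <- contrib[!contrib$low_count, allowed, drop = FALSE]
  summ <- data.frame(
    signature = allowed,
    mean = vapply(fitted, function(x) mean(x), numeric(1)),
    min = vapply(fitted, function(x) if (length(x)) min(x) else NA_real_,
                 numeric(1)),
    max = vapply(fitted, function(x) if (length(x)) max(x) else NA_real_,
                 numeric(1)))
  rownames(summ) <- NULL
  list(contributions = contrib, summary = summ)
}
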