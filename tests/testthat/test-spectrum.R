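test_that("six-class labels collapse purines onto the pyrimidine strand", {
  expect_equal(six_class("C", "T"), "C:G>T:A")
  expect_equal(six_class("G", "A"), "C:G>T:A")
  expect_equal(six_class("T", "G"), "T:A>G:C")
  expect_equal(six_class("A", "C"), "T:A>G:C")
  # complement pairs always agree
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in BASES4) {
    for (a in setdiff(BASES4, r)) {
      expect_equal(six_class(r, a), six_class(comp[[r]], comp[[a]]))
    }
  }
  expect_error(six_class("N", "A"), "A,C,G,T")
  expect_error(six_class("C", "C"), "differ")
})

test_that("the 96 channels are unique and index round-trips", {
  ch <- context_channels()
  expect_length(ch, 96)
  expect_length(unique(ch), 96)
  expect_equal(channel_index(ch), 1:96)
  expect_equal(ch[channel_index("A[C>T]G")], "A[C>T]G")
  expect_error(channel_index("A[C>C]G"), "invalid")
})

test_that("context collapse reverse-complements purine-centred triplets", {
  expect_equal(collapse_to_context96("C", "T", "A", "G"), "A[C>T]G")
  expect_equal(collapse_to_context96("G", "A", "C", "T"), "A[C>T]G")
  expect_equal(collapse_to_context96("T", "C", "A", "A"), "A[T>C]A")
  # every channel is its own reverse-complement representation's collapse
  ch <- context_channels()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_along(ch)) {
    f5 <- substr(ch[k], 1, 1); r <- substr(ch[k], 3, 3)
    a <- substr(ch[k], 5, 5); f3 <- substr(ch[k], 7, 7)
    expect_equal(collapse_to_context96(comp[[r]], comp[[a]],
                                       comp[[f3]], comp[[f5]]), ch[k])
  }
})

test_that("counts6 is the flank marginal of counts96", {
  set.seed(1)
  x <- stats::setNames(rpois(96, 5), context_channels())
  c6 <- counts6_from_96(x)
  expect_equal(sum(c6), sum(x))
  grp6 <- substr(context_channels(), 3, 5)
  manual <- tapply(as.numeric(x), grp6, sum)
  expect_equal(unname(c6), as.numeric(manual[c("C>A", "C>G", "C>T",
                                               "T>A", "T>C", "T>G")]))
})

test_that("sample_spectrum tallies single variants in the right channel", {
  genome <- Biostrings::DNAStringSet(c(chrT = "AAACGTTT"))
  v <- data.frame(chrom = "chrT", pos = 4L, ref = "C", alt = "T")
  sp <- sample_spectrum(v, genome, sample_id = "s1")
  expect_s3_class(sp, "spectrum_vector")
  expect_equal(sum(sp$counts96), 1)
  expect_equal(unname(sp$counts96["A[C>T]G"]), 1)
  expect_equal(unname(sp$counts6["C:G>T:A"]), 1)
})

test_that("sample_spectrum flags empties, ref mismatches and bad positions", {
  genome <- Biostrings::DNAStringSet(c(chrT = "AAACGTTT"))
  sp <- sample_spectrum(data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character()),
                        genome)
  expect_equal(sum(sp$counts96), 0)
  expect_true(all(is.na(sp$proportions96)))
  expect_error(sample_spectrum(
    data.frame(chrom = "chrT", pos = 4L, ref = "G", alt = "T"), genome),
    "reference allele mismatch")
  expect_error(sample_spectrum(
    data.frame(chrom = "chrT", pos = 99L, ref = "C", alt = "T"), genome),
    "beyond")
  expect_error(sample_spectrum(
    data.frame(chrom = "chrT", pos = 4L, ref = "CT", alt = "C"), genome),
    "SNVs only")
})

test_that("variants with N in the flank are excluded and counted", {
  genome <- Biostrings::DNAStringSet(c(chrT = "ANCGTTT"))
  v <- data.frame(chrom = "chrT", pos = c(3L, 5L), ref = c("C", "T"),
                  alt = c("A", "G"))
  sp <- sample_spectrum(v, genome)
  expect_equal(sp$n_excluded_N, 1L)
  expect_equal(sum(sp$counts96), 1)
})

test_that("spectra are invariant under reverse-complementing the genome", {
  set.seed(5)
  s <- paste(sample(BASES4, 3000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrT = s))
  pos <- sample(2:2999, 150)
  ref <- vapply(pos, function(p) substr(s, p, p), "")
  alt <- vapply(ref, function(r) sample(setdiff(BASES4, r), 1), "",
                USE.NAMES = FALSE)
  v <- data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt)
  sp1 <- sample_spectrum(v, genome)

  rc <- revcomp_chr(s)
  genome_rc <- Biostrings::DNAStringSet(c(chrT = rc))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_rc <- data.frame(chrom = "chrT", pos = 3000L - pos + 1L,
                     ref = unname(comp[ref]), alt = unname(comp[alt]))
  sp2 <- sample_spectrum(v_rc, genome_rc)
  expect_equal(sp1$counts96, sp2$counts96)
  expect_equal(sp1$counts6, sp2$counts6)
})

test_that("cohort spectra pool counts or average proportions", {
  genome <- Biostrings::DNAStringSet(c(chrT = "AAACGTTTACGT"))
  v1 <- data.frame(chrom = "chrT", pos = 4L, ref = "C", alt = "T")
  v2 <- data.frame(chrom = "chrT", pos = 10L, ref = "C", alt = "A")
  sp <- list(sample_spectrum(v1, genome, "a"), sample_spectrum(v2, genome, "b"))
  pooled <- cohort_spectrum(sp)
  expect_equal(sum(pooled$counts96), 2)
  avg <- cohort_spectrum(sp, method = "mean")
  expect_equal(sum(avg$proportions96), 1)
  tsv <- tempfile(fileext = ".tsv")
  write_spectrum_tsv(sp, tsv)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(back), 96)
  expect_equal(back$channel, context_channels())
  expect_equal(back$a, unname(sp[[1]]$counts96))
})
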