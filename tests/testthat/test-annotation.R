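test_that("region classification follows exonic > intronic > intergenic", {
  fx <- embed_gene(random_cds(60, seed = 1))
  model <- fx$model
  cds1 <- fx$tx$cds
  v <- data.frame(
    chrom = "chrT",
    pos = c(cds1$start[1] + 3L,                # inside CDS
            cds1$end[1] + 10L,                 # intron
            5L),                               # upstream
    ref = "A", alt = "T")
  expect_equal(classify_region(v, model),
               c("exonic", "intronic", "intergenic"))
  expect_warning(
    out <- classify_region(data.frame(chrom = "chrZ", pos = 1L, ref = "A"),
                           model),
    "absent from gene model")
  expect_equal(out, "intergenic")
})

test_that("overlapping transcripts resolve to exonic", {
  fx <- embed_gene(random_cds(60, seed = 2))
  tx2 <- fx$tx
  # second transcript whose CDS covers the first transcript's intron
  intron_mid <- fx$tx$cds$end[1] + 30L
  tx2$tx_id <- "TST.t2"; tx2$gene <- "OVL"
  tx2$exons <- tx2$cds <- data.frame(start = intron_mid - 1L,
                                     end = intron_mid + 1L)
  model <- gene_model(list(fx$tx, tx2))
  v <- data.frame(chrom = "chrT", pos = intron_mid, ref = "A")
  expect_equal(classify_region(v, model), "exonic")
})

test_that("known codon changes annotate to their printed protein changes", {
  for (strand in c("+", "-")) {
    fx <- embed_gene(random_cds(470, seed = 3), strand = strand,
                     pieces = c(600, 810),
                     planted = c("425" = "TGG", "463" = "CGG"))
    flip <- function(b) if (strand == "-") chartr("ACGT", "TGCA", b) else b

    # TGG codon, position 2, G>A: stop gained (W425X)
    g1274 <- fixture_cds_to_genome(fx, 1274L)
    r1 <- classify_effect(list(chrom = "chrT", pos = g1274,
                               ref = flip("G"), alt = flip("A")),
                          fx$model, fx$genome)
    expect_equal(r1$effect_class, "nonsense")
    expect_equal(r1$protein_change, "p.W425X")

    # CGG codon, position 2, G>A: missense (R463Q)
    g1388 <- fixture_cds_to_genome(fx, 1388L)
    r2 <- classify_effect(list(chrom = "chrT", pos = g1388,
                               ref = flip("G"), alt = flip("A")),
                          fx$model, fx$genome)
    expect_equal(r2$effect_class, "missense")
    expect_equal(r2$protein_change, "p.R463Q")
  }
})

test_that("third-base wobble changes are silent", {
  fx <- embed_gene(random_cds(50, seed = 4), planted = c("10" = "GCT"))
  g30 <- fixture_cds_to_genome(fx, 30L)  # codon 10, position 3
  r <- classify_effect(list(chrom = "chrT", pos = g30, ref = "T", alt = "C"),
                       fx$model, fx$genome)
  expect_equal(r$effect_class, "silent")
  expect_equal(r$protein_change, "p.A10A")
})

test_that("in-frame and frameshift deletions are told apart and named", {
  fx <- embed_gene(random_cds(100, seed = 5), pieces = 300,
                   planted = c("44" = "CCT", "56" = "GAT"))
  # 39-nt deletion of codons 44-56, anchored one base before codon 44
  anchor <- fixture_cds_to_genome(fx, 129L)
  s <- as.character(fx$genome[[1]])
  refdel <- substr(s, anchor, anchor + 39L)
  r <- classify_effect(list(chrom = "chrT", pos = anchor, ref = refdel,
                            alt = substr(refdel, 1, 1)),
                       fx$model, fx$genome)
  expect_equal(r$effect_class, "indel")
  expect_equal(r$protein_change, "p.P44_D56del")

  # single-base deletion: frameshift at the first affected codon
  refdel1 <- substr(s, anchor, anchor + 1L)
  r2 <- classify_effect(list(chrom = "chrT", pos = anchor, ref = refdel1,
                             alt = substr(refdel1, 1, 1)),
                        fx$model, fx$genome)
  expect_equal(r2$effect_class, "indel")
  expect_match(r2$protein_change, "^p\\.[A-Z]44fs$")

  # intergenic indel stays unannotated
  r3 <- classify_effect(list(chrom = "chrT", pos = 5L, ref = "AAA",
                             alt = "A"), fx$model, fx$genome)
  expect_equal(r3$effect_class, "none")
})

test_that("SNV effects agree with a full-protein translate-and-diff oracle", {
  set.seed(77)
  fx_plus <- embed_gene(random_cds(300, seed = 6), strand = "+",
                        pieces = c(240, 390, 270))
  fx_minus <- embed_gene(random_cds(300, seed = 6), strand = "-",
                         pieces = c(240, 390, 270))
  translate_oracle <- function(cds_seq, cds_pos, alt_cds) {
    mut <- cds_seq
    substr(mut, cds_pos, cds_pos) <- alt_cds
    p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
    p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
    codon <- (cds_pos - 1) %/% 3 + 1
    aa_ref <- substr(p_ref, codon, codon)
    aa_alt <- substr(p_alt, codon, codon)
    if (aa_alt == aa_ref) "silent" else if (aa_alt == "*") "nonsense"
    else "missense"
  }
  for (fx in list(fx_plus, fx_minus)) {
    L <- nchar(fx$cds_seq)
    cds_pos <- sample(4:(L - 3), 250)  # leave start/stop codons alone
    for (cp in cds_pos) {
      ref_cds <- substr(fx$cds_seq, cp, cp)
      alt_cds <- sample(setdiff(BASES4, ref_cds), 1)
      gpos <- fixture_cds_to_genome(fx, cp)
      flip <- function(b) if (fx$tx$strand == "-") chartr("ACGT", "TGCA", b) else b
      got <- classify_effect(list(chrom = "chrT", pos = gpos,
                                  ref = flip(ref_cds), alt = flip(alt_cds)),
                             fx$model, fx$genome)
      want <- translate_oracle(fx$cds_seq, cp, alt_cds)
      expect_equal(got$effect_class, want)
      # partition: exactly one of the three classes
      expect_true(got$effect_class %in% c("missense", "silent", "nonsense"))
      expect_match(got$protein_change, "^p\\.")
    }
  }
})

test_that("a variant and its minus-strand representation name identically", {
  cds <- random_cds(120, seed = 8)
  fx_p <- embed_gene(cds, strand = "+")
  fx_m <- embed_gene(cds, strand = "-")
  for (cp in c(50L, 151L, 300L)) {
    ref_cds <- substr(fx_p$cds_seq, cp, cp)
    alt_cds <- sample(setdiff(BASES4, ref_cds), 1)
    r_p <- classify_effect(list(chrom = "chrT",
                                pos = fixture_cds_to_genome(fx_p, cp),
                                ref = ref_cds, alt = alt_cds),
                           fx_p$model, fx_p$genome)
    r_m <- classify_effect(list(chrom = "chrT",
                                pos = fixture_cds_to_genome(fx_m, cp),
                                ref = chartr("ACGT", "TGCA", ref_cds),
                                alt = chartr("ACGT", "TGCA", alt_cds)),
                           fx_m$model, fx_m$genome)
    expect_equal(r_p$protein_change, r_m$protein_change)
    expect_equal(r_p$effect_class, r_m$effect_class)
  }
})

test_that("gene models round-trip through GFF3", {
  cfg <- small_config()
  g <- generate_reference(cfg)
  path <- tempfile(fileext = ".gff3")
  write_gff3(g$model, path)
  back <- read_gff3(path)
  expect_setequal(names(back$transcripts), names(g$model$transcripts))
  for (id in names(back$transcripts)) {
    a <- back$transcripts[[id]]; b <- g$model$transcripts[[id]]
    expect_equal(a$strand, b$strand)
    expect_equal(a$gene, b$gene)
    expect_equal(as.integer(unlist(a$cds)), as.integer(unlist(b$cds)))
  }
})

test_that("annotate_cohort fills region, effect and protein columns", {
  fx <- embed_gene(random_cds(60, seed = 9))
  v <- data.frame(sample_id = "s", chrom = "chrT",
                  pos = c(fx$tx$cds$start[1] + 3L, 5L),
                  ref = c(substr(as.character(fx$genome[[1]]),
                                 fx$tx$cds$start[1] + 3L,
                                 fx$tx$cds$start[1] + 3L), "A"),
                  alt = c("N", "T"), type = "SNV",
                  stringsAsFactors = FALSE)
  v$alt[1] <- setdiff(BASES4, v$ref[1])[1]
  ann <- annotate_cohort(v, fx$model, fx$genome)
  expect_equal(ann$region_class, c("exonic", "intergenic"))
  expect_true(ann$effect_class[1] %in% c("missense", "silent", "nonsense"))
  expect_equal(ann$effect_class[2], "none")
  expect_true(is.na(ann$protein_change[2]))
  empty <- annotate_cohort(v[0, ], fx$model, fx$genome)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("region_class", "effect_class") %in% names(empty)))
})
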