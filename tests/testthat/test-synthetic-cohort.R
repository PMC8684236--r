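test_that("reference generation is deterministic for a fixed seed", {
  cfg <- small_config(seed = 4)
  g1 <- generate_reference(cfg)
  g2 <- generate_reference(cfg)
  expect_identical(as.character(g1$chromosomes), as.character(g2$chromosomes))
  expect_identical(g1$mask, g2$mask)
  expect_identical(g1$gaps, g2$gaps)
  d1 <- tempfile(); d2 <- tempfile()
  write_reference(g1, d1)
  write_reference(g2, d2)
  expect_identical(readBin(file.path(d1, "ref.fa"), "raw", 1e7),
                   readBin(file.path(d2, "ref.fa"), "raw", 1e7))
})

test_that("different seeds change sequence content but not layout", {
  g1 <- generate_reference(small_config(seed = 1))
  g2 <- generate_reference(small_config(seed = 2))
  expect_equal(Biostrings::width(g1$chromosomes),
               Biostrings::width(g2$chromosomes))
  expect_false(identical(as.character(g1$chromosomes),
                         as.character(g2$chromosomes)))
})

test_that("a zero low-complexity setting yields an empty mask", {
  g <- generate_reference(small_config(low_complexity_per_mb = 0))
  expect_equal(nrow(g$mask), 0)
  d <- tempfile()
  write_reference(g, d)
  expect_equal(file.size(file.path(d, "mask.bed")), 0)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(chrom_lengths = c(chr1 = 500000L)),
               "at least 2 chromosomes")
  expect_error(cohort_config(chrom_lengths = c(chr1 = 500000L,
                                               chr2 = 100000L)),
               "200 kb")
  expect_error(cohort_config(terminal_fraction = 0.5), "terminal_fraction")
  expect_error(cohort_config(terminal_bias = 1.5), "rates")
  expect_error(cohort_config(signature_mixture = c(sigA_clock = 1.2)),
               "sum to <= 1")
})

test_that("the gene model has multi-exon transcripts on both strands", {
  g <- generate_reference(small_config())
  txs <- g$model$transcripts
  expect_gte(length(txs), 3)
  expect_setequal(unique(vapply(txs, `[[`, "", "strand")), c("+", "-"))
  expect_true(all(vapply(txs, function(t) nrow(t$cds) >= 2, TRUE)))
  # every CDS translates: starts ATG, ends with a stop, no internal stops
  for (tx in txs) {
    cds <- somacohort:::.cds_translation_order(tx)
    seqs <- lapply(seq_len(nrow(cds)), function(i) {
      x <- Biostrings::subseq(g$chromosomes[[tx$chrom]],
                              cds$start[i], cds$end[i])
      if (tx$strand == "-") as.character(Biostrings::reverseComplement(x))
      else as.character(x)
    })
    full <- paste(unlist(seqs), collapse = "")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(full)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("an empty cohort request plants nothing", {
  cfg <- small_config(mean_snv = 0, mean_indel = 0,
                      driver_rate_acp = 0, driver_rate_pcp = 0,
                      kataegis_spec = NULL)
  tr <- plant_somatic_mutations(generate_reference(cfg), cfg)
  expect_equal(nrow(tr$variants), 0)
  expect_equal(nrow(tr$samples), 5)
})

test_that("planting is deterministic and channel-faithful", {
  cfg <- small_config(seed = 8)
  g <- generate_reference(cfg)
  t1 <- plant_somatic_mutations(g, cfg)
  t2 <- plant_somatic_mutations(g, cfg)
  expect_identical(t1$variants, t2$variants)
  # recorded channel equals the pyrimidine-collapsed reference context,
  # checked exhaustively with direct string extraction
  v <- t1$variants[t1$variants$type == "SNV", ]
  chroms <- as.character(g$chromosomes)
  for (cn in unique(v$chrom)) {
    k <- v$chrom == cn
    f5 <- unname(substr(rep(chroms[[cn]], sum(k)), v$pos[k] - 1, v$pos[k] - 1))
    f3 <- unname(substr(rep(chroms[[cn]], sum(k)), v$pos[k] + 1, v$pos[k] + 1))
    rr <- unname(substr(rep(chroms[[cn]], sum(k)), v$pos[k], v$pos[k]))
    expect_identical(rr, v$ref[k])
    expect_identical(collapse_to_context96(v$ref[k], v$alt[k], f5, f3),
                     v$channel[k])
  }
})

test_that("a pooled single-signature cohort converges to its profile", {
  cfg <- small_config(n_acp = 1, n_pcp = 1, mean_snv = 2500, mean_indel = 0,
                      signature_mixture = c(sigE_tg = 1),
                      terminal_bias = 0, kataegis_spec = NULL,
                      driver_rate_acp = 0, driver_rate_pcp = 0,
                      burden_dispersion = 0, seed = 21)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  expect_gte(nrow(tr$variants), 4500)
  emp <- table(factor(tr$variants$channel, levels = context_channels()))
  emp <- as.numeric(emp) / sum(emp)
  sig <- synthetic_signature_matrix()[, "sigE_tg"]
  tv <- 0.5 * sum(abs(emp - sig))
  expect_lte(tv, 0.05)
})

test_that("configured kataegis clusters are planted inside their span", {
  cfg <- small_config(seed = 13)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  kat <- tr$variants[tr$variants$kataegis, ]
  expect_equal(nrow(kat), 8)
  expect_equal(unique(kat$chrom), "chr1")
  expect_length(unique(kat$sample_id), 1)
  expect_true(all(abs(kat$pos - 320000) <= 1500))
})

test_that("driver events are mutually exclusive by subtype", {
  cfg <- small_config(n_acp = 8, n_pcp = 5, seed = 2)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  drv <- tr$variants[tr$variants$driver != "none", ]
  by_sample <- split(drv$driver, drv$sample_id)
  for (d in by_sample) expect_length(unique(d), 1)
  acp_drv <- unique(drv$sample_id[drv$driver == "exon3_driver"])
  pcp_drv <- unique(drv$sample_id[drv$driver == "v600e_driver"])
  expect_equal(length(acp_drv), round(8 * cfg$driver_rate_acp))
  expect_equal(length(pcp_drv), round(5 * cfg$driver_rate_pcp))
  expect_true(all(grepl("^ACP", acp_drv)))
  expect_true(all(grepl("^PCP", pcp_drv)))
})

test_that("zero caller error reproduces the truth set exactly", {
  cfg <- zero_noise_config(seed = 6)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  emu <- emulate_caller_outputs(tr, g)
  key <- function(df) unique(paste(df$sample_id, df$chrom, df$pos,
                                   df$ref, df$alt))
  expect_setequal(key(emu$calls), key(tr$variants))
  expect_false(any(emu$calls$is_fp))
})

test_that("a caller's false negatives do not silence other callers", {
  cfg <- small_config(seed = 9,
                      caller_error = list(fn = c(A = 0.5, B = 0, C = 0),
                                          fp = c(A = 0, B = 0, C = 0)),
                      artifact_site_rate = 0)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  emu <- emulate_caller_outputs(tr, g)
  snv <- tr$variants[tr$variants$type == "SNV", ]
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$alt)
  in_a <- key(snv) %in% key(emu$calls[emu$calls$caller == "A", ])
  in_b <- key(snv) %in% key(emu$calls[emu$calls$caller == "B", ])
  expect_true(all(in_b))
  expect_gt(sum(!in_a), 0)
})

test_that("artifact sites recur in at least two normals", {
  cfg <- small_config(seed = 10)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  emu <- emulate_caller_outputs(tr, g)
  art_key <- paste(emu$artifact_sites$chrom, emu$artifact_sites$pos,
                   emu$artifact_sites$alt)
  norm <- emu$normal_calls
  support <- tapply(norm$normal_id, paste(norm$chrom, norm$pos, norm$alt),
                    function(x) length(unique(x)))
  expect_true(all(support[art_key] >= 2))
})

test_that("caller VCFs round-trip through write and read", {
  cfg <- small_config(n_acp = 1, n_pcp = 1, mean_snv = 30, mean_indel = 5,
                      seed = 12)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  dir <- tempfile()
  emu <- emulate_caller_outputs(tr, g, dir = dir)
  path <- emu$paths$tumor[["ACP01"]][["B"]]
  expect_true(file.exists(path))
  back <- read_caller_vcf(path)
  orig <- emu$calls[emu$calls$sample_id == "ACP01" & emu$calls$caller == "B", ]
  orig <- orig[order(orig$chrom, orig$pos), ]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$pos, orig$pos)
  expect_equal(back$ref, orig$ref)
  expect_equal(back$alt, orig$alt)
  expect_equal(back$NDP, orig$NDP)
  expect_equal(back$VAF, orig$VAF, tolerance = 1e-6)
  expect_equal(back$caller[1], "B")
  expect_equal(back$sample_id[1], "ACP01")
  # normal panel files exist for every sample
  expect_length(emu$paths$normal, 2)
})

test_that("truth sets serialize to JSON with the sample sheet", {
  cfg <- small_config(n_acp = 1, n_pcp = 1, mean_snv = 10, mean_indel = 2,
                      seed = 14)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_truth(tr, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(nrow(back), nrow(tr$variants))
  meta <- utils::read.delim(tp)
  expect_equal(meta$sample_id, tr$samples$sample_id)
})
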