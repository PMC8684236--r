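make_call <- function(type = "SNV", callers = "A,B", passed = TRUE,
                      vaf = 0.25, bq = 30, ndp = 20, tdp = 15, vp = NA_real_,
                      chrom = "chr1", pos = 1000L, ref = NULL, alt = NULL) {
  if (is.null(ref)) ref <- if (type == "DEL") "ATT" else "A"
  if (is.null(alt)) alt <- if (type == "DEL") "A" else
    if (type == "INS") "ATG" else "T"
  data.frame(sample_id = "T1", chrom = chrom, pos = pos, ref = ref,
             alt = alt, type = type, callers = callers,
             passed_primary = passed, normal_depth = ndp, tumor_depth = tdp,
             tumor_alt_reads = round(vaf * tdp), vaf = vaf,
             mean_base_quality = bq, indel_pvalue = vp,
             stringsAsFactors = FALSE)
}

test_that("panel membership requires the configured number of normals", {
  df <- data.frame(
    normal_id = c("n1", "n2", "n3", "n1"),
    chrom = "chr1", pos = c(100L, 100L, 100L, 200L),
    ref = "A", alt = "T")
  p2 <- build_normal_panel(df, min_supporting_normals = 2)
  expect_equal(nrow(p2$sites), 1)
  expect_equal(p2$sites$pos, 100L)
  expect_equal(p2$n_normals, 3)
  # site seen in a single normal stays out at min 2, enters at min 1
  p1 <- build_normal_panel(df, min_supporting_normals = 1)
  expect_setequal(p1$sites$pos, c(100L, 200L))
  # contradictory reference alleles are an input error
  bad <- rbind(df, data.frame(normal_id = "n2", chrom = "chr1", pos = 200L,
                              ref = "G", alt = "T"))
  expect_error(build_normal_panel(bad), "contradictory")
})

test_that("panels serialize to a sites-only VCF", {
  df <- data.frame(normal_id = c("n1", "n2"), chrom = "chr1",
                   pos = c(100L, 100L), ref = "A", alt = "T")
  p <- build_normal_panel(df, 2)
  path <- tempfile(fileext = ".vcf")
  write_panel_vcf(p, path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_true(any(grepl("^chr1\t100\t", lines)))
})

test_that("threshold rules fire exactly as printed", {
  ok <- make_call()
  d <- apply_threshold_filters(ok)
  expect_true(d$retained)
  expect_equal(d$failed_rules, "")

  expect_equal(apply_threshold_filters(make_call(vaf = 0.08))$failed_rules,
               "VAF")
  # boundary: exactly 10% passes ("not less than 10%")
  expect_true(apply_threshold_filters(make_call(vaf = 0.10))$retained)
  expect_equal(apply_threshold_filters(make_call(ndp = 14))$failed_rules,
               "DEPTH_NORMAL")
  expect_true(apply_threshold_filters(make_call(ndp = 15))$retained)
  expect_equal(apply_threshold_filters(make_call(tdp = 8))$failed_rules,
               "DEPTH_TUMOR")
  expect_equal(apply_threshold_filters(make_call(bq = 19))$failed_rules,
               "BQ")
  expect_true(apply_threshold_filters(make_call(bq = 20))$retained)
  d <- apply_threshold_filters(make_call(type = "DEL", callers = "B,C",
                                         tdp = 10, vp = 5e-4))
  expect_equal(d$failed_rules, "INDEL_DEPTH")
  d <- apply_threshold_filters(make_call(type = "DEL", callers = "B,C",
                                         tdp = 20, vp = 0.002))
  expect_equal(d$failed_rules, "INDEL_P")
  expect_true(apply_threshold_filters(
    make_call(type = "DEL", callers = "B,C", tdp = 20, vp = 0.001))$retained)
  # p-value rule only applies when caller C reported the InDel
  expect_true(apply_threshold_filters(
    make_call(type = "DEL", callers = "B", tdp = 20))$retained)
})

test_that("failures are enumerated, not short-circuited", {
  panel <- build_normal_panel(
    data.frame(normal_id = "n1", chrom = "chr1", pos = 1000L,
               ref = "A", alt = "T"), 1)
  mask <- data.frame(chrom = "chr1", start = 990L, end = 1010L)
  d <- apply_threshold_filters(make_call(vaf = 0.05, bq = 10), panel, mask)
  expect_equal(strsplit(d$failed_rules, ",")[[1]],
               c("VAF", "BQ", "PON", "MASK"))
})

test_that("deletion footprints hit masks their anchor misses", {
  mask <- data.frame(chrom = "chr1", start = 1002L, end = 1050L)
  del <- make_call(type = "DEL", callers = "B,C", tdp = 20, vp = 1e-4,
                   ref = "AGGG", alt = "A")
  expect_equal(apply_threshold_filters(del, mask = mask)$failed_rules, "MASK")
  snv <- make_call()  # same pos, single-base footprint misses the mask
  expect_true(apply_threshold_filters(snv, mask = mask)$retained)
})

test_that("an SNV carrying an InDel p-value is a schema violation", {
  expect_error(apply_threshold_filters(make_call(vp = 0.001)),
               "schema violation")
})

test_that("consensus merge unions provenance and prefers caller A evidence", {
  rec <- function(caller, pos = 500L, ref = "C", alt = "T", type = "SNV",
                  filt = ".", vp = NA_real_, ndp = 20L) {
    data.frame(sample_id = "T1", chrom = "chr1", pos = pos, ref = ref,
               alt = alt, type = type, NDP = ndp, TDP = 30L, TAD = 10L,
               VAF = 0.33, MBQ = 35, VP = vp, caller = caller,
               filter = filt, stringsAsFactors = FALSE)
  }
  m <- consensus_merge(rbind(rec("A", filt = "PASS", ndp = 21L),
                             rec("B", ndp = 19L)))
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "A,B")
  expect_true(m$passed_primary)
  expect_equal(m$normal_depth, 21L)
  expect_equal(m$evidence_source, "A")

  m2 <- consensus_merge(rec("B"))
  expect_equal(m2$callers, "B")
  expect_false(m2$passed_primary)

  m3 <- consensus_merge(rbind(
    rec("B", pos = 600L, ref = "CAA", alt = "C", type = "DEL"),
    rec("C", pos = 600L, ref = "CAA", alt = "C", type = "DEL", vp = 2e-4)))
  expect_equal(m3$callers, "B,C")
  expect_equal(m3$indel_pvalue, 2e-4)
  expect_equal(m3$evidence_source, "B")

  expect_error(consensus_merge(rbind(
    rec("B", pos = 700L, ref = "G"), rec("C", pos = 700L, ref = "GA"))),
    "conflicting reference")
})

test_that("SNVs without a primary PASS call are dropped by consensus", {
  calls <- rbind(make_call(callers = "B", passed = FALSE),
                 make_call(callers = "A,B", passed = FALSE, pos = 2000L),
                 make_call(callers = "A,B", passed = TRUE, pos = 3000L),
                 make_call(type = "DEL", callers = "B", passed = FALSE,
                           pos = 4000L, tdp = 20),
                 make_call(type = "DEL", callers = "B,C", passed = FALSE,
                           pos = 5000L, tdp = 20, vp = 1e-4))
  out <- filter_cohort(calls)
  expect_equal(out$retained, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$failed_rules[1], "CALLER_CONSENSUS")
  expect_equal(out$failed_rules[4], "CALLER_CONSENSUS")
})

test_that("the consensus filter matches a rule-by-rule oracle on random calls", {
  calls <- random_raw_calls(400, seed = 31)
  panel_sites <- data.frame(
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    pos = sample.int(100000, 60),
    alt = sample(BASES4, 60, replace = TRUE))
  panel <- structure(list(sites = cbind(panel_sites, n_support = 2L),
                          n_normals = 3L), class = "panel_of_normals")
  mask <- data.frame(chrom = "chr1",
                     start = seq(1000L, 91000L, by = 10000L),
                     end = seq(1400L, 91400L, by = 10000L))
  got <- filter_cohort(calls, panel, mask)
  want <- oracle_filter(calls, panel_sites, mask)
  expect_equal(got$retained, want$retained)
  # identical rule sets record-by-record (order-insensitive)
  split_rules <- function(x) lapply(strsplit(x, ","), sort)
  expect_equal(split_rules(got$failed_rules), split_rules(want$failed_rules))
})

test_that("raising any threshold never increases the retained count", {
  calls <- random_raw_calls(300, seed = 7)
  base <- filter_thresholds()
  n0 <- sum(filter_cohort(calls, thresholds = base)$retained)
  bump <- list(min_vaf = 0.2, min_bq = 30, min_normal_depth = 20,
               min_tumor_depth = 14, min_indel_depth = 18,
               max_indel_p = 1e-4)
  for (k in names(bump)) {
    th <- base
    th[[k]] <- bump[[k]]
    expect_lte(sum(filter_cohort(calls, thresholds = th)$retained), n0)
  }
})

test_that("no retained variant remains in the panel of normals", {
  calls <- random_raw_calls(300, seed = 17)
  panel_sites <- calls[sample.int(300, 50), c("chrom", "pos", "alt")]
  panel <- structure(list(sites = cbind(panel_sites, n_support = 1L),
                          n_normals = 2L), class = "panel_of_normals")
  out <- filter_cohort(calls, panel)
  final <- out[out$retained, ]
  expect_false(any(paste(final$chrom, final$pos, final$alt) %in%
                     paste(panel_sites$chrom, panel_sites$pos,
                           panel_sites$alt)))
})

test_that("synthetic artifact sites all enter a min-2 panel", {
  cfg <- small_config(seed = 19)
  g <- generate_reference(cfg)
  tr <- plant_somatic_mutations(g, cfg)
  emu <- emulate_caller_outputs(tr, g)
  panel <- build_normal_panel(emu$normal_calls, min_supporting_normals = 2)
  pk <- paste(panel$sites$chrom, panel$sites$pos, panel$sites$alt)
  ak <- paste(emu$artifact_sites$chrom, emu$artifact_sites$pos,
              emu$artifact_sites$alt)
  expect_true(all(ak %in% pk))
})
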