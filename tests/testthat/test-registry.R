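test_that("per-variant MAF is the exact count ratio", {
  expect_equal(maf(1299, 107928), 1299 / 107928)
  expect_equal(percent(maf(1299, 107928), 1), 1.2)
  expect_equal(maf(0, 16760), 0)
  expect_equal(maf(5, 2730), 5 / 2730)
  expect_error(maf(5, 0), "positive")
  expect_error(maf(6, 5), "0 <= alt")
})

test_that("percent rounds half away from zero at the requested precision", {
  expect_equal(percent(7 / 2730, 2), 0.26)
  expect_equal(percent(1299 / 107928, 1), 1.2)
  expect_equal(percent(0, 3), 0)
  expect_equal(percent(368 / 576, 1), 63.9)   # 63.888... rounds up
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.5), 3)       # not banker's rounding
})

test_that("cmaf pools distinct variants of one cohort", {
  store <- load_registry(cf_fixture("aprt_registry.tsv"),
                         cf_fixture("table2_decode.tsv"))
  ice <- cmaf(store$counts[store$counts$population == "Iceland", ])
  expect_equal(ice$total_alt, 1304L)
  expect_equal(ice$allele_number_used, 107928L)
  expect_equal(ice$p, 1304 / 107928)
  expect_equal(ice$p + ice$q, 1)
  expect_false(ice$mixed_an)

  irl <- cmaf(store$counts[store$counts$population == "Ireland", ])
  expect_equal(irl$p, 7 / 2730)
  expect_equal(percent(irl$p, 2), 0.26)
})

test_that("cmaf handles empty input, mixed cohorts and duplicates", {
  empty <- cmaf(data.frame(variant_id = character(), database = character(),
                           population = character(), alt_count = integer(),
                           allele_number = integer()))
  expect_equal(empty$p, 0)
  expect_equal(empty$q, 1)

  two <- data.frame(variant_id = c("a", "b"),
                    database = "deCODE",
                    population = c("Iceland", "Denmark"),
                    alt_count = c(1L, 1L), allele_number = c(10L, 10L))
  expect_error(cmaf(two), "single cohort")

  dup <- data.frame(variant_id = c("a", "a"), database = "x",
                    population = "y", alt_count = c(1L, 2L),
                    allele_number = 10L)
  expect_error(cmaf(dup), "duplicate variant_id")
})

test_that("unequal allele numbers pool as summed frequencies with the largest denominator", {
  nfe <- data.frame(variant_id = c("c.400+2dup", "c.194A>T"),
                    database = "gnomAD",
                    population = "European (Non-Finnish)",
                    alt_count = c(27L, 1L),
                    allele_number = c(128838L, 124598L))
  expect_message(f <- cmaf(nfe), "mixed allele numbers")
  expect_true(f$mixed_an)
  expect_equal(f$p, 27 / 128838 + 1 / 124598)
  expect_equal(f$allele_number_used, 128838L)
})

test_that("cmaf is additive over disjoint variant sets and dominates each MAF", {
  set.seed(11)
  for (rep in 1:25) {
    an <- sample(100:10000, 1)
    k <- sample(1:6, 1)
    alt <- sample(0:10, k, replace = TRUE)
    df <- data.frame(variant_id = paste0("v", seq_len(k)), database = "db",
                     population = "pop", alt_count = alt,
                     allele_number = an)
    f <- cmaf(df)
    expect_equal(f$p, sum(alt) / an)
    expect_gte(f$p, max(alt / an))
    expect_identical(f$p == 0, all(alt == 0))
    if (k > 1) {   # additivity over a split, common denominator
      f1 <- cmaf(df[1, , drop = FALSE])
      f2 <- cmaf(df[-1, , drop = FALSE])
      expect_equal(f$p, f1$p + f2$p)
    }
  }
})

test_that("registry and counts files round-trip through save and load", {
  store <- load_registry(cf_fixture("aprt_registry.tsv"),
                         cf_fixture("table2_decode.tsv"))
  expect_equal(nrow(store$counts), 14L)   # one row per sequenced-cohort entry
  expect_equal(nrow(store$registry), 17L)
  rp <- tempfile(fileext = ".tsv"); cp <- tempfile(fileext = ".tsv")
  save_registry(store, rp, cp)
  again <- load_registry(rp, cp)
  reg1 <- store$registry; attr(reg1, "variants") <- NULL
  reg2 <- again$registry; attr(reg2, "variants") <- NULL
  expect_identical(reg1, reg2)
  expect_identical(store$counts, again$counts)
})

test_that("count validation reports the offending rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tdatabase\tpopulation\talt_count\tallele_number",
               "v1\tdb\tpop\t5\t0"), path)
  expect_error(read_counts(path), "positive integer.*1")
  writeLines(c("variant_id\tdatabase\tpopulation\talt_count\tallele_number",
               "v1\tdb\tpop\t5\t4"), path)
  expect_error(read_counts(path), "0 <= alt")
  writeLines(c("variant_id\tdatabase\tpopulation\talt_count\tallele_number",
               "v1\tdb\tpop\t1\t10",
               "v1\tdb\tpop\t2\t10"), path)
  expect_error(read_counts(path), "duplicate")
  writeLines("variant_id\tdatabase\talt_count", path)
  expect_error(read_counts(path), "lacks required column")
  # empty file with header is a valid, empty store
  writeLines("variant_id\tdatabase\tpopulation\talt_count\tallele_number",
             path)
  expect_equal(nrow(read_counts(path)), 0L)
})

test_that("VCF export emits only rows with explicit genomic alleles", {
  rp <- tempfile(fileext = ".tsv")
  writeLines(paste(c(
    "variant_id\tcdna\tprotein\tregion\tbuild38_pos\tpaper_label\tgenomic_ref\tgenomic_alt",
    "c.194A>T\tc.194A>T\tp.(Asp65Val)\tExon 3\t16:88810550\tMissense\tT\tA",
    "c.81-3C>G\tc.81-3C>G\t\tIntron 1\t\tSplice\t\t"),
    collapse = "\n"), rp)
  store <- load_registry(rp)
  out <- tempfile(fileext = ".vcf")
  expect_warning(n <- write_vcf(store, out), "skipping c.81-3C>G")
  expect_equal(n, 1L)
  body <- grep("^#", readLines(out), value = TRUE, invert = TRUE)
  expect_match(body, "^16\t88810550\tc.194A>T\tT\tA")
})
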