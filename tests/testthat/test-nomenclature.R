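test_that("cDNA parsing recovers coordinates, offsets and edit types", {
  x <- parse_cdna("c.194A>T")
  expect_equal(x$start_pos, 194L)
  expect_equal(x$start_offset, 0L)
  expect_equal(x$edit, "substitution")
  expect_equal(c(x$ref_base, x$alt_base), c("A", "T"))

  d <- parse_cdna("c.400+2dup")
  expect_equal(d$start_pos, 400L)
  expect_equal(d$start_offset, 2L)
  expect_equal(d$edit, "duplication")

  r <- parse_cdna("c.521_523del")
  expect_equal(c(r$start_pos, r$end_pos), c(521L, 523L))
  expect_equal(r$edit, "deletion")
  expect_equal(r$start_offset, 0L)

  i <- parse_cdna("c.81-3C>G")
  expect_equal(i$start_pos, 81L)
  expect_equal(i$start_offset, -3L)
  expect_equal(i$edit, "substitution")

  ins <- parse_cdna("c.100_101insACG")
  expect_equal(ins$edit, "insertion")
  expect_equal(ins$alt_base, "ACG")
  expect_equal(parse_cdna("c.100delinsGT")$edit, "delins")
})

test_that("malformed or inconsistent cDNA descriptions are rejected", {
  expect_error(parse_cdna("c.FOO"), "FOO")
  expect_error(parse_cdna("g.194A>T"), "c\\.")
  expect_error(parse_cdna("c.194A>A"), "identical")
  expect_error(parse_cdna("c.523_521del"), "precedes")
  expect_warning(parse_cdna("c.600A>T"), "coding span")
})

test_that("whitespace inside a description is normalised away", {
  expect_identical(format(parse_cdna("c.400 + 2dup")), "c.400+2dup")
  expect_identical(format(parse_cdna(" c.194A>T ")), "c.194A>T")
})

test_that("protein parsing tags every consequence shape", {
  m <- parse_protein("p.(Asp65Val)")
  expect_equal(m$type, "missense")
  expect_equal(m$position, 65L)
  expect_equal(c(m$ref_residue, m$alt_residue), c("Asp", "Val"))

  fs <- parse_protein("p.(Ala108Glufs*3)")
  expect_equal(fs$type, "frameshift")
  expect_equal(fs$stop_distance, 3L)

  expect_equal(parse_protein("p.(Met1?)")$type, "start_loss")
  sl <- parse_protein("p.(*181Argext*?)")
  expect_equal(sl$type, "stop_loss")
  expect_true(is.na(sl$stop_distance))
  expect_equal(sl$position, 181L)

  ns <- parse_protein("p.(Trp98*)")
  expect_equal(ns$type, "nonsense")
  expect_equal(ns$position, 98L)
  expect_equal(parse_protein("p.(Phe174del)")$type, "inframe_del")
})

test_that("protein parsing rejects unknown codes and impossible codons", {
  expect_error(parse_protein("p.(Xyz65Val)"), "unknown amino acid")
  expect_error(parse_protein("p.(Asp200Val)"), "outside 1..181")
  expect_error(parse_protein("Asp65Val"), "p\\.")
  expect_error(parse_protein("p.(65Val)"), "malformed")
})

test_that("round-trip formatting is the identity on every table string", {
  for (s in table_cdna_strings) {
    expect_identical(format(parse_cdna(s)), s)
  }
  for (s in table_protein_strings) {
    expect_identical(format(parse_protein(s)), s)
  }
  # and across the packaged registry (includes the novel variants)
  reg <- read_registry(cf_fixture("aprt_registry.tsv"))
  for (v in attr(reg, "variants")) {
    expect_identical(format(v$cdna), v$cdna$raw)
    expect_identical(format(parse_cdna(format(v$cdna))), format(v$cdna))
    if (!is.null(v$protein)) {
      expect_identical(format(v$protein), v$protein$raw)
    }
  }
})

test_that("classification is deterministic and flags only canonical splice offsets", {
  expect_equal(classify_variant("c.400+2dup", "p.(Ala108Glufs*3)"),
               "splice_region")
  expect_equal(classify_variant("c.194A>T", "p.(Asp65Val)"), "missense")
  # offset -3 is outside the canonical dinucleotide
  expect_equal(classify_variant("c.81-3C>G"), "other")
  expect_equal(classify_variant("c.1A>C", "p.(Met1?)"), "start_loss")
  expect_equal(classify_variant("c.541T>C", "p.(*181Argext*?)"), "stop_loss")
  expect_equal(classify_variant("c.294G>A", "p.(Trp98*)"), "nonsense")
  expect_equal(classify_variant("c.521_523del", "p.(Phe174del)"),
               "inframe_indel")
  # out-of-frame deletion with no protein annotation
  expect_equal(classify_variant("c.521_524del"), "frameshift")
  expect_equal(classify_variant("c.23dup", "p.(Val9Glyfs*2)"), "frameshift")

  enum <- c("missense", "nonsense", "frameshift", "inframe_indel",
            "start_loss", "stop_loss", "splice_region", "other")
  reg <- read_registry(cf_fixture("aprt_registry.tsv"))
  for (v in attr(reg, "variants")) {
    expect_true(v$consequence %in% enum)
    # same input, same class
    expect_identical(v$consequence, classify_variant(v$cdna, v$protein))
  }
})

test_that("loose source-table labels are preserved next to the systematic class", {
  v <- new_variant("c.1A>C", "c.1A>C", "p.(Met1?)", "Exon 1",
                   "16:88811899", paper_label = "Nonsense")
  expect_equal(v$consequence, "start_loss")
  expect_equal(v$paper_label, "Nonsense")
  d <- new_variant("c.400+2dup", "c.400+2dup", "p.(Ala108Glufs*3)",
                   "Intron 4", paper_label = "Indel")
  expect_equal(d$consequence, "splice_region")
  expect_equal(d$paper_label, "Indel")
})

test_that("variant display joins cDNA and protein in house style", {
  v <- new_variant("c.194A>T", "c.194A>T", "p.(Asp65Val)", "Exon 3")
  expect_identical(format(v), "c.194A>T (p.(Asp65Val))")
  w <- new_variant("c.81-3C>G", "c.81-3C>G", NULL, "Intron 1")
  expect_identical(format(w), "c.81-3C>G")
})

test_that("region index and intron/exon consistency are enforced", {
  expect_error(new_variant("x", "c.194A>T", NULL, "Exon 7"), "outside 1..5")
  expect_error(new_variant("x", "c.400+2dup", NULL, "Exon 4"),
               "inconsistent")
  expect_error(new_variant("x", "c.194A>T", NULL, "Intron 3"),
               "inconsistent")
  expect_error(new_variant("x", "c.194A>T", NULL, "near exon 3"),
               "unparseable")
})
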