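test_that("coding-DNA descriptions parse into their components", {
  x <- parse_cdna("c.3244G>T")
  expect_equal(x$kind, "substitution")
  expect_equal(x$start_anchor, 3244L)
  expect_equal(x$start_offset, 0L)
  expect_equal(c(x$ref, x$alt), c("G", "T"))

  # en-dash intronic offset, as typeset in published tables
  x <- parse_cdna("c.12067–2A>G")
  expect_equal(x$kind, "substitution")
  expect_equal(x$start_anchor, 12067L)
  expect_equal(x$start_offset, -2L)

  x <- parse_cdna("c.9_10dupGG")
  expect_equal(x$kind, "duplication")
  expect_equal(c(x$start_anchor, x$end_anchor), c(9L, 10L))
  expect_equal(x$ref, "GG")

  x <- parse_cdna("c.802–8_810delinsGC")
  expect_equal(x$kind, "delins")
  expect_equal(c(x$start_anchor, x$start_offset), c(802L, -8L))
  expect_equal(c(x$end_anchor, x$end_offset), c(810L, 0L))
  expect_equal(x$alt, "GC")

  # deletions with and without stated bases are the same edit kind
  expect_equal(parse_cdna("c.871delT")$kind, "deletion")
  expect_equal(parse_cdna("c.269del")$kind, "deletion")
  expect_equal(parse_cdna("c.10_11insAC")$kind, "insertion")
})

test_that("coding-DNA parser rejects what it cannot represent", {
  expect_error(parse_cdna("g.123A>T"), "prefix")
  expect_error(parse_cdna("c.xyzA>T"), "position")
  expect_error(parse_cdna("c.100N>T"), ".")
  expect_error(parse_cdna("c.100delinsXY"), "non-ACGT")
  expect_error(parse_cdna("c.200_100del"), "follows")
})

test_that("protein descriptions parse with * and Ter unified", {
  x <- parse_protein("(p.Glu4Glyfs*41)")
  expect_equal(x$kind, "frameshift")
  expect_equal(x$position, 4L)
  expect_equal(x$fs_stop_distance, 41L)

  x <- parse_protein("(p.Ser2043ArgfsTer6)")
  expect_equal(x$kind, "frameshift")
  expect_equal(x$fs_stop_distance, 6L)

  expect_equal(parse_protein("(p.?)")$kind, "unknown")
  expect_equal(parse_protein("p.?")$kind, "unknown")
  expect_equal(parse_protein("p.Gly706Gly")$kind, "synonymous")
  expect_equal(parse_protein("p.Arg675*")$kind, "nonsense")
  expect_equal(parse_protein("p.Tyr1660Ter")$kind, "nonsense")

  # internal stray space tolerated
  x <- parse_protein("(p.Arg 4192Gly)")
  expect_equal(x$kind, "substitution")
  expect_equal(x$position, 4192L)
  expect_equal(c(x$ref, x$alt), c("Arg", "Gly"))

  expect_error(parse_protein("Val1082Leu"), "prefix")
  expect_error(parse_protein("p.Xyz12Abc"), "unrecognizable")
})

test_that("consequence classification gives protein evidence precedence", {
  # a DNA delins producing a stop-gain is nonsense, not delins
  expect_equal(classify_consequence("c.1744_1751delinsT", "p.Ile582*"),
               "nonsense")
  expect_equal(classify_consequence("c.802–8_810delinsGC", "p.?"),
               "delins")
  expect_equal(classify_consequence("c.12067–2A>G", "p.?"),
               "splice_site")
  expect_equal(classify_consequence("c.5882G>A", "p.Gly1961Glu"),
               "missense")
  expect_equal(classify_consequence("c.2118G>T", "p.Gly706Gly"),
               "synonymous")
  # intronic deletion keeps its DNA edit kind, never splice_site
  expect_equal(classify_consequence("c.1356+3_1356+6del", "p.?"),
               "deletion")
  # window boundary: within 20 bp in, beyond out
  expect_equal(classify_consequence("c.3228+13G>A", "p.?"), "splice_site")
  expect_equal(classify_consequence("c.3228+20G>A", "p.?"), "splice_site")
  expect_equal(classify_consequence("c.3228+21G>A", "p.?"),
               "intronic_other")
  # exonic substitution with unknown protein effect stays unknown
  expect_equal(classify_consequence("c.100A>G", "p.?"), "unknown")
})

test_that("narrowing the splice window never converts a protein-decided class", {
  tab2 <- load_fixture("table2")
  for (i in seq_len(nrow(tab2))) {
    p <- parse_protein(if (is.na(tab2$protein[i])) "p.?" else tab2$protein[i])
    if (p$kind == "unknown") next
    expect_identical(classify_consequence(tab2$cdna[i], tab2$protein[i], 20),
                     classify_consequence(tab2$cdna[i], tab2$protein[i], 2))
  }
})

test_that("fixture HGVS strings round-trip through parse and format", {
  tab2 <- load_fixture("table2")
  for (s in tab2$cdna) {
    expect_identical(format_cdna(parse_cdna(s)), normalize_hgvs(s))
  }
})
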