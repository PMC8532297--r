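test_that("gene-name canonicalization maps common synonyms", {
  expect_equal(canonicalize_gene_name("COI"), "cox1")
  expect_equal(canonicalize_gene_name("cox1"), "cox1")
  expect_equal(canonicalize_gene_name("ND4L"), "nad4l")
  expect_equal(canonicalize_gene_name("ND2"), "nad2")
  expect_equal(canonicalize_gene_name("CYTB"), "cob")
  expect_equal(canonicalize_gene_name("l-rRNA"), "rrnL")
  expect_equal(canonicalize_gene_name("12S ribosomal RNA"), "rrnS")
  expect_equal(canonicalize_gene_name("tRNA-Leu(UUR)"), "trnL2")
  expect_equal(canonicalize_gene_name("tRNA-Ser(AGN)"), "trnS1")
  expect_equal(canonicalize_gene_name("tRNA-Ala"), "trnA")
  expect_equal(canonicalize_gene_name("trnW"), "trnW")
  expect_equal(canonicalize_gene_name("hypothetical"), "unknown")
  # ambiguous Leu/Ser without tag stays ambiguous (rejected at record level)
  expect_equal(canonicalize_gene_name("tRNA-Leu"), "trnL")
})

test_that("parse_genbank reads a minimal record and normalizes names", {
  rec <- parse_genbank(make_gb_text())
  expect_s3_class(rec, "mito_record")
  expect_true(rec$circular)
  expect_false(rec$complete)  # fragment below the complete-genome range
  expect_equal(nchar(rec$sequence), 1600)
  expect_equal(rec$features$name, c("cox1", "trnL2"))
  expect_equal(rec$features$type, c("PCG", "tRNA"))
  expect_equal(rec$features$start, c(1L, 1540L))
  expect_equal(rec$features$strand, c("+", "-"))
})

test_that("parse_genbank rejects malformed and inconsistent records", {
  txt <- make_gb_text()
  expect_error(parse_genbank(sub("LOCUS       SYNTH01 1600", "LOCUS       SYNTH01 1601", txt)),
               "declares")
  expect_error(parse_genbank(gsub("^LOCUS.*$", "LOCOS   x", txt)), "LOCUS")
  # coordinates beyond the sequence
  bad <- make_gb_text(features = c("     CDS             1..2000",
                                   "                     /gene=\"COX1\""))
  expect_error(parse_genbank(bad), "outside")
  # two leucine tRNAs both collapsing to trnL without a tag
  dup <- make_gb_text(features = c(
    "     tRNA            10..70",
    "                     /product=\"tRNA-Leu\"",
    "     tRNA            80..140",
    "                     /product=\"tRNA-Leu\""))
  expect_error(parse_genbank(dup), "anticodon|UUR")
})

test_that("unknown features are dropped with a warning", {
  txt <- make_gb_text(features = c(
    "     CDS             1..1531",
    "                     /gene=\"COX1\"",
    "     misc_feature    1540..1580",
    "                     /note=\"repeat region\""))
  expect_warning(rec <- parse_genbank(txt), "ignoring")
  expect_equal(rec$features$name, "cox1")
})

test_that("extract_gene honours strand and circular wrap", {
  feats <- tibble::tibble(name = c("cox1", "nad2"), type = "PCG",
                          start = c(1L, 1L), end = c(6L, 6L),
                          strand = c("+", "-"))
  rec <- mito_record("t1", "ATGAAATT", feats, complete = FALSE, circular = FALSE)
  expect_equal(extract_gene(rec, "cox1"), "ATGAAA")
  expect_equal(extract_gene(rec, "nad2"), "TTTCAT")
  expect_error(extract_gene(rec, "cob"), "not annotated")
  # wrap: length-10 circular molecule, feature 9..2 -> bases 9,10,1,2
  featw <- tibble::tibble(name = "cox1", type = "PCG", start = 9L, end = 2L,
                          strand = "+")
  recw <- mito_record("t2", "ATGAAAATGC", featw, complete = FALSE, circular = TRUE)
  expect_equal(extract_gene(recw, "cox1"), "GCAT")
  expect_error(mito_record("t3", "ATGAAAATGC", featw, complete = FALSE,
                           circular = FALSE), "non-circular")
})

test_that("record validation enforces length and uniqueness invariants", {
  feats <- tibble::tibble(name = "cox1", type = "PCG", start = 1L, end = 6L,
                          strand = "+")
  expect_error(mito_record("t", "ATGAAA", feats, complete = TRUE), "sanity range")
  dup <- dplyr::bind_rows(feats, feats)
  expect_error(mito_record("t", "ATGAAATTT", dup, complete = FALSE), "duplicate")
  wrong <- tibble::tibble(name = "cox1", type = "tRNA", start = 1L, end = 6L,
                          strand = "+")
  expect_error(mito_record("t", "ATGAAA", wrong, complete = FALSE), "inconsistent")
})

test_that("taxonomy loading validates schema and uniqueness", {
  tab <- tibble::tibble(sample_id = c("a", "b"), subfamily = "S", tribe = "T",
                        genus = "G", species = c("sp1", "sp2"),
                        individual = c("a", "b"))
  tx <- load_taxonomy(tab)
  expect_equal(nrow(tx), 2)
  expect_error(load_taxonomy(dplyr::select(tab, -tribe)), "missing column")
  tab2 <- tab; tab2$tribe[1] <- ""
  expect_error(load_taxonomy(tab2), "empty rank")
  tab3 <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(load_taxonomy(tab3), "duplicated sample_id")
  # round-trip through TSV
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, tf)
  expect_equal(load_taxonomy(tf), tx)
})

test_that("aligned FASTA round-trips and rejects bad input", {
  blk <- random_block(3, 60, seed = 3)
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(blk, tf)
  back <- read_aligned_fasta(tf, gene = "cox1")
  expect_identical(back$matrix, blk$matrix)
  # ragged input
  writeLines(c(">a", "ACGT", ">b", "ACG"), tf)
  expect_error(read_aligned_fasta(tf, "cox1"), "ragged")
  # disallowed ambiguity symbol, named by sequence and column
  writeLines(c(">a", "ACGT", ">b", "ACRT"), tf)
  expect_error(read_aligned_fasta(tf, "cox1"), "'R' in sequence b, column 3")
})

test_that("genbank parse -> write -> parse is a fixed point", {
  rec <- parse_genbank(make_gb_text())
  txt <- write_genbank(rec)
  rec2 <- parse_genbank(txt)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(as.data.frame(rec2$features), as.data.frame(rec$features))
  expect_identical(write_genbank(rec2), txt)
})

test_that("reverse complement is an involution and length-preserving", {
  withr_seed(11)
  for (i in 1:5) {
    s <- random_dna(50, seed = i)
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  expect_equal(reverse_complement("ATGC-N"), "N-GCAT")
})
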