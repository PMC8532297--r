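# Two tiny in-frame PCG blocks, one rRNA, one tRNA, shared sample universe
toy_blocks <- function() {
  list(
    cox1 = make_block(c(s1 = "ATGAAA", s2 = "ATGAAG", s3 = "ATAAAA"),
                      gene = "cox1", is_coding = TRUE),
    nad2 = make_block(c(s1 = "TTATTT", s2 = "TTATTC", s3 = "TTGTTT"),
                      gene = "nad2", is_coding = TRUE),
    rrnL = make_block(c(s1 = "AATTA", s2 = "AATTA", s3 = "AATTG"), gene = "rrnL"),
    trnA = make_block(c(s1 = "ACGT", s2 = "ACGT"), gene = "trnA")
  )
}

test_that("schemes select the expected columns and charsets tile the matrix", {
  b <- toy_blocks()
  p123 <- build_supermatrix(b[c("cox1", "nad2")], "P123")
  expect_equal(ncol(p123$matrix), 12)
  expect_equal(nrow(p123$charsets), 2)
  expect_equal(p123$charsets$start, c(1L, 7L))
  expect_equal(p123$charsets$end, c(6L, 12L))
  p12 <- build_supermatrix(b[c("cox1", "nad2")], "P12")
  expect_equal(ncol(p12$matrix), 8)   # positions 1,2 of each codon
  expect_equal(paste(p12$matrix["s1", 1:4], collapse = ""), "ATAA")
  p123r <- build_supermatrix(b, "P123R")
  expect_equal(ncol(p123r$matrix), 12 + 5)
  p123rt <- build_supermatrix(b, "P123RT")
  expect_equal(ncol(p123rt$matrix), ncol(p123r$matrix) + 4)
  expect_error(build_supermatrix(b, "P99"), "arg")
  # gene-level charsets tile [1, ncol] without overlap
  cs <- p123rt$charsets
  expect_equal(cs$start, c(1L, head(cs$end, -1) + 1L))
  expect_equal(cs$end[nrow(cs)], ncol(p123rt$matrix))
})

test_that("samples missing from a block are gap-padded and reported", {
  b <- toy_blocks()
  sm <- build_supermatrix(b, "P123RT")
  expect_setequal(sm$samples, c("s1", "s2", "s3"))
  trna_cols <- sm$provenance$column[sm$provenance$gene == "trnA"]
  expect_true(all(sm$matrix["s3", trna_cols] == "-"))
  expect_equal(sm$coverage$trnA, "s3")
  # padded sample rows still have full length
  expect_true(all(nchar(apply(sm$matrix, 1, paste, collapse = "")) == ncol(sm$matrix)))
})

test_that("column provenance is an invertible map onto included columns", {
  b <- toy_blocks()
  for (scheme in c("P12", "P123", "P123RT")) {
    sm <- build_supermatrix(b, scheme)
    prov <- sm$provenance
    expect_equal(prov$column, seq_len(ncol(sm$matrix)))
    expect_false(any(duplicated(prov[c("gene", "orig_column")])))
    # every mapped column equals the original block column
    for (i in seq_len(nrow(prov))) {
      blk <- b[[prov$gene[i]]]
      shared <- intersect(rownames(blk$matrix), sm$samples)
      expect_equal(sm$matrix[shared, prov$column[i]],
                   blk$matrix[shared, prov$orig_column[i]])
    }
  }
})

test_that("P123 is exactly the interleave of P12 and the position-3 columns", {
  b <- toy_blocks()[c("cox1", "nad2")]
  p123 <- build_supermatrix(b, "P123")
  p12 <- build_supermatrix(b, "P12")
  rebuilt <- matrix(NA_character_, nrow(p123$matrix), ncol(p123$matrix),
                    dimnames = dimnames(p123$matrix))
  # place P12 columns via provenance
  for (i in seq_len(nrow(p12$provenance))) {
    pr <- p12$provenance[i, ]
    target <- p123$provenance$column[p123$provenance$gene == pr$gene &
                                     p123$provenance$orig_column == pr$orig_column]
    rebuilt[, target] <- p12$matrix[, pr$column]
  }
  pos3 <- p123$provenance[!is.na(p123$provenance$codon_pos) &
                          p123$provenance$codon_pos == 3, ]
  for (i in seq_len(nrow(pos3))) {
    blk <- b[[pos3$gene[i]]]
    rebuilt[, pos3$column[i]] <- blk$matrix[rownames(rebuilt), pos3$orig_column[i]]
  }
  expect_identical(rebuilt, p123$matrix)
})

test_that("partition export uses stride charsets that a parser recovers", {
  # single 9-column PCG -> three stride charsets
  one <- list(cox1 = make_block(c(a = "ATGAAATTT", b = "ATGAAGTTC"),
                                gene = "cox1", is_coding = TRUE))
  sm <- build_supermatrix(one, "P123")
  nex <- export_partitions(sm, "nexus_sets")
  expect_match(nex, "charset cox1_pos1 = 1-7\\\\3;", fixed = FALSE)
  expect_match(nex, "charset cox1_pos3 = 3-9\\\\3;", fixed = FALSE)
  rax <- export_partitions(sm, "raxml")
  expect_match(rax, "DNA, cox1_pos2 = 2-8\\\\3")
  # rRNA block: single contiguous charset
  smr <- build_supermatrix(toy_blocks()["rrnL"], "P123R")
  expect_match(export_partitions(smr, "nexus_sets"), "charset rrnL = 1-5;")
  # parse the emitted NEXUS back and verify the recovered column sets
  lines <- strsplit(nex, "\n")[[1]]
  defs <- grep("charset", lines, value = TRUE)
  got <- lapply(defs, function(l) {
    m <- regmatches(l, regexec("charset (\\S+) = (\\d+)-(\\d+)(\\\\(\\d+))?;", l))[[1]]
    seq(as.integer(m[3]), as.integer(m[4]),
        by = if (nzchar(m[5])) as.integer(m[6]) else 1L)
  })
  names(got) <- vapply(defs, function(l) sub(".*charset (\\S+) =.*", "\\1", l), "")
  expect_equal(got$cox1_pos1, c(1L, 4L, 7L))
  expect_equal(got$cox1_pos2, c(2L, 5L, 8L))
  expect_equal(got$cox1_pos3, c(3L, 6L, 9L))
  expect_equal(sort(unname(unlist(got))), 1:9)
})

test_that("supermatrix writers emit readable PHYLIP and FASTA", {
  sm <- build_supermatrix(toy_blocks()[c("cox1", "nad2")], "P123")
  tf <- withr::local_tempfile(fileext = ".phy")
  write_supermatrix(sm, tf, "phylip")
  lines <- readLines(tf)
  expect_equal(lines[1], "3 12")
  expect_length(lines, 4)
  tf2 <- withr::local_tempfile(fileext = ".fasta")
  write_supermatrix(sm, tf2, "fasta")
  back <- read_aligned_fasta(tf2, gene = "concat")
  expect_identical(back$matrix, sm$matrix)
})
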