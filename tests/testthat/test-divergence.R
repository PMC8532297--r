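gc5 <- genetic_code(5)

test_that("K2P components and distance follow the model formula", {
  id <- k2p("ACGT", "ACGT")
  expect_equal(id$P, 0); expect_equal(id$Q, 0); expect_equal(id$d, 0)
  tr <- k2p("AAAA", "AGAA")   # one transition in four sites
  expect_equal(tr$P, 0.25); expect_equal(tr$Q, 0)
  expect_equal(tr$d, -0.5 * log(0.5), tolerance = 1e-12)
  tv <- k2p("AAAA", "ACAA")   # one transversion in four sites
  expect_equal(tv$P, 0); expect_equal(tv$Q, 0.25)
  expect_equal(tv$d, -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
})

test_that("K2P agrees with an independent implementation and applies pairwise deletion", {
  withr_seed(14)
  for (i in 1:5) {
    a <- seq_chars(random_dna(300, seed = 50 + i))
    b <- a
    mut <- sample(300, 40)
    b[mut] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    ours <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))
    bin <- ape::as.DNAbin(rbind(x = a, y = b))
    expect_equal(ours$d, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-10)
    # the distance correction never undershoots the raw p-distance
    p_dist <- mean(a != b)
    expect_gte(ours$d, p_dist - 1e-12)
  }
  # gap/N columns are excluded pairwise
  g <- k2p("A-GTN", "AAGTA")
  expect_equal(g$sites_compared, 3L)
  # saturation yields the NA sentinel, not an error
  expect_true(is.na(k2p("AAAA", "GGGG")$d))
  expect_true(is.na(k2p("NNNN", "AAAA")$d))
})

test_that("pairwise matrix is symmetric, zero-diagonal and matches per-pair calls", {
  blk <- random_block(4, 150, seed = 4)
  D <- k2p_matrix(blk)
  expect_true(isSymmetric(unclass(D)))
  expect_equal(diag(D), stats::setNames(rep(0, 4), rownames(D)))
  seqs <- block_sequences(blk)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(D[i, j], k2p(seqs[[i]], seqs[[j]])$d)
  }
  expect_equal(attr(D, "gene"), "cox1")
})

test_that("rank-stratified means use the most specific shared rank", {
  tax <- tibble::tibble(
    sample_id = c("a1", "a2", "b", "c", "e", "d"),
    subfamily = c("S1", "S1", "S1", "S1", "S1", "S2"),
    tribe = c("T1", "T1", "T1", "T1", "T2", "T3"),
    genus = c("G1", "G1", "G1", "G2", "G4", "G5"),
    species = c("G1_s1", "G1_s1", "G1_s2", "G2_s1", "G4_s1", "G5_s1"),
    individual = c("a1", "a2", "b", "c", "e", "d"))
  ids <- tax$sample_id
  D <- matrix(0.1, 6, 6, dimnames = list(ids, ids)); diag(D) <- 0
  D["a1", "a2"] <- D["a2", "a1"] <- 0.001
  out <- rank_mean_distances(D, tax)
  expect_equal(as.character(out$rank_category),
               c("within_species", "among_species_within_genus",
                 "among_genera_within_tribe", "among_tribes_within_subfamily",
                 "between_subfamilies"))
  expect_equal(out$mean_distance[out$rank_category == "within_species"], 0.001)
  expect_equal(out$n_pairs, c(1L, 2L, 3L, 4L, 5L))
  # all fifteen unordered pairs are assigned exactly once
  expect_equal(sum(out$n_pairs) + sum(out$n_undefined), choose(6, 2))
  # worked arithmetic: three congeneric pairs
  tax3 <- tax[1:3, ]; tax3$species <- c("s1", "s2", "s3")
  D3 <- matrix(0, 3, 3, dimnames = list(ids[1:3], ids[1:3]))
  D3["a1", "a2"] <- D3["a2", "a1"] <- 0.06
  D3["a1", "b"] <- D3["b", "a1"] <- 0.08
  D3["a2", "b"] <- D3["b", "a2"] <- 0.10
  out3 <- rank_mean_distances(D3, tax3)
  expect_equal(out3$mean_distance, 0.08)
  expect_equal(out3$n_pairs, 3L)
  expect_error(rank_mean_distances(D, tax[-1, ]), "missing from taxonomy")
})

test_that("nucleotide diversity averages pairwise differences after complete deletion", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 95), strrep("C", 5))
  expect_equal(nucleotide_diversity(make_block(c(x = a, y = b))), 0.05)
  # three rows with pairwise p-distances 0.1 / 0.2 / 0.3 -> mean 0.2
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 90), strrep("C", 10))
  s3 <- paste0(strrep("G", 20), strrep("A", 80))
  blk3 <- make_block(c(p = s1, q = s2, r = s3))
  expect_equal(nucleotide_diversity(blk3), mean(c(0.1, 0.2, 0.3)))
  # a column with a gap or N anywhere is dropped for every pair
  withgap <- make_block(c(x = "A-GT", y = "AAGT", z = "CCGN"))
  expect_equal(nucleotide_diversity(withgap),
               nucleotide_diversity(make_block(c(x = "AG", y = "AG", z = "CG"))))
})

test_that("sliding windows follow the 300/25 geometry and average back to genewide pi", {
  blk <- random_block(4, 350, seed = 9, sub_rate = 0.15)
  prof <- sliding_pi(blk)
  expect_s3_class(prof, "diversity_profile")
  expect_equal(nrow(prof), 3)                       # offsets 0, 25, 50
  expect_equal(prof$midpoint, c(150.5, 175.5, 200.5))
  expect_true(all(prof$pi >= 0 & prof$pi <= 1))
  # short alignment: empty profile, genewide value retained
  short <- random_block(3, 120, seed = 10)
  expect_warning(p2 <- sliding_pi(short), "below window")
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "mean_pi"), nucleotide_diversity(short))
  # window averages are exactly the coverage-weighted column mean, and on a
  # (near) uniform-coverage alignment they reconstruct genewide pi closely
  long <- random_block(4, 3000, seed = 11, sub_rate = 0.12)
  pl <- sliding_pi(long)
  d <- mitocomp:::.pi_columns(long$matrix)
  cover <- integer(length(d))
  starts <- seq(1, length(d) - 300 + 1, by = 25)
  for (s in starts) cover[s:(s + 299)] <- cover[s:(s + 299)] + 1L
  weighted <- sum(pl$pi * 300) / sum(cover)
  expect_equal(weighted, sum(d * cover) / sum(cover), tolerance = 1e-12)
  expect_equal(weighted, mean(d), tolerance = 0.02)
  expect_equal(attr(pl, "mean_pi"), mean(d))
})

test_that("Nei-Gojobori site counts match exhaustive enumeration", {
  expect_equal(mitocomp:::.syn_sites_codon("TTT", gc5), 1 / 3)
  withr_seed(16)
  codons <- setdiff(gc5$sense_codons, character(0))
  for (cod in sample(codons, 12)) {
    expect_equal(mitocomp:::.syn_sites_codon(cod, gc5),
                 oracle_syn_sites(cod, gc5))
  }
  # four-fold third position is one full synonymous site
  expect_equal(mitocomp:::.syn_sites_codon("GGG", gc5), 1)
})

test_that("Nei-Gojobori distances behave on identical, synonymous and saturating pairs", {
  idn <- nei_gojobori("TTTAAAGGG", "TTTAAAGGG", gc5)
  expect_equal(idn$Ka, 0); expect_equal(idn$Ks, 0)
  expect_equal(idn$S + idn$N, 9)  # S + N = 3 x codons
  # one synonymous third-position change on a three-codon toy
  syn <- nei_gojobori("TTTAAAGGG", "TTCAAAGGG", gc5)
  expect_equal(syn$Sd, 1); expect_equal(syn$Nd, 0)
  expect_gt(syn$Ks, 0); expect_equal(syn$Ka, 0)
  expect_equal(syn$S, 1 / 3 + 1 / 3 + 1)
  # one nonsynonymous change
  non <- nei_gojobori("TTTAAAGGG", "TTTCAAGGG", gc5)
  expect_equal(non$Nd, 1); expect_equal(non$Sd, 0)
  expect_gt(non$Ka, 0); expect_equal(non$Ks, 0)
  # codons with gaps or N are skipped pairwise
  gap <- nei_gojobori("TTT---GGG", "TTTAAAGGG", gc5)
  expect_equal(gap$S + gap$N, 6)
  # saturation of the synonymous class yields the sentinel
  sat <- nei_gojobori("TTTAAA", "TTCAAA", gc5)
  expect_true(is.na(sat$Ks))
  # two-position difference averages both substitution pathways:
  # TTA -> CTG stays leucine along either order, so both changes are synonymous
  two <- nei_gojobori("TTAAAAGGG", "CTGAAAGGG", gc5)
  expect_equal(two$Sd, 2); expect_equal(two$Nd, 0)
})
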