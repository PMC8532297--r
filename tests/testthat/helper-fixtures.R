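# Fixtures are built in code; no binary or downloaded data.

# Deterministic random DNA string
random_dna <- function(n, seed = 1, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  withr_seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs), collapse = "")
}

# local seed without leaking RNG state into other tests
withr_seed <- function(seed) set.seed(seed)

# A small synthetic GenBank flat-file record (plain text, built in code).
make_gb_text <- function(seq_len = 1600, circular = TRUE,
                         features = NULL, name = "SYNTH01") {
  seq <- random_dna(seq_len, seed = 99)
  if (is.null(features)) {
    features <- c(
      "     CDS             1..1531",
      "                     /gene=\"COX1\"",
      "     tRNA            complement(1540..1590)",
      "                     /product=\"tRNA-Leu(UUR)\"")
  }
  pos <- seq(1, seq_len, by = 60)
  origin <- vapply(pos, function(p) {
    chunk <- substr(seq, p, min(p + 59, seq_len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", p, tolower(paste(groups, collapse = " ")))
  }, character(1))
  paste(c(
    sprintf("LOCUS       %s %d bp    DNA     %s   INV", name, seq_len,
            if (circular) "circular" else "linear"),
    "DEFINITION  synthetic test mitogenome fragment.",
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN",
    origin,
    "//"), collapse = "\n")
}

# Alignment block over a fixed generating matrix with optional mutations
make_block <- function(seqs, gene = "cox1", is_coding = FALSE, frame = 0) {
  alignment_block(seqs, gene = gene, is_coding = is_coding, frame = frame)
}

# A random alignment block: base sequence plus per-row substitutions
random_block <- function(n_samples = 4, n_sites = 120, seed = 7, gene = "cox1",
                        sub_rate = 0.1, is_coding = FALSE) {
  withr_seed(seed)
  base <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  seqs <- vapply(seq_len(n_samples), function(i) {
    x <- base
    mut <- runif(n_sites) < sub_rate
    x[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n_samples))
  make_block(seqs, gene = gene, is_coding = is_coding)
}

# Independent brute-force recomputation of Wright's ENC (oracle): written
# as direct loops over amino acids, structurally unlike enc().
oracle_enc <- function(counts, code) {
  F_vals <- list()
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    n <- sum(counts[fam])
    if (n < 2) next
    p2 <- sum((counts[fam] / n)^2)
    F_vals[[a]] <- list(k = length(fam), F = (n * p2 - 1) / (n - 1))
  }
  ks <- sort(unique(lengths(code$families)))
  Fbar <- c(); Nk <- c()
  for (k in ks) {
    Nk[as.character(k)] <- sum(lengths(code$families) == k)
    vals <- unlist(lapply(F_vals, function(x) if (x$k == k) x$F))
    Fbar[as.character(k)] <- if (length(vals)) mean(vals) else NA
  }
  Fbar[names(Fbar) == "1"] <- 1
  usable <- !is.na(Fbar) & Fbar > 0
  if (any(!usable)) {
    Fbar[!usable] <- sum(Fbar[usable] * Nk[usable]) / sum(Nk[usable])
  }
  min(sum(Nk / Fbar), length(code$sense_codons))
}

# Exhaustive single-mutation enumeration of synonymous site fraction of a
# codon (oracle for the Nei-Gojobori site counts).
oracle_syn_sites <- function(codon, code) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (mut %in% code$stops) next
      valid <- valid + 1
      if (code$aa[[mut]] == code$aa[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# small fixed ultrametric tree for informativeness tests
six_taxon_tree <- function() {
  mitocomp::read_newick(
    "(((A:0.2,B:0.2):0.3,(C:0.2,D:0.2):0.3):0.5,(E:0.6,F:0.6):0.4);")
}
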