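# Seeded mitogenome-set simulator. Sequences evolve by HKY along a fixed
# tree: the rate matrix combines a transition/transversion ratio kappa
# with (AT-rich) equilibrium base frequencies and is normalized so one
# unit of branch length is one expected substitution per site at rate
# multiplier 1. Protein-coding genes carry deterministic codon-position
# rate classes (3rd >> 1st > 2nd by default), making ground-truth
# bookkeeping exact. Alignments are gap-free; no indel or selection
# process is modelled.

#' Simulation configuration
#'
#' @param tree `phylo` tree or newick string; branch lengths are expected
#'   substitutions/site at rate multiplier 1.
#' @param seed integer seed; the simulation is bit-reproducible given
#'   `seed` + config.
#' @param base_freqs equilibrium frequencies `c(A=, C=, G=, T=)`; the
#'   default reproduces a strongly AT-biased insect mitogenome
#'   (A 40.5%, C 11.5%, G 7.8%, T 40.2%).
#' @param kappa transition/transversion rate ratio (default 4, a
#'   conventional mitochondrial-scale value).
#' @param gene_plan tibble with columns `gene`, `type`
#'   (`PCG`/`rRNA`/`tRNA`), `length` (bp; PCGs must be multiples of 3),
#'   `rate` (per-gene multiplier > 0).
#' @param codon_pos_multipliers relative rates of codon positions 1/2/3;
#'   normalized to mean 1 within each PCG. Default `c(1, 0.4, 5)`.
#' @param taxonomy taxonomy tibble ([load_taxonomy()] schema) whose
#'   `sample_id`s are exactly the tree's tips.
#' @param base_freqs_by_type optional named list (`PCG`/`rRNA`/`tRNA` ->
#'   frequency vector) overriding `base_freqs` per gene class; lets rRNAs
#'   run more AT-rich than PCGs, as real mitogenomes do.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(tree, seed = 1,
                              base_freqs = c(A = 0.405, C = 0.115, G = 0.078, T = 0.402),
                              kappa = 4,
                              gene_plan,
                              codon_pos_multipliers = c(1, 0.4, 5),
                              taxonomy = NULL,
                              base_freqs_by_type = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  check_freqs <- function(f, what) {
    if (!all(c("A", "C", "G", "T") %in% names(f)) || abs(sum(f) - 1) > 1e-8 || any(f <= 0)) {
      abort(sprintf("%s must be positive, named A/C/G/T and sum to 1", what))
    }
  }
  check_freqs(base_freqs, "base_freqs")
  for (ty in names(base_freqs_by_type %||% list())) {
    check_freqs(base_freqs_by_type[[ty]], sprintf("base_freqs_by_type$%s", ty))
  }
  gene_plan <- tibble::as_tibble(gene_plan)
  stopifnot(all(c("gene", "type", "length", "rate") %in% names(gene_plan)))
  if (any(gene_plan$length <= 0) || any(gene_plan$rate <= 0)) {
    abort("gene lengths and rate multipliers must be positive")
  }
  bad <- gene_plan$type == "PCG" & gene_plan$length %% 3 != 0
  if (any(bad)) {
    abort(sprintf("PCG length(s) not multiples of 3: %s",
                  paste(gene_plan$gene[bad], collapse = ", ")))
  }
  if (length(codon_pos_multipliers) != 3 || any(codon_pos_multipliers <= 0)) {
    abort("codon_pos_multipliers must be three positive values")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- load_taxonomy(taxonomy)
    if (!setequal(taxonomy$sample_id, tree$tip.label)) {
      abort("taxonomy sample_ids must match the tree tips exactly")
    }
  }
  structure(
    list(tree = tree, seed = as.integer(seed), base_freqs = base_freqs,
         kappa = kappa, gene_plan = gene_plan,
         codon_pos_multipliers = codon_pos_multipliers,
         taxonomy = taxonomy, base_freqs_by_type = base_freqs_by_type),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d tips, %d genes (%d PCG / %d rRNA / %d tRNA), kappa %g, seed %d\n",
              length(x$tree$tip.label), nrow(x$gene_plan),
              sum(x$gene_plan$type == "PCG"), sum(x$gene_plan$type == "rRNA"),
              sum(x$gene_plan$type == "tRNA"), x$kappa, x$seed))
  invisible(x)
}

# HKY rate matrix normalized to mean rate 1, and its symmetric
# eigendecomposition for stable transition probabilities.
.hky_decomposition <- function(freqs, kappa) {
  f <- freqs[c("A", "C", "G", "T")]
  Q <- matrix(0, 4, 4, dimnames = list(names(f), names(f)))
  for (i in names(f)) for (j in names(f)) {
    if (i == j) next
    ti <- (i %in% c("A", "G")) == (j %in% c("A", "G"))  # transition
    Q[i, j] <- (if (ti) kappa else 1) * f[[j]]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q <- Q / mu
  d_half <- sqrt(f)
  B <- diag(d_half) %*% Q %*% diag(1 / d_half)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = eig$values, U = eig$vectors, d_half = d_half)
}

.hky_pmatrix <- function(dec, t) {
  P <- diag(1 / dec$d_half) %*% dec$U %*% diag(exp(dec$values * t)) %*%
    t(dec$U) %*% diag(dec$d_half)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Simulate one site class (n sites at a common rate scale) along the tree.
.simulate_class <- function(tree, dec, freqs, n_sites, scale) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  states <- matrix(NA_integer_, n_tip + n_node, n_sites)
  root <- tr$edge[nrow(tr$edge), 1]
  f <- freqs[c("A", "C", "G", "T")]
  states[root, ] <- sample.int(4, n_sites, replace = TRUE, prob = f)
  for (i in rev(seq_len(nrow(tr$edge)))) {  # preorder
    parent <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    P <- .hky_pmatrix(dec, tr$edge.length[i] * scale)
    s <- states[parent, ]
    out <- integer(n_sites)
    for (st in 1:4) {
      idx <- which(s == st)
      if (length(idx)) out[idx] <- sample.int(4, length(idx), replace = TRUE,
                                              prob = P[st, ])
    }
    states[child, ] <- out
  }
  m <- matrix(.DNA_LETTERS[states[seq_len(n_tip), , drop = FALSE]],
              n_tip, n_sites, dimnames = list(tr$tip.label, NULL))
  m
}

#' Simulate a mitogenome set with known ground truth
#'
#' Evolves every gene of `config$gene_plan` by HKY along `config$tree`
#' (codon positions of PCGs as deterministic rate classes, normalized to
#' mean 1 within the gene), assembles per-sample records in the canonical
#' gene order, and returns the true alignments plus truth bookkeeping.
#' Deterministic given `config` (seeded internally from `config$seed`).
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_set`: list with `records` (named
#'   list of `mito_record`), `blocks` (named list of gap-free
#'   `alignment_block`s), `truth` (tree, per-gene rate multipliers,
#'   per-class rates, expected pairwise distance factors).
#' @export
simulate_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  plan <- config$gene_plan
  pos_mult <- config$codon_pos_multipliers / mean(config$codon_pos_multipliers)
  decs <- list()
  blocks <- list()
  class_rates <- list()
  for (gi in seq_len(nrow(plan))) {
    g <- plan$gene[gi]; ty <- plan$type[gi]
    L <- plan$length[gi]; r <- plan$rate[gi]
    freqs <- (config$base_freqs_by_type[[ty]] %||% config$base_freqs)
    key <- paste(ty, collapse = "")
    if (is.null(decs[[key]])) decs[[key]] <- .hky_decomposition(freqs, config$kappa)
    dec <- decs[[key]]
    if (ty == "PCG") {
      n_cod <- L %/% 3
      cols <- matrix(NA_character_, length(tree$tip.label), L,
                     dimnames = list(tree$tip.label, NULL))
      for (p in 1:3) {
        mp <- .simulate_class(tree, dec, freqs, n_cod, r * pos_mult[p])
        cols[, seq(p, L, by = 3)] <- mp[rownames(cols), ]
        class_rates[[sprintf("%s_pos%d", g, p)]] <- r * pos_mult[p]
      }
      blocks[[g]] <- alignment_block(cols, gene = g, is_coding = TRUE, frame = 0)
    } else {
      m <- .simulate_class(tree, dec, freqs, L, r)
      blocks[[g]] <- alignment_block(m[tree$tip.label, , drop = FALSE], gene = g)
      class_rates[[g]] <- r
    }
  }
  order_all <- intersect(mito_gene_order("all"), names(blocks))
  tax <- config$taxonomy
  records <- lapply(tree$tip.label, function(id) {
    seqs <- vapply(order_all, function(g) {
      paste(blocks[[g]]$matrix[id, ], collapse = "")
    }, character(1))
    ends <- cumsum(nchar(seqs))
    starts <- ends - nchar(seqs) + 1L
    features <- tibble(name = order_all, type = gene_type_of(order_all),
                       start = starts, end = ends, strand = "+")
    trow <- if (!is.null(tax)) as.list(tax[tax$sample_id == id, ]) else NULL
    total <- sum(nchar(seqs))
    mito_record(id, paste(seqs, collapse = ""), features, taxonomy = trow,
                circular = TRUE,
                complete = total >= 14000 && total <= 17000)
  })
  names(records) <- tree$tip.label
  structure(
    list(records = records, blocks = blocks,
         truth = list(tree = tree,
                      gene_rates = stats::setNames(plan$rate, plan$gene),
                      class_rates = unlist(class_rates),
                      base_freqs = config$base_freqs,
                      kappa = config$kappa),
         config = config),
    class = "simulated_set")
}

#' @export
print.simulated_set <- function(x, ...) {
  cat(sprintf("<simulated_set> %d samples, %d gene blocks, %d bp per genome\n",
              length(x$records), length(x$blocks),
              nchar(x$records[[1]]$sequence)))
  invisible(x)
}

# Nested ultrametric clade: children are (label or sub-newick) strings that
# stand at `child_height`; the clade node sits at `height`.
.clade <- function(children, child_heights, height) {
  sprintf("(%s)", paste0(children, ":", format(height - child_heights, digits = 12),
                         collapse = ","))
}

#' Frozen study-like simulation configuration
#'
#' A 30-tip ultrametric tree with two subfamilies, six tribes, genera of
#' 1-3 species and one species sampled as six conspecific individuals
#' (terminal branches 0.001, i.e. near-zero intraspecific divergence).
#' Clade heights: species 0.012, genus 0.03, tribe 0.05, root 0.075 --
#' chosen so rank-stratified K2P means span roughly 0.002 to 0.15 without
#' saturating third codon positions. Thirteen PCGs carry rate multipliers
#' from 0.6 (slowest, labelled `nad5`-like) to 1.9 (fastest, `nad6`-like);
#' the two rRNAs evolve slowly with a more AT-rich composition; the 22
#' tRNAs are 65-72 bp at a low multiplier.
#'
#' @param seed seed stored in the config (default 1).
#' @return a [simulation_config()].
#' @export
paper_like_config <- function(seed = 1) {
  h_ind <- 0.001; h_sp <- 0.012; h_gen <- 0.03; h_tribe <- 0.05; h_root <- 0.075
  genus <- function(ids) {
    if (length(ids) == 1) return(list(nwk = ids, h = 0))
    list(nwk = .clade(ids, rep(0, length(ids)), h_sp), h = h_sp)
  }
  tribe <- function(genera) {
    if (length(genera) == 1) return(genera[[1]])  # single-genus tribe: no extra node
    nwk <- vapply(genera, `[[`, character(1), "nwk")
    hs <- vapply(genera, `[[`, numeric(1), "h")
    list(nwk = .clade(nwk, hs, h_gen), h = h_gen)
  }
  subfam <- function(tribes) {
    nwk <- vapply(tribes, `[[`, character(1), "nwk")
    hs <- vapply(tribes, `[[`, numeric(1), "h")
    list(nwk = .clade(nwk, hs, h_tribe), h = h_tribe)
  }
  # conspecific series: six individuals of one species
  consp <- list(nwk = .clade(sprintf("GE1_sp1_i%d", 1:6), rep(0, 6), h_ind), h = h_ind)
  sf1 <- subfam(list(
    tribe(list(genus(sprintf("GA1_sp%d_i1", 1:3)), genus(sprintf("GA2_sp%d_i1", 1:2)))),
    tribe(list(genus(sprintf("GB1_sp%d_i1", 1:3)), genus(sprintf("GB2_sp%d_i1", 1:2))))
  ))
  gen_GE1 <- list(nwk = .clade(c(consp$nwk, "GE1_sp2_i1", "GE1_sp3_i1"),
                               c(consp$h, 0, 0), h_sp), h = h_sp)
  sf2 <- subfam(list(
    tribe(list(gen_GE1)),
    tribe(list(genus(sprintf("GF1_sp%d_i1", 1:3)), genus(sprintf("GF2_sp%d_i1", 1:2)))),
    tribe(list(genus(sprintf("GH1_sp%d_i1", 1:2)), genus(sprintf("GH2_sp%d_i1", 1:2)))),
    tribe(list(genus(sprintf("GJ1_sp%d_i1", 1:2)), genus("GJ2_sp1_i1")))
  ))
  newick <- paste0(.clade(c(sf1$nwk, sf2$nwk), c(sf1$h, sf2$h), h_root), ";")
  tree <- read_newick(newick)

  ids <- tree$tip.label
  parts <- strsplit(ids, "_", fixed = TRUE)
  genus_of <- vapply(parts, `[[`, character(1), 1)
  tribe_of <- paste0("Tribe_", substr(genus_of, 1, 2))
  subfam_of <- ifelse(substr(genus_of, 2, 2) %in% c("A", "B"), "SubfamilyI", "SubfamilyII")
  taxonomy <- tibble(
    sample_id = ids,
    subfamily = subfam_of,
    tribe = tribe_of,
    genus = genus_of,
    species = paste(genus_of, vapply(parts, `[[`, character(1), 2), sep = "_"),
    individual = ids
  )

  gene_plan <- dplyr::bind_rows(
    tibble(gene = c("cox1", "cox2", "atp8", "atp6", "cox3", "nad3", "nad5",
                    "nad4", "nad4l", "nad6", "cob", "nad1", "nad2"),
           type = "PCG",
           length = c(1536, 684, 165, 678, 789, 354, 1737, 1341, 294, 531,
                      1137, 942, 1023),
           rate = c(0.75, 0.85, 1.5, 1.2, 0.95, 1.3, 0.6, 0.8, 0.9, 1.9,
                    1.0, 1.05, 1.4)),
    tibble(gene = c("rrnL", "rrnS"), type = "rRNA",
           length = c(1350, 780), rate = c(0.55, 0.5)),
    tibble(gene = mito_gene_order("tRNA"), type = "tRNA",
           length = rep(c(65, 66, 67, 68, 69, 70, 71, 72), length.out = 22),
           rate = 0.35)
  )
  simulation_config(
    tree = tree, seed = seed, gene_plan = gene_plan,
    base_freqs_by_type = list(
      rRNA = c(A = 0.43, C = 0.075, G = 0.075, T = 0.42),
      tRNA = c(A = 0.42, C = 0.09, G = 0.085, T = 0.405)
    ),
    taxonomy = taxonomy
  )
}

#' Write a simulated set to plain-file outputs
#'
#' Emits per-gene FASTA alignments, GenBank flat files per record, a
#' taxonomy TSV and a truth JSON under `dir`.
#'
#' @param sim a `simulated_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_simulated_set <- function(sim, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "records"), recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$blocks)) {
    write_fasta(sim$blocks[[g]], file.path(dir, "alignments", paste0(g, ".fasta")))
  }
  for (rec in sim$records) {
    write_genbank(rec, file.path(dir, "records", paste0(rec$sample_id, ".gb")))
  }
  if (!is.null(sim$config$taxonomy)) {
    readr::write_tsv(sim$config$taxonomy, file.path(dir, "taxonomy.tsv"))
  }
  truth <- list(newick = write_newick(sim$truth$tree),
                gene_rates = as.list(sim$truth$gene_rates),
                class_rates = as.list(sim$truth$class_rates),
                kappa = sim$truth$kappa,
                base_freqs = as.list(sim$truth$base_freqs))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
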