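# Pairwise divergence: Kimura-2-parameter distances (pairwise deletion),
# rank-stratified distance means, nucleotide diversity (complete deletion,
# the diversity-software convention), and Nei-Gojobori (1986) Ka/Ks.

.RANK_LEVELS <- c("within_species", "among_species_within_genus",
                  "among_genera_within_tribe", "among_tribes_within_subfamily",
                  "between_subfamilies")

#' Kimura-2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries `-` or `N` are excluded (pairwise
#' deletion). `P` and `Q` are the transition and transversion proportions;
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Saturated pairs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) and pairs with no comparable sites
#' return `d = NA` (sentinel) rather than an error.
#'
#' @param seq_a,seq_b aligned DNA strings (or character vectors of bases)
#'   of equal length.
#' @return one-row tibble with `P`, `Q`, `sites_compared`, `d`.
#' @export
#' @examples
#' k2p("AAAA", "AGAA")$d  # -0.5 * log(0.5)
k2p <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1) seq_chars(seq_a) else toupper(seq_a)
  b <- if (length(seq_b) == 1) seq_chars(seq_b) else toupper(seq_b)
  if (length(a) != length(b)) abort("sequences must be aligned to equal length")
  ok <- a %in% .DNA_LETTERS & b %in% .DNA_LETTERS
  n <- sum(ok)
  if (n == 0) {
    return(tibble(P = NA_real_, Q = NA_real_, sites_compared = 0L, d = NA_real_))
  }
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  tibble(P = P, Q = Q, sites_compared = as.integer(n), d = d)
}

#' Pairwise K2P distance matrix for an alignment block
#'
#' @param block an `alignment_block` with at least two samples.
#' @return symmetric numeric matrix (class `k2p_matrix`) with zero
#'   diagonal; saturated/undefined pairs are `NA`. The gene symbol is
#'   stored in the `"gene"` attribute.
#' @export
k2p_matrix <- function(block) {
  m <- block$matrix
  if (nrow(m) < 2) abort("need at least two samples")
  ids <- rownames(m)
  D <- matrix(0, nrow(m), nrow(m), dimnames = list(ids, ids))
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq(i + 1, nrow(m))) {
      D[i, j] <- D[j, i] <- k2p(m[i, ], m[j, ])$d
    }
  }
  structure(D, gene = block$gene, class = c("k2p_matrix", class(D)))
}

#' Assign each pair of samples to its most specific shared rank
#' @keywords internal
rank_category <- function(tax_a, tax_b) {
  dplyr::case_when(
    tax_a$species == tax_b$species & tax_a$genus == tax_b$genus ~ "within_species",
    tax_a$genus == tax_b$genus & tax_a$tribe == tax_b$tribe ~ "among_species_within_genus",
    tax_a$tribe == tax_b$tribe ~ "among_genera_within_tribe",
    tax_a$subfamily == tax_b$subfamily ~ "among_tribes_within_subfamily",
    TRUE ~ "between_subfamilies"
  )
}

#' Rank-stratified mean genetic distances
#'
#' Every unordered pair of samples is assigned to exactly one of five
#' categories by the most specific taxonomic rank the two samples share
#' (within species < among species within genus < among genera within
#' tribe < among tribes within subfamily < between subfamilies); the mean
#' distance per category is reported over defined (unsaturated) pairs.
#'
#' @param dm distance matrix from [k2p_matrix()] (or any labelled
#'   symmetric matrix).
#' @param taxonomy taxonomy tibble covering all matrix labels.
#' @return tibble with `gene`, `rank_category` (ordered factor),
#'   `mean_distance`, `n_pairs`, `n_undefined`; categories with zero pairs
#'   are omitted.
#' @export
rank_mean_distances <- function(dm, taxonomy) {
  ids <- rownames(dm)
  miss <- setdiff(ids, taxonomy$sample_id)
  if (length(miss)) abort(sprintf("samples missing from taxonomy: %s",
                                  paste(miss, collapse = ", ")))
  tx <- taxonomy[match(ids, taxonomy$sample_id), ]
  pairs <- utils::combn(seq_along(ids), 2)
  cat_of <- rank_category(tx[pairs[1, ], ], tx[pairs[2, ], ])
  d <- dm[cbind(pairs[1, ], pairs[2, ])]
  tibble(rank_category = cat_of, d = d) |>
    dplyr::group_by(.data$rank_category) |>
    dplyr::summarise(mean_distance = mean(.data$d, na.rm = TRUE),
                     n_pairs = sum(!is.na(.data$d)),
                     n_undefined = sum(is.na(.data$d)), .groups = "drop") |>
    dplyr::mutate(rank_category = factor(.data$rank_category, levels = .RANK_LEVELS),
                  gene = attr(dm, "gene") %||% NA_character_, .before = 1) |>
    dplyr::arrange(.data$rank_category)
}

# Per-column mean pairwise difference after complete deletion of columns
# containing gaps or N. Returns the column-wise diversity vector.
.pi_columns <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% .DNA_LETTERS))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  if (ncol(m) == 0) return(numeric(0))
  mismatches <- numeric(ncol(m))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      mismatches <- mismatches + (m[i, ] != m[j, ])
    }
  }
  mismatches / n_pairs
}

#' Whole-gene nucleotide diversity
#'
#' Columns containing any gap or `N` are removed first (complete
#' deletion); the diversity is the mean over all unordered sequence pairs
#' of the per-site difference proportion.
#'
#' @param block an `alignment_block` with at least two samples.
#' @return nucleotide diversity in `[0, 1]` (`NA` with no usable columns).
#' @export
nucleotide_diversity <- function(block) {
  if (nrow(block$matrix) < 2) abort("need at least two samples")
  d <- .pi_columns(block$matrix)
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows are laid on gap-stripped alignment columns (complete deletion),
#' reported at the window midpoint. With usable length `L`, the profile
#' has `floor((L - window)/step) + 1` windows.
#'
#' @param block an `alignment_block`.
#' @param window window length in sites (default 300).
#' @param step step size in sites (default 25).
#' @return object of class `diversity_profile`: a tibble with `gene`,
#'   `midpoint`, `pi`; whole-gene diversity in attribute `mean_pi`. With
#'   usable length below `window` the profile is empty (with a warning)
#'   and only `mean_pi` is informative.
#' @export
sliding_pi <- function(block, window = 300, step = 25) {
  stopifnot(window > step, step > 0)
  d <- .pi_columns(block$matrix)
  L <- length(d)
  mean_pi <- if (L > 0) mean(d) else NA_real_
  if (L < window) {
    warn(sprintf("%s: usable length %d below window %d; empty profile",
                 block$gene, L, window))
    prof <- tibble(gene = character(), midpoint = numeric(), pi = numeric())
  } else {
    starts <- seq(1, L - window + 1, by = step)
    prof <- tibble(
      gene = block$gene,
      midpoint = starts + (window - 1) / 2,
      pi = vapply(starts, function(s) mean(d[s:(s + window - 1)]), numeric(1))
    )
  }
  structure(prof, mean_pi = mean_pi, window = window, step = step,
            class = c("diversity_profile", class(prof)))
}

## ---- Nei-Gojobori (1986) -------------------------------------------------

# Synonymous-site fraction of one codon: at each position, among the three
# single-base changes, those creating a stop codon are dropped from both
# numerator and denominator, so the three positions always contribute one
# site each and S + N = 3 per codon.
.syn_sites_codon <- function(codon, code) {
  aa0 <- code$aa[[codon]]
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    muts <- setdiff(.DNA_LETTERS, orig)
    alt <- vapply(muts, function(b) {
      x <- codon; substr(x, pos, pos) <- b; x
    }, character(1))
    keep <- !(alt %in% code$stops)
    if (!any(keep)) next  # position contributes a full nonsynonymous site
    s <- s + sum(code$aa[alt[keep]] == aa0) / sum(keep)
  }
  s
}

# Observed synonymous/nonsynonymous differences between two codons,
# averaged over all substitution pathways that avoid stop codons.
.codon_differences <- function(ca, cb, code) {
  pos <- which(seq_chars(ca) != seq_chars(cb))
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  paths <- if (k == 1) list(pos) else {
    perms <- if (k == 2) list(pos, rev(pos)) else {
      idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3), ]
      lapply(seq_len(nrow(idx)), function(i) pos[as.integer(idx[i, ])])
    }
    perms
  }
  tally <- list()
  for (p in paths) {
    cur <- ca
    sd <- 0; nd <- 0; blocked <- FALSE
    for (site in p) {
      nxt <- cur
      substr(nxt, site, site) <- substr(cb, site, site)
      if (nxt %in% code$stops) { blocked <- TRUE; break }
      if (code$aa[[nxt]] == code$aa[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tally[[length(tally) + 1]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  open <- Filter(function(t) !t$blocked, tally)
  if (!length(open)) open <- tally  # all pathways blocked: fall back to all
  c(sd = mean(vapply(open, `[[`, numeric(1), "sd")),
    nd = mean(vapply(open, `[[`, numeric(1), "nd")))
}

#' Nei-Gojobori Ka/Ks between two aligned coding sequences
#'
#' Counting method of Nei & Gojobori (1986): synonymous site fractions per
#' codon from exhaustive single-base mutation enumeration (averaged between
#' the two sequences); observed differences averaged over all substitution
#' pathways avoiding stop codons; proportions Jukes-Cantor corrected,
#' `d = -3/4 log(1 - 4p/3)`. Codons containing gaps, `N` or a stop in
#' either sequence are skipped pairwise.
#'
#' @param cds_a,cds_b aligned in-frame DNA strings of equal length.
#' @param code a [genetic_code()].
#' @return one-row tibble with `S`, `N` (site counts), `Sd`, `Nd`
#'   (difference counts), `ps`, `pn`, `Ks`, `Ka`, `ka_ks`. Saturation
#'   (`p >= 3/4`) or `S = 0` yield `NA` sentinels.
#' @export
nei_gojobori <- function(cds_a, cds_b, code = genetic_code(5)) {
  if (nchar(cds_a) != nchar(cds_b)) abort("sequences must be aligned to equal length")
  cod_a <- split_codons(cds_a, warn = FALSE)
  cod_b <- split_codons(cds_b, warn = FALSE)
  usable <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b) &
    !(cod_a %in% code$stops) & !(cod_b %in% code$stops)
  cod_a <- cod_a[usable]; cod_b <- cod_b[usable]
  if (!length(cod_a)) abort("no comparable codons")
  # per-codon site fractions depend only on the codon: tabulate once
  syn_tab <- vapply(code$sense_codons, .syn_sites_codon, numeric(1), code = code)
  S <- (sum(syn_tab[cod_a]) + sum(syn_tab[cod_b])) / 2
  N <- 3 * length(cod_a) - S
  # pathway averaging depends only on the codon pair: compute unique pairs
  pair_key <- paste(cod_a, cod_b)
  uniq <- !duplicated(pair_key)
  diffs_u <- vapply(which(uniq), function(i) {
    .codon_differences(cod_a[i], cod_b[i], code)
  }, numeric(2))
  colnames(diffs_u) <- pair_key[uniq]
  Sd <- sum(diffs_u["sd", pair_key]); Nd <- sum(diffs_u["nd", pair_key])
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- jc(ps); Ka <- jc(pn)
  tibble(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
         Ks = Ks, Ka = Ka,
         ka_ks = ifelse(!is.na(Ks) & Ks > 0 & !is.na(Ka), Ka / Ks, NA_real_))
}
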