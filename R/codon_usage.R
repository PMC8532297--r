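# Codon-usage bias statistics under an injected genetic code (default:
# invertebrate mitochondrial, NCBI table 5): RSCU, Wright's effective
# number of codons (ENC), the codon bias index (CBI) and GC3s.

#' Count codon usage over one or more in-frame CDS
#'
#' Stop codons and any codon containing `N` or `-` are excluded; internal
#' stop codons raise a warning before exclusion. Trailing partial codons
#' are dropped.
#'
#' @param cds_list character vector (or list) of in-frame CDS strings.
#' @param code a [genetic_code()].
#' @return named integer vector over the 64 codons (stops stay zero).
#' @export
codon_counts <- function(cds_list, code = genetic_code(5)) {
  cds_list <- unlist(cds_list, use.names = FALSE)
  if (any(nchar(cds_list) < 3)) abort("CDS shorter than one codon")
  counts <- stats::setNames(integer(length(code$codons)), code$codons)
  for (cds in cds_list) {
    cod <- split_codons(cds, warn = FALSE)
    clean <- grepl("^[ACGT]{3}$", cod)
    cod <- cod[clean]
    is_stop <- cod %in% code$stops
    # a stop anywhere but the final codon is an internal stop
    if (any(is_stop[-length(is_stop)])) {
      warn(sprintf("%d internal stop codon(s) excluded from counts",
                   sum(is_stop[-length(is_stop)])))
    }
    cod <- cod[!is_stop]
    tab <- table(factor(cod, levels = code$codons))
    counts <- counts + as.integer(tab)
  }
  counts
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = observed(c) / (family total / family size)`. Codons of a
#' family with zero total usage get `NA` (undefined), not 0; a codon that
#' is absent while its family is observed gets 0.
#'
#' @param counts codon counts from [codon_counts()].
#' @param code a [genetic_code()].
#' @return tibble with `codon`, `amino_acid`, `count`, `rscu`.
#' @export
rscu <- function(counts, code = genetic_code(5)) {
  purrr::map_dfr(names(code$families), function(a) {
    fam <- code$families[[a]]
    n <- counts[fam]
    tot <- sum(n)
    tibble(codon = fam, amino_acid = a, count = as.integer(n),
           rscu = if (tot == 0) NA_real_ else n / (tot / length(fam)))
  }) |>
    dplyr::arrange(.data$amino_acid, .data$codon)
}

# Wright's homozygosity estimate for one amino acid: requires total count
# n >= 2; F = (n * sum(p^2) - 1) / (n - 1).
.wright_F <- function(n_codons) {
  n <- sum(n_codons)
  if (n < 2) return(NA_real_)
  p <- n_codons / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (ENC)
#'
#' Wright's statistic generalized to the active genetic code: families are
#' grouped by size k; `F̄_k` is the mean homozygosity over amino acids of
#' that size with at least two observed codons, and
#' `ENC = sum_k N_k / F̄_k` with `N_k` the number of size-k families
#' (table 5: `12/F̄2 + 6/F̄4 + 1/F̄6 + 1/F̄8`). A size class with no usable
#' (or non-positive) `F̄` is imputed as the weighted mean of the available
#' classes, weights = class family counts. The result is capped at the
#' sense-codon count (62 for table 5); uniform usage attains the cap.
#'
#' @inheritParams rscu
#' @return ENC value, or `NA` when no family is observable.
#' @export
enc <- function(counts, code = genetic_code(5)) {
  sizes <- lengths(code$families)
  F_by_aa <- vapply(code$families, function(fam) .wright_F(counts[fam]), numeric(1))
  classes <- sort(unique(sizes))
  Fbar <- vapply(classes, function(k) {
    v <- F_by_aa[sizes == k & !is.na(F_by_aa)]
    if (!length(v)) return(NA_real_)
    mean(v)
  }, numeric(1))
  names(Fbar) <- classes
  Nk <- vapply(classes, function(k) sum(sizes == k), numeric(1))
  # single-codon families contribute F = 1 by definition
  Fbar[classes == 1] <- 1
  usable <- !is.na(Fbar) & Fbar > 0
  if (!any(usable & classes > 1)) return(NA_real_)
  if (any(!usable)) {
    Fbar[!usable] <- sum(Fbar[usable] * Nk[usable]) / sum(Nk[usable])
  }
  min(sum(Nk / Fbar), length(code$sense_codons))
}

#' Most frequent synonym per family (optimal codons for CBI)
#'
#' @inheritParams rscu
#' @return named character vector, amino acid -> codon, for families with
#'   at least two codons; ties broken lexicographically.
#' @export
optimal_codons <- function(counts, code = genetic_code(5)) {
  fams <- code$families[lengths(code$families) >= 2]
  vapply(fams, function(fam) {
    fam <- sort(fam)
    fam[which.max(counts[fam])]
  }, character(1))
}

#' Codon bias index (CBI)
#'
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)` over multi-codon families,
#' where `N_tot` is the total codon count in those families, `N_opt` the
#' count falling on the designated optimal codons, and
#' `N_ran = sum_a n_a / k_a` the count expected under uniform synonym
#' usage. 0 under uniform usage, 1 when only optimal codons are used.
#'
#' @inheritParams rscu
#' @param optimal named character vector amino acid -> optimal codon, one
#'   per multi-codon family (see [optimal_codons()]).
#' @return CBI value; `NA` when `N_tot == N_ran` (degenerate).
#' @export
cbi <- function(counts, code = genetic_code(5), optimal = optimal_codons(counts, code)) {
  fams <- code$families[lengths(code$families) >= 2]
  if (!all(names(fams) %in% names(optimal))) {
    abort("optimal codon set must cover every multi-codon family")
  }
  n_tot <- 0; n_opt <- 0; n_ran <- 0
  for (a in names(fams)) {
    fam <- fams[[a]]
    n_a <- sum(counts[fam])
    n_tot <- n_tot + n_a
    n_opt <- n_opt + counts[[optimal[[a]]]]
    n_ran <- n_ran + n_a / length(fam)
  }
  if (abs(n_tot - n_ran) < .Machine$double.eps * n_tot || n_tot == 0) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' G+C fraction at synonymous third codon positions (GC3s)
#'
#' Fraction of G or C third bases among codons belonging to multi-codon
#' families (all families of table 5 qualify); stops are never counted.
#'
#' @inheritParams rscu
#' @return fraction in `[0, 1]`; `NA` with zero eligible codons.
#' @export
gc3s <- function(counts, code = genetic_code(5)) {
  fams <- code$families[lengths(code$families) >= 2]
  eligible <- unlist(fams, use.names = FALSE)
  n <- counts[eligible]
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  third_gc <- substr(eligible, 3, 3) %in% c("G", "C")
  sum(n[third_gc]) / tot
}

#' Most frequently used codons
#'
#' @inheritParams rscu
#' @param k number of codons to return.
#' @return tibble `codon`, `amino_acid`, `count`, ranked by count with ties
#'   broken lexicographically.
#' @export
top_codons <- function(counts, k = 5, code = genetic_code(5)) {
  if (k > length(code$sense_codons)) abort("k exceeds the sense-codon count")
  sense <- counts[code$sense_codons]
  ord <- order(-sense, names(sense))
  picked <- names(sense)[ord][seq_len(k)]
  tibble(codon = picked, amino_acid = unname(code$aa[picked]),
         count = as.integer(sense[picked]))
}

#' Pearson correlation with two-sided p-value
#'
#' Convenience wrapper used for the ENC~GC3s and CBI~GC3s relations.
#'
#' @param xs,ys numeric vectors of equal length (>= 3).
#' @return tibble with `r`, `p`, `n`; `r` is `NA` for constant input.
#' @export
correlate <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = length(xs)))
  }
  ct <- stats::cor.test(xs, ys, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(xs))
}

#' Per-sample codon-usage indices over the concatenated PCGs
#'
#' For each record, counts codons over the 13 concatenated protein-coding
#' genes and reports ENC, CBI, GC3s and the codon total. Optimal codons
#' for CBI are the most frequent synonyms in the pooled dataset (recorded
#' in the `optimal_codons` attribute). With a taxonomy, unweighted tribe
#' means are appended.
#'
#' @param records list of `mito_record`s.
#' @param taxonomy optional taxonomy tibble.
#' @param code a [genetic_code()].
#' @return tibble with `group`, `level`, `enc`, `cbi`, `gc3s`, `n_codons`.
#' @export
codon_usage_report <- function(records, taxonomy = NULL, code = genetic_code(5)) {
  per_sample_counts <- purrr::map(records, function(rec) {
    genes <- intersect(mito_gene_order("PCG"), rec$features$name)
    cds <- vapply(genes, function(g) extract_gene(rec, g), character(1))
    suppressWarnings(codon_counts(cds, code))
  })
  names(per_sample_counts) <- purrr::map_chr(records, "sample_id")
  pooled <- Reduce(`+`, per_sample_counts)
  opt <- optimal_codons(pooled, code)
  rows <- purrr::imap_dfr(per_sample_counts, function(n, id) {
    tibble(group = id, level = "sample",
           enc = enc(n, code), cbi = cbi(n, code, opt),
           gc3s = gc3s(n, code), n_codons = sum(n[code$sense_codons]))
  })
  if (!is.null(taxonomy)) {
    tribe_rows <- rows |>
      dplyr::inner_join(taxonomy, by = c(group = "sample_id")) |>
      dplyr::group_by(.data$tribe) |>
      dplyr::summarise(enc = mean(.data$enc), cbi = mean(.data$cbi),
                       gc3s = mean(.data$gc3s),
                       n_codons = sum(.data$n_codons), .groups = "drop") |>
      dplyr::mutate(group = .data$tribe, level = "tribe") |>
      dplyr::select("group", "level", "enc", "cbi", "gc3s", "n_codons")
    rows <- dplyr::bind_rows(rows, tribe_rows)
  }
  attr(rows, "optimal_codons") <- opt
  rows
}

#' RSCU tables pooled by taxonomic group
#'
#' @param records list of `mito_record`s.
#' @param taxonomy taxonomy tibble.
#' @param group rank column to pool by (default `"tribe"`).
#' @param code a [genetic_code()].
#' @return tibble `group`, `codon`, `amino_acid`, `count`, `rscu`.
#' @export
rscu_by_group <- function(records, taxonomy, group = "tribe", code = genetic_code(5)) {
  ids <- purrr::map_chr(records, "sample_id")
  key <- stats::setNames(taxonomy[[group]], taxonomy$sample_id)[ids]
  purrr::map_dfr(split(records, key), function(recs) {
    counts <- Reduce(`+`, purrr::map(recs, function(rec) {
      genes <- intersect(mito_gene_order("PCG"), rec$features$name)
      suppressWarnings(codon_counts(
        vapply(genes, function(g) extract_gene(rec, g), character(1)), code))
    }))
    rscu(counts, code)
  }, .id = "group")
}
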