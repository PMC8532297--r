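# Nucleotide content and strand-skew statistics. Skews follow the usual
# strand-asymmetry definitions AT-skew = (A - T)/(A + T) and
# GC-skew = (G - C)/(G + C), computed on the majority strand as stored.

#' Count A/T/G/C in a sequence
#'
#' `N` and the gap symbol are excluded from all four counts.
#'
#' @param seq DNA string over `A C G T N -`.
#' @return named integer vector `c(A=, T=, G=, C=)`.
#' @export
base_counts <- function(seq) {
  seq <- check_dna(seq, "sequence")
  c(A = stringr::str_count(seq, stringr::fixed("A")),
    T = stringr::str_count(seq, stringr::fixed("T")),
    G = stringr::str_count(seq, stringr::fixed("G")),
    C = stringr::str_count(seq, stringr::fixed("C")))
}

.counts_of <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x))) {
    base_counts(x)
  } else {
    stopifnot(all(c("A", "T") %in% names(x)) || all(c("G", "C") %in% names(x)))
    x
  }
}

#' AT-skew: (A - T) / (A + T)
#'
#' @param x base counts from [base_counts()], or a DNA string.
#' @return dimensionless value in `[-1, 1]`; `NA` when `A + T == 0`.
#' @export
at_skew <- function(x) {
  n <- .counts_of(x)
  denom <- n[["A"]] + n[["T"]]
  if (denom == 0) return(NA_real_)
  (n[["A"]] - n[["T"]]) / denom
}

#' GC-skew: (G - C) / (G + C)
#'
#' @inheritParams at_skew
#' @return dimensionless value in `[-1, 1]`; `NA` when `G + C == 0`.
#' @export
gc_skew <- function(x) {
  n <- .counts_of(x)
  denom <- n[["G"]] + n[["C"]]
  if (denom == 0) return(NA_real_)
  (n[["G"]] - n[["C"]]) / denom
}

#' Extract one codon position from an in-frame CDS
#'
#' Trailing bases not completing a codon are dropped with a warning. The
#' three position subsequences partition the first `3*floor(L/3)` bases.
#'
#' @param cds in-frame DNA string.
#' @param position codon position, 1, 2 or 3.
#' @return DNA string of length `floor(nchar(cds)/3)`.
#' @export
#' @examples
#' codon_position_subsequence("ATGAAA", 3)  # "GA"
codon_position_subsequence <- function(cds, position) {
  if (!position %in% 1:3) abort("position must be 1, 2 or 3")
  x <- seq_chars(check_dna(cds, "cds"))
  n_cod <- length(x) %/% 3
  if (length(x) > 3 * n_cod) {
    warn(sprintf("dropping %d trailing base(s) not completing a codon",
                 length(x) - 3 * n_cod))
  }
  if (n_cod == 0) return("")
  paste(x[seq(position, 3 * n_cod, by = 3)], collapse = "")
}

.summary_row <- function(group, level, partition, seq, incomplete = FALSE) {
  n <- base_counts(seq)
  tot <- sum(n)
  tibble(
    group = group, level = level, partition = partition,
    n_A = n[["A"]], n_T = n[["T"]], n_G = n[["G"]], n_C = n[["C"]],
    pct_A = 100 * n[["A"]] / tot, pct_T = 100 * n[["T"]] / tot,
    pct_G = 100 * n[["G"]] / tot, pct_C = 100 * n[["C"]] / tot,
    at_content = 100 * (n[["A"]] + n[["T"]]) / tot,
    at_skew = at_skew(n), gc_skew = gc_skew(n),
    incomplete = incomplete
  )
}

.PARTITIONS <- c("whole", "PCG", "pos1", "pos2", "pos3", "rRNA", "tRNA")

.partition_sequence <- function(record, partition) {
  if (partition == "whole") return(list(seq = record$sequence, missing = character(0)))
  genes <- switch(partition,
                  PCG = , pos1 = , pos2 = , pos3 = mito_gene_order("PCG"),
                  rRNA = mito_gene_order("rRNA"),
                  tRNA = mito_gene_order("tRNA"))
  have <- intersect(genes, record$features$name)
  missing <- setdiff(genes, have)
  seqs <- vapply(have, function(g) extract_gene(record, g), character(1))
  if (partition %in% c("pos1", "pos2", "pos3")) {
    p <- as.integer(sub("pos", "", partition))
    seqs <- vapply(seqs, function(s) {
      suppressWarnings(codon_position_subsequence(s, p))
    }, character(1))
  }
  list(seq = paste(seqs, collapse = ""), missing = missing)
}

#' Nucleotide composition report per sample and per tribe
#'
#' For each record and each requested partition, concatenates the relevant
#' gene sequences on their annotated strand (minus-strand genes are
#' reverse-complemented by extraction, so skews are comparable across
#' genes), pools the bases and summarizes content and skews. When a
#' taxonomy is supplied, unweighted tribe means of the percentage/skew
#' columns are appended (`level == "tribe"`); samples missing any gene of a
#' partition are flagged `incomplete` and excluded from tribe means.
#'
#' @param records list of `mito_record`s.
#' @param taxonomy optional taxonomy tibble from [load_taxonomy()].
#' @param partitions subset of
#'   `c("whole", "PCG", "pos1", "pos2", "pos3", "rRNA", "tRNA")`.
#' @return tibble of composition summaries (one row per group x partition).
#' @export
composition_report <- function(records, taxonomy = NULL,
                               partitions = .PARTITIONS) {
  partitions <- match.arg(partitions, .PARTITIONS, several.ok = TRUE)
  rows <- purrr::map_dfr(records, function(rec) {
    purrr::map_dfr(partitions, function(p) {
      ps <- .partition_sequence(rec, p)
      if (length(ps$missing) > 0) {
        warn(sprintf("%s: partition %s missing gene(s) %s; flagged incomplete",
                     rec$sample_id, p, paste(ps$missing, collapse = ", ")))
      }
      .summary_row(rec$sample_id, "sample", p, ps$seq,
                   incomplete = length(ps$missing) > 0)
    })
  })
  if (!is.null(taxonomy)) {
    tribe_rows <- rows |>
      dplyr::filter(!.data$incomplete) |>
      dplyr::inner_join(taxonomy, by = c(group = "sample_id")) |>
      dplyr::group_by(.data$tribe, .data$partition) |>
      dplyr::summarise(dplyr::across(
        c("pct_A", "pct_T", "pct_G", "pct_C", "at_content", "at_skew", "gc_skew"),
        mean), n_samples = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(group = .data$tribe, level = "tribe", incomplete = FALSE) |>
      dplyr::select(-"tribe")
    rows <- dplyr::bind_rows(rows, tribe_rows)
  }
  rows
}
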