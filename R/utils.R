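#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Alphabet accepted throughout: unambiguous bases, N, and the gap symbol.
# Ambiguity codes other than N are rejected at parse time because they
# would silently corrupt skew and diversity counts.
.DNA_LETTERS <- c("A", "C", "G", "T")
.ALLOWED <- c(.DNA_LETTERS, "N", "-")

#' Check that a string (or character vector of bases) is valid DNA
#'
#' @param x character string or vector of single characters.
#' @param what label used in error messages.
#' @param allow_gap allow the alignment gap symbol `-`.
#' @return invisibly, the uppercased input.
#' @keywords internal
check_dna <- function(x, what = "sequence", allow_gap = TRUE) {
  x <- toupper(x)
  allowed <- if (allow_gap) .ALLOWED else c(.DNA_LETTERS, "N")
  joined <- paste(x, collapse = "")
  bad <- regmatches(joined, gregexpr(sprintf("[^%s]", paste(allowed, collapse = "")), joined))[[1]]
  if (length(bad) > 0) {
    abort(sprintf("invalid symbol(s) in %s: %s (allowed: %s)",
                  what, paste(unique(bad), collapse = ", "),
                  paste(allowed, collapse = "")))
  }
  invisible(x)
}

#' Split a DNA string into a character vector of bases
#' @keywords internal
seq_chars <- function(seq) {
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' Reverse complement of a DNA string
#'
#' Gaps and N are preserved (N complements to N, `-` to `-`).
#'
#' @param seq a DNA string over `A C G T N -`.
#' @return the reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ATGAAA")
reverse_complement <- function(seq) {
  seq <- check_dna(seq, "sequence")
  x <- rev(seq_chars(chartr("ACGT", "TGCA", seq)))
  paste(x, collapse = "")
}

#' Canonical mitochondrial gene order used for concatenation
#'
#' Protein-coding genes in the canonical lepidopteran mitogenome order,
#' followed by the two rRNAs and the 22 tRNAs alphabetically. Used for
#' deterministic supermatrix assembly and simulated record layout.
#'
#' @param type one of `"all"`, `"PCG"`, `"rRNA"`, `"tRNA"`.
#' @return character vector of canonical gene symbols.
#' @export
mito_gene_order <- function(type = c("all", "PCG", "rRNA", "tRNA")) {
  type <- match.arg(type)
  pcg <- c("cox1", "cox2", "atp8", "atp6", "cox3", "nad3", "nad5",
           "nad4", "nad4l", "nad6", "cob", "nad1", "nad2")
  rrna <- c("rrnL", "rrnS")
  trna <- sort(c("trnA", "trnR", "trnN", "trnD", "trnC", "trnQ", "trnE",
                 "trnG", "trnH", "trnI", "trnK", "trnM", "trnF", "trnP",
                 "trnT", "trnW", "trnY", "trnV", "trnL1", "trnL2",
                 "trnS1", "trnS2"))
  switch(type,
         all  = c(pcg, rrna, trna),
         PCG  = pcg,
         rRNA = rrna,
         tRNA = trna)
}

#' Gene class (PCG / rRNA / tRNA) of a canonical symbol
#' @keywords internal
gene_type_of <- function(name) {
  dplyr::case_when(
    name %in% mito_gene_order("PCG")  ~ "PCG",
    name %in% mito_gene_order("rRNA") ~ "rRNA",
    name %in% mito_gene_order("tRNA") ~ "tRNA",
    TRUE ~ "unknown"
  )
}
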