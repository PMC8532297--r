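#' Genetic code object
#'
#' Wraps an NCBI translation table (via [Biostrings::getGeneticCode()]) into
#' the structure the codon-usage and Ka/Ks machinery needs: the codon to
#' amino-acid map, the stop codons, and the synonymous-codon families.
#' The default, table 5, is the invertebrate mitochondrial code (AGA/AGG
#' serine, ATA methionine, TGA tryptophan; stops TAA/TAG), with 62 sense
#' codons partitioned into 12 two-fold, 6 four-fold, one six-fold (Leu) and
#' one eight-fold (Ser) family.
#'
#' @param table_id NCBI translation table number (default 5; table 1 is the
#'   standard code).
#' @return an object of class `genetic_code`: list with `table_id`, `codons`
#'   (64 DNA triplets), `aa` (named by codon, `*` for stops), `stops`,
#'   `sense_codons`, `families` (named list amino acid -> codons) and
#'   `family_size` (named by codon).
#' @export
#' @examples
#' gc5 <- genetic_code(5)
#' gc5$aa[["AGA"]]          # "S" under the invertebrate mito code
#' lengths(gc5$families)[["L"]]
genetic_code <- function(table_id = 5) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  # Biostrings returns RNA-less DNA codons named e.g. "TTT"
  codons <- names(map)
  aa <- unname(map)
  names(aa) <- codons
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  families <- split(sense, aa[sense])
  fam_size <- stats::setNames(rep(NA_integer_, length(codons)), codons)
  for (a in names(families)) fam_size[families[[a]]] <- length(families[[a]])
  structure(
    list(table_id = as.integer(table_id),
         codons = codons,
         aa = aa,
         stops = stops,
         sense_codons = sense,
         families = families,
         family_size = fam_size),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> NCBI table %d: %d sense codons, stops %s\n",
              x$table_id, length(x$sense_codons),
              paste(x$stops, collapse = "/")))
  sizes <- table(lengths(x$families))
  cat("  family sizes:",
      paste(sprintf("%s-fold x%d", names(sizes), as.integer(sizes)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Split an in-frame CDS into codons
#'
#' Trailing bases that do not complete a codon are dropped (with a warning
#' when `warn = TRUE`), mirroring how partial stop codons are handled.
#'
#' @param cds DNA string.
#' @param frame reading-frame offset 0/1/2 (bases skipped at the start).
#' @param warn warn when trailing bases are dropped.
#' @return character vector of triplets.
#' @export
split_codons <- function(cds, frame = 0, warn = TRUE) {
  stopifnot(frame %in% 0:2)
  x <- seq_chars(cds)
  if (frame > 0) x <- x[-seq_len(frame)]
  n_cod <- length(x) %/% 3
  extra <- length(x) - 3 * n_cod
  if (extra > 0 && warn) {
    warn(sprintf("dropping %d trailing base(s) not completing a codon", extra))
  }
  if (n_cod == 0) return(character(0))
  x <- x[seq_len(3 * n_cod)]
  apply(matrix(x, nrow = 3), 2, paste, collapse = "")
}
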