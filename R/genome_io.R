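#' Canonicalize mitochondrial gene names
#'
#' Maps the common synonym spellings found in GenBank annotations
#' (COI/COX1, ND4L, CYTB, 16S/l-rRNA, tRNA-Leu(UUR), ...) onto the 37
#' canonical symbols used throughout the package (`cox1..cox3`, `nad1..nad6`,
#' `nad4l`, `atp6`, `atp8`, `cob`, `rrnL`, `rrnS`, `trnX`, `trnL1/trnL2`,
#' `trnS1/trnS2`). Case-insensitive; total (never errors). Leucine/serine
#' tRNAs without a codon-family tag or anticodon map to the ambiguous
#' `"trnL"`/`"trnS"`, which record validation refuses; anything
#' unrecognized maps to `"unknown"`.
#'
#' @param raw character vector of raw names/products.
#' @return character vector of canonical symbols (or `"trnL"`, `"trnS"`,
#'   `"unknown"`).
#' @export
#' @examples
#' canonicalize_gene_name(c("COI", "ND4L", "l-rRNA", "tRNA-Ser(AGN)"))
canonicalize_gene_name <- function(raw) {
  vapply(raw, function(r) .canon_one(r), character(1), USE.NAMES = FALSE)
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.canon_one <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return("unknown")
  up <- toupper(raw)
  # codon-family tags decide trnL1/trnL2 and trnS1/trnS2
  tag <- dplyr::case_when(
    grepl("CUN|\\(TAG\\)|\\(UAG\\)", up) ~ "L1",
    grepl("UUR|\\(TAA\\)|\\(UAA\\)", up) ~ "L2",
    grepl("AGN|\\(TCT\\)|\\(UCU\\)|\\(GCT\\)|\\(GCU\\)", up) ~ "S1",
    grepl("UCN|\\(TGA\\)|\\(UGA\\)", up) ~ "S2",
    TRUE ~ ""
  )
  x <- gsub("[^A-Z0-9]", "", up)  # strip spaces, hyphens, parentheses

  # tRNAs -----------------------------------------------------------------
  if (grepl("^TRN", x)) {
    if (grepl("^TRNA?L1$", x)) return("trnL1")
    if (grepl("^TRNA?L2$", x)) return("trnL2")
    if (grepl("^TRNA?S1$", x)) return("trnS1")
    if (grepl("^TRNA?S2$", x)) return("trnS2")
    aa <- NA_character_
    # prefer a three-letter amino-acid code after the 'tRNA' prefix
    # ("tRNA-Leu" -> LEU); fall back to the one-letter form after 'trn'
    # ("trnW", and bare "trnA" where the final A is the amino acid)
    body_a <- if (grepl("^TRNA.", x)) sub("^TRNA", "", x) else ""
    body <- sub("^TRN", "", x)
    if (substr(body_a, 1, 3) %in% names(.AA3TO1)) {
      aa <- .AA3TO1[[substr(body_a, 1, 3)]]
    } else if (substr(body, 1, 3) %in% names(.AA3TO1)) {
      aa <- .AA3TO1[[substr(body, 1, 3)]]
    } else if (nzchar(body) && substr(body, 1, 1) %in% .AA3TO1) {
      aa <- substr(body, 1, 1)
    }
    if (is.na(aa)) return("unknown")
    if (aa == "L") return(if (nzchar(tag)) paste0("trn", tag) else "trnL")
    if (aa == "S") return(if (nzchar(tag)) paste0("trn", tag) else "trnS")
    return(paste0("trn", aa))
  }

  # rRNAs -----------------------------------------------------------------
  if (grepl("^(16S|LRRNA|RRNL|LSU)", x) || grepl("LARGESUBUNIT", x)) return("rrnL")
  if (grepl("^(12S|SRRNA|RRNS|SSU)", x) || grepl("SMALLSUBUNIT", x)) return("rrnS")

  # PCGs ------------------------------------------------------------------
  roman <- c(I = "1", II = "2", III = "3")
  m <- regmatches(x, regexec("^(COX?)(III|II|I|[123])$", x))[[1]]
  if (length(m)) {
    num <- if (m[3] %in% names(roman)) roman[[m[3]]] else m[3]
    return(paste0("cox", num))
  }
  if (grepl("CYTOCHROMEOXIDASE.*SUBUNIT(III|II|I|[123])", x)) {
    num <- sub(".*SUBUNIT", "", x)
    num <- if (num %in% names(roman)) roman[[num]] else num
    return(paste0("cox", num))
  }
  m <- regmatches(x, regexec("^(NADH?|ND)(4L|[1-6])$", x))[[1]]
  if (length(m)) return(paste0("nad", tolower(m[3])))
  if (grepl("NADHDEHYDROGENASESUBUNIT(4L|[1-6])", x)) {
    return(paste0("nad", tolower(sub(".*SUBUNIT", "", x))))
  }
  if (grepl("^(CYTB|CYB|COB)$", x) || grepl("CYTOCHROMEB", x)) return("cob")
  if (grepl("^ATP(ASE)?6$", x) || grepl("ATPSYNTHASE.*(F0)?SUBUNIT6", x)) return("atp6")
  if (grepl("^ATP(ASE)?8$", x) || grepl("ATPSYNTHASE.*(F0)?SUBUNIT8", x)) return("atp8")

  "unknown"
}

#' Construct an annotated mitogenome record
#'
#' @param sample_id unique sample identifier.
#' @param sequence DNA string over `A C G T N` (no gaps).
#' @param features tibble/data.frame with columns `name` (canonical symbol),
#'   `type` (`PCG`, `tRNA`, `rRNA`, `control_region`), `start`, `end`
#'   (1-based inclusive, GenBank convention), `strand` (`+`/`-`). Features
#'   with `start > end` wrap the origin and are only valid on circular
#'   records.
#' @param taxonomy optional named list / one-row data frame with
#'   `subfamily`, `tribe`, `genus`, `species`, `individual`.
#' @param circular is the molecule circular (complete assemblies are).
#' @param complete was the control region assembled; if `TRUE` the total
#'   length must fall in the 14-17 kb sanity range for complete
#'   lepidopteran mitogenomes.
#' @return object of class `mito_record`.
#' @export
mito_record <- function(sample_id, sequence, features,
                        taxonomy = NULL, circular = TRUE, complete = TRUE) {
  sequence <- check_dna(sequence, sprintf("sequence of %s", sample_id),
                        allow_gap = FALSE)
  features <- tibble::as_tibble(features)
  rec <- structure(
    list(sample_id = sample_id, sequence = sequence, features = features,
         taxonomy = taxonomy, circular = isTRUE(circular),
         complete = isTRUE(complete)),
    class = "mito_record")
  validate_mito_record(rec)
}

#' Validate a mitogenome record's invariants
#' @param rec a `mito_record`.
#' @return the record, invisibly checked.
#' @export
validate_mito_record <- function(rec) {
  len <- nchar(rec$sequence)
  if (len == 0) abort("empty sequence")
  if (rec$complete && (len < 14000 || len > 17000)) {
    abort(sprintf("complete mitogenome length %d outside sanity range [14000, 17000]", len))
  }
  f <- rec$features
  need <- c("name", "type", "start", "end", "strand")
  if (!all(need %in% names(f))) {
    abort(sprintf("features must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(f$start < 1 | f$start > len | f$end < 1 | f$end > len)) {
    abort("feature coordinates outside [1, sequence length]")
  }
  wrap <- f$start > f$end
  if (any(wrap) && !rec$circular) {
    abort("origin-wrapping feature on a non-circular record")
  }
  amb <- f$name %in% c("trnL", "trnS")
  if (any(amb)) {
    abort(sprintf(
      "ambiguous leucine/serine tRNA (%s): an anticodon or (UUR)/(CUN)/(AGN)/(UCN) tag is required",
      paste(unique(f$name[amb]), collapse = ", ")))
  }
  genes <- f$name[f$type != "control_region"]
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene name(s): %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  tmatch <- gene_type_of(f$name) == f$type | f$type == "control_region"
  if (!all(tmatch)) {
    abort(sprintf("feature type inconsistent with name: %s",
                  paste(f$name[!tmatch], collapse = ", ")))
  }
  invisible(rec)
}

#' @export
print.mito_record <- function(x, ...) {
  cat(sprintf("<mito_record> %s: %d bp, %s, %s; %d features\n",
              x$sample_id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              if (x$complete) "complete" else "partial",
              nrow(x$features)))
  invisible(x)
}

#' Extract a gene sequence from a record
#'
#' Returns the subsequence on the annotated strand (reverse-complemented
#' for minus-strand genes). Features wrapping the origin of a circular
#' molecule concatenate the tail and head of the sequence.
#'
#' @param record a `mito_record`.
#' @param name canonical gene symbol.
#' @return DNA string.
#' @export
extract_gene <- function(record, name) {
  f <- record$features
  i <- which(f$name == name)
  if (length(i) == 0) abort(sprintf("gene '%s' not annotated on %s", name, record$sample_id))
  i <- i[[1]]
  len <- nchar(record$sequence)
  if (f$start[i] > f$end[i]) {
    if (!record$circular) abort("origin-wrapping feature on a non-circular record")
    s <- paste0(substr(record$sequence, f$start[i], len),
                substr(record$sequence, 1, f$end[i]))
  } else {
    s <- substr(record$sequence, f$start[i], f$end[i])
  }
  if (f$strand[i] == "-") s <- reverse_complement(s)
  s
}

#' Load a taxonomy table
#'
#' Five-rank taxonomy (subfamily, tribe, genus, species, individual) keyed
#' by `sample_id`; `individual` distinguishes conspecific samples and must
#' be unique across the dataset.
#'
#' @param x path to a TSV file or a data frame.
#' @return tibble with columns `sample_id`, `subfamily`, `tribe`, `genus`,
#'   `species`, `individual`.
#' @export
load_taxonomy <- function(x) {
  tab <- if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    readr::read_tsv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  need <- c("sample_id", "subfamily", "tribe", "genus", "species", "individual")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort(sprintf("taxonomy table missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  tab <- tab[need]
  empty <- !stats::complete.cases(tab) | apply(tab == "", 1, any)
  if (any(empty)) {
    abort(sprintf("taxonomy rows with empty rank(s): %s",
                  paste(tab$sample_id[empty], collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) {
    abort(sprintf("duplicated sample_id: %s",
                  paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", ")))
  }
  if (anyDuplicated(tab$individual)) {
    abort(sprintf("duplicated individual id: %s",
                  paste(unique(tab$individual[duplicated(tab$individual)]), collapse = ", ")))
  }
  tab
}

#' Construct a per-gene alignment block
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (names are sample ids), or a character matrix (rows = samples,
#'   columns = sites) with row names.
#' @param gene canonical gene symbol.
#' @param is_coding is this an in-frame protein-coding alignment.
#' @param frame reading-frame offset 0/1/2 for coding blocks.
#' @return object of class `alignment_block`: list with `gene`, `matrix`,
#'   `is_coding`, `frame`.
#' @export
alignment_block <- function(seqs, gene, is_coding = FALSE, frame = 0) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      abort("aligned sequences must carry unique sample names")
    }
    widths <- nchar(seqs)
    if (length(unique(widths)) > 1) {
      abort(sprintf("ragged alignment for %s: lengths %s", gene,
                    paste(unique(widths), collapse = ", ")))
    }
    m <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  bad <- matrix(!(m %in% .ALLOWED), nrow(m), ncol(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("invalid symbol '%s' in sequence %s, column %d",
                  m[bad][1], rownames(m)[idx[1]], idx[2]))
  }
  stopifnot(frame %in% 0:2)
  structure(list(gene = gene, matrix = m, is_coding = isTRUE(is_coding),
                 frame = as.integer(frame)),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %s: %d samples x %d sites%s\n",
              x$gene, nrow(x$matrix), ncol(x$matrix),
              if (x$is_coding) sprintf(" (coding, frame %d)", x$frame) else ""))
  invisible(x)
}

#' Sequences of an alignment block as strings
#' @param block an `alignment_block`.
#' @return named character vector.
#' @export
block_sequences <- function(block) {
  stats::setNames(apply(block$matrix, 1, paste, collapse = ""),
                  rownames(block$matrix))
}

#' Read an aligned FASTA file into an alignment block
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param gene canonical gene symbol to label the block with.
#' @param is_coding,frame see [alignment_block()].
#' @return an `alignment_block`.
#' @export
read_aligned_fasta <- function(path, gene, is_coding = FALSE, frame = 0) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  alignment_block(seqs, gene = gene, is_coding = is_coding, frame = frame)
}

#' Write sequences to FASTA
#'
#' Accepts an `alignment_block`, a `mito_record` (whole-genome sequence) or
#' a named character vector.
#'
#' @param x sequences to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "alignment_block")) {
    block_sequences(x)
  } else if (inherits(x, "mito_record")) {
    stats::setNames(x$sequence, x$sample_id)
  } else {
    x
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70)
  invisible(path)
}
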