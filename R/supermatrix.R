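# Concatenated datasets for phylogenetic analysis. Four schemes:
#   P12    first and second codon positions of the 13 PCGs
#   P123   all codon positions of the PCGs
#   P123R  P123 plus the two rRNAs
#   P123RT P123R plus the 22 tRNAs
# Genes are concatenated in the fixed canonical order (mito_gene_order()),
# samples missing a gene are padded with '-'. Charset coordinates are
# 1-based inclusive with stride notation for codon positions.

.SCHEMES <- c("P12", "P123", "P123R", "P123RT")

#' Build a concatenated supermatrix under a partitioning scheme
#'
#' @param blocks named list of `alignment_block`s (names or `$gene` give
#'   the canonical symbols); protein-coding blocks must be in frame.
#' @param scheme one of `"P12"`, `"P123"`, `"P123R"`, `"P123RT"`.
#' @return object of class `supermatrix`: list with `name`, `samples`,
#'   `matrix` (samples x columns), `charsets` (gene-level, tiling the
#'   matrix), `provenance` (tibble column -> gene/original column/codon
#'   position) and `coverage` (samples padded per gene).
#' @export
build_supermatrix <- function(blocks, scheme = c("P123RT", "P12", "P123", "P123R")) {
  scheme <- match.arg(scheme)
  genes_of <- vapply(blocks, function(b) b$gene, character(1))
  names(blocks) <- genes_of
  keep_pos <- if (scheme == "P12") c(1L, 2L) else 1:3
  wanted <- mito_gene_order("PCG")
  if (scheme %in% c("P123R", "P123RT")) wanted <- c(wanted, mito_gene_order("rRNA"))
  if (scheme == "P123RT") wanted <- c(wanted, mito_gene_order("tRNA"))
  wanted <- wanted[wanted %in% genes_of]
  if (!length(wanted)) abort("no blocks match the requested scheme")

  samples <- sort(unique(unlist(lapply(blocks[wanted], function(b) rownames(b$matrix)))))
  pieces <- list(); prov <- list(); charsets <- list(); coverage <- list()
  offset <- 0L
  for (g in wanted) {
    b <- blocks[[g]]
    m <- b$matrix
    L0 <- ncol(m)
    if (b$is_coding) {
      i <- seq_len(L0)
      pos <- ifelse(i > b$frame, ((i - b$frame - 1L) %% 3L) + 1L, NA_integer_)
      n_cod <- (L0 - b$frame) %/% 3L
      in_full <- !is.na(pos) & i <= b$frame + 3L * n_cod
      keep <- which(in_full & pos %in% keep_pos)
    } else {
      pos <- rep(NA_integer_, L0)
      keep <- seq_len(L0)
    }
    sel <- m[, keep, drop = FALSE]
    # pad samples absent from this block
    pad_ids <- setdiff(samples, rownames(sel))
    if (length(pad_ids)) {
      pad <- matrix("-", length(pad_ids), ncol(sel),
                    dimnames = list(pad_ids, NULL))
      sel <- rbind(sel, pad)
      coverage[[g]] <- pad_ids
    }
    sel <- sel[samples, , drop = FALSE]
    pieces[[g]] <- sel
    prov[[g]] <- tibble(column = offset + seq_along(keep), gene = g,
                        orig_column = keep,
                        codon_pos = pos[keep])
    charsets[[g]] <- tibble(label = g, start = offset + 1L,
                            end = offset + length(keep))
    offset <- offset + length(keep)
  }
  structure(
    list(name = scheme, samples = samples,
         matrix = do.call(cbind, pieces),
         charsets = dplyr::bind_rows(charsets),
         provenance = dplyr::bind_rows(prov),
         coverage = coverage),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %s: %d samples x %d columns, %d charsets\n",
              x$name, length(x$samples), ncol(x$matrix), nrow(x$charsets)))
  invisible(x)
}

# Position-level charsets: per gene and codon position for PCG columns
# (stride = number of positions kept per codon), contiguous for RNAs.
.position_charsets <- function(sm) {
  prov <- sm$provenance
  out <- list()
  for (g in unique(prov$gene)) {
    p <- prov[prov$gene == g, ]
    if (all(is.na(p$codon_pos))) {
      out[[length(out) + 1]] <- tibble(label = g, start = min(p$column),
                                       end = max(p$column), stride = 1L)
    } else {
      stride <- length(unique(p$codon_pos))
      for (cp in sort(unique(p$codon_pos))) {
        cols <- p$column[p$codon_pos == cp]
        out[[length(out) + 1]] <- tibble(
          label = sprintf("%s_pos%d", g, cp),
          start = min(cols), end = max(cols), stride = stride)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Export partition (charset) definitions
#'
#' Emits codon-position charsets with stride notation, 1-based inclusive
#' (e.g. `charset cox1_pos1 = 1-1531\3;` for NEXUS,
#' `DNA, cox1_pos1 = 1-1531\3` for RAxML); RNA genes get contiguous
#' charsets.
#'
#' @param sm a `supermatrix`.
#' @param dialect `"nexus_sets"` or `"raxml"`.
#' @return character scalar with the partition text.
#' @export
export_partitions <- function(sm, dialect = c("nexus_sets", "raxml")) {
  dialect <- match.arg(dialect)
  cs <- .position_charsets(sm)
  fmt_range <- function(s, e, k) {
    ifelse(k == 1, sprintf("%d-%d", s, e), sprintf("%d-%d\\%d", s, e, k))
  }
  if (dialect == "nexus_sets") {
    body <- sprintf("  charset %s = %s;", cs$label,
                    fmt_range(cs$start, cs$end, cs$stride))
    paste(c("begin sets;", body, "end;"), collapse = "\n")
  } else {
    paste(sprintf("DNA, %s = %s", cs$label,
                  fmt_range(cs$start, cs$end, cs$stride)), collapse = "\n")
  }
}

#' Write a supermatrix to disk
#'
#' @param sm a `supermatrix`.
#' @param path output file.
#' @param format `"phylip"` (relaxed) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  seqs <- apply(sm$matrix, 1, paste, collapse = "")
  if (format == "fasta") {
    write_fasta(seqs, path)
  } else {
    lines <- c(sprintf("%d %d", length(seqs), ncol(sm$matrix)),
               sprintf("%s  %s", names(seqs), unname(seqs)))
    writeLines(lines, path)
  }
  invisible(path)
}
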