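# Minimal GenBank flat-file reader/writer for annotated mitogenomes.
# Coordinates are GenBank convention: 1-based, inclusive. Only the feature
# keys relevant to mitogenomes are interpreted (CDS, tRNA, rRNA, D-loop,
# misc_feature); origin-wrapping locations are expressed as
# join(a..LEN,1..b) and only allowed on circular molecules.

#' Parse a GenBank flat-file mitogenome record
#'
#' Reads a single well-formed record. Gene names from `/gene`, `/product`
#' or `/note` qualifiers are normalized via [canonicalize_gene_name()];
#' leucine/serine tRNAs additionally consult `/anticodon` and codon-family
#' tags. Features with unrecognizable names are ignored with a warning
#' unless annotated as control region. Ambiguity codes other than `N` are
#' rejected so that downstream base counts stay exact.
#'
#' @param x path to a `.gb` file, or the record text itself.
#' @param sample_id identifier for the record; defaults to the LOCUS name.
#' @param taxonomy optional taxonomy entry (named list or one-row tibble).
#' @return a [mito_record()].
#' @export
parse_genbank <- function(x, sample_id = NULL, taxonomy = NULL) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1) abort("malformed record: expected exactly one LOCUS line")
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  if (length(locus) < 3 || is.na(suppressWarnings(as.integer(locus[3])))) {
    abort(sprintf("malformed LOCUS line (line %d): '%s'", locus_i, lines[locus_i]))
  }
  declared_len <- as.integer(locus[3])
  circular <- any(grepl("circular", locus, ignore.case = TRUE))
  if (is.null(sample_id)) sample_id <- locus[2]

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1) abort("malformed record: expected exactly one ORIGIN line")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i][1] else length(lines) + 1
  seq_lines <- lines[seq(origin_i + 1, end_i - 1)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) abort(sprintf("malformed ORIGIN (line %d): no sequence", origin_i))
  check_dna(sequence, sprintf("ORIGIN of %s", sample_id), allow_gap = FALSE)
  if (nchar(sequence) != declared_len) {
    abort(sprintf("LOCUS declares %d bp but ORIGIN holds %d", declared_len, nchar(sequence)))
  }

  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i) == 1) {
    block <- lines[seq(feat_i + 1, origin_i - 1)]
    feats <- .parse_feature_table(block, nchar(sequence), circular, sample_id)
  }
  complete <- !any(vapply(feats, function(f) isTRUE(f$partial_flag), logical(1))) &&
    nchar(sequence) >= 14000
  features <- dplyr::bind_rows(lapply(feats, function(f) {
    tibble(name = f$name, type = f$type, start = f$start, end = f$end, strand = f$strand)
  }))
  if (nrow(features) == 0) {
    features <- tibble(name = character(), type = character(),
                       start = integer(), end = integer(), strand = character())
  }
  mito_record(sample_id, sequence, features, taxonomy = taxonomy,
              circular = circular,
              complete = nchar(sequence) >= 14000 && nchar(sequence) <= 17000)
}

.parse_feature_table <- function(block, seq_len, circular, sample_id) {
  # split into raw feature chunks: a new feature starts at indent 5
  starts <- grep("^ {5}\\S", block)
  if (!length(starts)) return(list())
  chunks <- Map(function(a, b) block[a:b], starts,
                c(starts[-1] - 1, length(block)))
  out <- list()
  for (ch in chunks) {
    head <- ch[[1]]
    key <- sub("^ {5}(\\S+).*", "\\1", head)
    loc <- trimws(sub("^ {5}\\S+", "", head))
    rest <- if (length(ch) > 1) trimws(ch[-1]) else character(0)
    # location may continue onto lines that do not start a qualifier
    qual_start <- which(grepl("^/", rest))[1]
    if (is.na(qual_start)) qual_start <- length(rest) + 1
    if (qual_start > 1) loc <- paste0(loc, paste(rest[seq_len(qual_start - 1)], collapse = ""))
    quals <- .parse_qualifiers(rest[seq_along(rest) >= qual_start])
    if (key %in% c("source", "gene")) next
    type <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   `D-loop` = "control_region", misc_feature = "misc", NULL)
    if (is.null(type)) next
    note_all <- paste(unlist(quals[c("note", "product")]), collapse = " ")
    if (type == "misc") {
      if (grepl("control region", note_all, ignore.case = TRUE)) {
        type <- "control_region"
      } else {
        warn(sprintf("%s: ignoring unrecognized feature '%s' (%s)", sample_id, key, loc))
        next
      }
    }
    pos <- .parse_location(loc, seq_len, circular)
    name <- if (type == "control_region") {
      "control_region"
    } else {
      raw <- quals$gene %||% quals$product %||% quals$note %||% ""
      hint <- paste(raw, quals$product %||% "", quals$anticodon %||% "", quals$note %||% "")
      nm <- canonicalize_gene_name(raw)
      if (nm %in% c("trnL", "trnS", "unknown")) {
        nm2 <- canonicalize_gene_name(hint)
        if (!nm2 %in% c("unknown")) nm <- nm2
      }
      nm
    }
    if (name == "unknown") {
      warn(sprintf("%s: ignoring feature with unrecognizable name (%s %s)",
                   sample_id, key, loc))
      next
    }
    out[[length(out) + 1]] <- list(name = name, type = type,
                                   start = pos$start, end = pos$end,
                                   strand = pos$strand)
  }
  out
}

.parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  # join continuation lines onto their qualifier
  idx <- cumsum(grepl("^/", lines))
  parts <- vapply(split(lines, idx), paste, character(1), collapse = " ")
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec('^/([A-Za-z_]+)(=("?)(.*?)\\3)?\\s*$', p, perl = TRUE))[[1]]
    if (length(m)) out[[m[2]]] <- if (nzchar(m[5])) m[5] else TRUE
  }
  out
}

.parse_location <- function(loc, seq_len, circular) {
  strand <- "+"
  x <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", x)
    ranges <- strsplit(inner, ",", fixed = TRUE)[[1]]
    if (length(ranges) != 2) abort(sprintf("unsupported join location: %s", loc))
    r1 <- .parse_range(ranges[1], loc)
    r2 <- .parse_range(ranges[2], loc)
    if (!(r1$end == seq_len && r2$start == 1)) {
      abort(sprintf("join location is not an origin wrap: %s", loc))
    }
    if (!circular) abort(sprintf("origin-wrapping location on linear record: %s", loc))
    return(list(start = r1$start, end = r2$end, strand = strand))
  }
  r <- .parse_range(x, loc)
  if (r$start > seq_len || r$end > seq_len) {
    abort(sprintf("location outside sequence [1, %d]: %s", seq_len, loc))
  }
  list(start = r$start, end = r$end, strand = strand)
}

.parse_range <- function(x, loc) {
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (!length(m)) abort(sprintf("cannot parse location: %s", loc))
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

#' Serialize a mitogenome record as a GenBank flat file
#'
#' Writes a minimal canonical record (LOCUS, FEATURES, ORIGIN) that
#' [parse_genbank()] reads back unchanged: parse -> write -> parse is a
#' fixed point on canonical records.
#'
#' @param record a `mito_record`.
#' @param path optional output file; when `NULL` the text is returned.
#' @return the flat-file text (invisibly when `path` is given).
#' @export
write_genbank <- function(record, path = NULL) {
  len <- nchar(record$sequence)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     record$sample_id, len,
                     if (record$circular) "circular" else "linear"),
             sprintf("DEFINITION  %s mitochondrion%s.", record$sample_id,
                     if (record$complete) ", complete genome" else ", partial genome"),
             "FEATURES             Location/Qualifiers")
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control_region = "D-loop")
  for (i in seq_len(nrow(record$features))) {
    f <- record$features[i, ]
    loctxt <- if (f$start > f$end) {
      sprintf("join(%d..%d,1..%d)", f$start, len, f$end)
    } else {
      sprintf("%d..%d", f$start, f$end)
    }
    if (f$strand == "-") loctxt <- sprintf("complement(%s)", loctxt)
    lines <- c(lines, sprintf("     %-16s%s", key_of[[f$type]], loctxt))
    if (f$type != "control_region") {
      lines <- c(lines, sprintf("                     /gene=\"%s\"", f$name))
    } else {
      lines <- c(lines, "                     /note=\"control region\"")
    }
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  lines <- c(lines, "//")
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
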