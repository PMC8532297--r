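# End-to-end orchestration: ingest -> composition -> codon usage ->
# divergence/diversity -> Ka/Ks -> supermatrix -> trees -> informativeness.
# Plain-file outputs only (TSV/FASTA/newick/NEXUS); every table carries a
# header comment with the tool version, config hash and input checksums,
# and a JSON manifest records what ran. Stages whose outputs are
# up-to-date for the same config + inputs are skipped on rerun.

#' Informativeness profiles for the partitions of a supermatrix
#'
#' Estimates per-site rates once over the whole matrix on the given
#' ultrametric tree, then assembles net/per-site profiles for each gene
#' and for the pooled codon-position partitions (`pos1`, `pos2`, `pos3`)
#' using the column provenance map.
#'
#' @param sm a `supermatrix` built from in-frame PCG blocks (plus RNAs).
#' @param tree rooted ultrametric `phylo` covering the samples.
#' @param times profile time grid (default 200 points on `(0, 1]`).
#' @param rate_cap,tol passed to [estimate_site_rates()].
#' @return list with `rates` (the full `site_rates`) and `profiles`
#'   (combined `pi_profile` tibble over all partitions).
#' @export
pi_profiles_by_partition <- function(sm, tree, times = seq_len(200) / 200,
                                     rate_cap = 20, tol = 1e-6) {
  sr <- estimate_site_rates(sm, tree, rate_cap = rate_cap, tol = tol,
                            partition = sm$name)
  lam <- sr$rates$lambda
  prov <- sm$provenance
  parts <- list()
  for (g in unique(prov$gene)) {
    parts[[g]] <- prov$column[prov$gene == g]
  }
  for (p in 1:3) {
    cols <- prov$column[!is.na(prov$codon_pos) & prov$codon_pos == p]
    if (length(cols)) parts[[sprintf("pos%d", p)]] <- cols
  }
  profiles <- purrr::imap(parts, function(cols, label) {
    pi_profile(lam[cols], times = times, partition = label)
  })
  list(rates = sr, profiles = dplyr::bind_rows(profiles))
}

.hash_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

.config_hash <- function(config) {
  # stable content hash of the run configuration
  dump <- paste(utils::capture.output(dput(config[sort(names(config))])), collapse = "")
  .hash_string(dump)
}

.input_checksums <- function(paths) {
  paths <- unlist(paths)
  paths <- paths[!is.na(paths) & file.exists(paths)]
  files <- if (length(paths)) {
    unlist(lapply(paths, function(p) {
      if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE) else p
    }))
  } else character(0)
  sums <- tools::md5sum(sort(files))
  stats::setNames(unname(sums), basename(names(sums)))
}

.header_line <- function(cfg_hash, input_hash) {
  sprintf("# mitocomp %s  config=%s  inputs=%s",
          as.character(utils::packageVersion("mitocomp")), cfg_hash, input_hash)
}

.write_table <- function(tab, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline run configuration
#'
#' @param config named list (or path to a YAML file) with fields
#'   `records_dir` (GenBank flat files), `taxonomy` (TSV path),
#'   `alignments_dir` (per-gene FASTA, `<gene>.fasta`), optional `tree`
#'   (newick path), `out_dir`, `schemes` (subset of
#'   P12/P123/P123R/P123RT), `window`/`step` (defaults 300/25),
#'   `code_id` (default 5), `seed` (default 1), `stages` (character
#'   vector; default all).
#' @return validated config list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(schemes = .SCHEMES, window = 300, step = 25,
                   code_id = 5, seed = 1,
                   stages = c("composition", "codon_usage", "divergence",
                              "diversity", "kaks", "supermatrix", "tree",
                              "informativeness"),
                   tree = NULL)
  config <- utils::modifyList(defaults, config)
  need <- c("records_dir", "taxonomy", "alignments_dir", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) abort(sprintf("run config missing field(s): %s",
                                  paste(miss, collapse = ", ")))
  for (p in c("records_dir", "taxonomy", "alignments_dir")) {
    if (!file.exists(config[[p]])) abort(sprintf("%s does not exist: %s", p, config[[p]]))
  }
  if (!(config$window > config$step && config$step > 0)) {
    abort("window must exceed step and step must be positive")
  }
  bad <- setdiff(config$schemes, .SCHEMES)
  if (length(bad)) abort(sprintf("unknown scheme(s): %s", paste(bad, collapse = ", ")))
  config
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Executes the enabled stages in dependency order on a directory of
#' GenBank records plus per-gene aligned FASTA blocks, writing plain-text
#' tables under `out_dir` and a JSON run manifest. A rerun with unchanged
#' config and inputs skips up-to-date stages.
#'
#' @param config see [run_config()].
#' @return the manifest (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  inputs <- .input_checksums(c(config$records_dir, config$taxonomy,
                               config$alignments_dir, config$tree))
  input_hash <- .hash_string(paste(inputs, collapse = ""))
  header <- .header_line(cfg_hash, input_hash)

  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else NULL
  fresh <- !is.null(old_manifest) &&
    identical(old_manifest$config_hash, cfg_hash) &&
    identical(old_manifest$input_hash, input_hash)

  up_to_date <- function(paths) {
    fresh && all(file.exists(file.path(out, paths)))
  }

  # ---- ingest (always; everything downstream needs it) --------------------
  taxonomy <- load_taxonomy(config$taxonomy)
  rec_files <- sort(list.files(config$records_dir, pattern = "\\.gb$",
                               full.names = TRUE))
  records <- lapply(rec_files, parse_genbank)
  names(records) <- vapply(records, `[[`, character(1), "sample_id")
  aln_files <- sort(list.files(config$alignments_dir, pattern = "\\.fasta$",
                               full.names = TRUE))
  blocks <- lapply(aln_files, function(f) {
    g <- sub("\\.fasta$", "", basename(f))
    read_aligned_fasta(f, gene = g, is_coding = g %in% mito_gene_order("PCG"))
  })
  names(blocks) <- vapply(blocks, `[[`, character(1), "gene")
  code <- genetic_code(config$code_id)
  pcg_blocks <- blocks[intersect(mito_gene_order("PCG"), names(blocks))]

  ran <- character(0); skipped <- character(0); failed <- NULL
  run_stage <- function(name, outputs, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    if (up_to_date(outputs)) {
      skipped <<- c(skipped, name)
      return(invisible(NULL))
    }
    tryCatch({
      fn()
      ran <<- c(ran, name)
    }, error = function(e) {
      failed <<- list(stage = name, error = conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    invisible(NULL)
  }

  run_stage("composition", "composition.tsv", function() {
    tab <- suppressWarnings(composition_report(records, taxonomy))
    .write_table(tab, file.path(out, "composition.tsv"), header)
  })

  run_stage("codon_usage", c("codon_usage_indices.tsv", "rscu_by_tribe.tsv",
                             "usage_correlations.tsv"), function() {
    idx <- codon_usage_report(records, taxonomy, code)
    .write_table(idx, file.path(out, "codon_usage_indices.tsv"), header)
    .write_table(rscu_by_group(records, taxonomy, "tribe", code),
                 file.path(out, "rscu_by_tribe.tsv"), header)
    samp <- idx[idx$level == "sample", ]
    corr <- dplyr::bind_rows(
      dplyr::mutate(correlate(samp$gc3s, samp$enc), pair = "ENC~GC3s"),
      dplyr::mutate(correlate(samp$gc3s, samp$cbi), pair = "CBI~GC3s"))
    .write_table(corr, file.path(out, "usage_correlations.tsv"), header)
  })

  dms <- NULL
  get_dms <- function() {
    if (is.null(dms)) dms <<- lapply(pcg_blocks, k2p_matrix)
    dms
  }

  run_stage("divergence", "rank_distances.tsv", function() {
    dir.create(file.path(out, "distances"), showWarnings = FALSE)
    summaries <- purrr::imap_dfr(get_dms(), function(dm, g) {
      .write_table(tibble::as_tibble(as.data.frame(unclass(dm)), rownames = "sample_id"),
                   file.path(out, "distances", paste0(g, ".k2p.tsv")), header)
      rank_mean_distances(dm, taxonomy)
    })
    .write_table(summaries, file.path(out, "rank_distances.tsv"), header)
  })

  run_stage("diversity", c("diversity_profile.tsv", "diversity_summary.tsv"), function() {
    profs <- purrr::map(pcg_blocks, function(b) {
      suppressWarnings(sliding_pi(b, config$window, config$step))
    })
    .write_table(dplyr::bind_rows(profs), file.path(out, "diversity_profile.tsv"), header)
    summ <- purrr::imap_dfr(profs, function(p, g) {
      tibble(gene = g, mean_pi = attr(p, "mean_pi"),
             mean_window_pi = if (nrow(p)) mean(p$pi) else NA_real_,
             n_windows = nrow(p))
    })
    .write_table(summ, file.path(out, "diversity_summary.tsv"), header)
  })

  run_stage("kaks", "kaks.tsv", function() {
    # one representative per tribe keeps the counting-method cost modest
    reps <- taxonomy |>
      dplyr::group_by(.data$tribe) |>
      dplyr::slice_min(.data$sample_id, n = 1) |>
      dplyr::pull(.data$sample_id)
    tab <- purrr::imap_dfr(pcg_blocks, function(b, g) {
      seqs <- block_sequences(b)
      have <- intersect(reps, names(seqs))
      if (length(have) < 2) return(NULL)
      pairs <- utils::combn(sort(have), 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
        a <- pairs[1, i]; b2 <- pairs[2, i]
        dplyr::mutate(nei_gojobori(seqs[[a]], seqs[[b2]], code),
                      gene = g, sample_a = a, sample_b = b2, .before = 1)
      })
    })
    .write_table(tab, file.path(out, "kaks.tsv"), header)
  })

  sms <- list()
  run_stage("supermatrix", paste0("supermatrix_", config$schemes, ".phy"), function() {
    for (sc in config$schemes) {
      sm <- build_supermatrix(blocks, sc)
      sms[[sc]] <<- sm
      write_supermatrix(sm, file.path(out, sprintf("supermatrix_%s.phy", sc)))
      writeLines(export_partitions(sm, "nexus_sets"),
                 file.path(out, sprintf("partitions_%s.nex", sc)))
      writeLines(export_partitions(sm, "raxml"),
                 file.path(out, sprintf("partitions_%s.raxml", sc)))
    }
  })

  tree_env <- new.env()
  run_stage("tree", c("tree_upgma.nwk", "tree_nj.nwk"), function() {
    sm <- sms[["P123RT"]] %||% build_supermatrix(blocks, "P123RT")
    seqs <- apply(sm$matrix, 1, paste, collapse = "")
    n <- length(seqs)
    D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- k2p(seqs[[i]], seqs[[j]])$d
    }
    tree_env$upgma <- upgma_tree(D)
    write_newick(tree_env$upgma, file.path(out, "tree_upgma.nwk"))
    write_newick(nj_tree(D), file.path(out, "tree_nj.nwk"))
  })

  run_stage("informativeness", c("informativeness.tsv", "pi_ranking.tsv"), function() {
    tr <- if (!is.null(config$tree)) {
      read_newick(config$tree)
    } else if (!is.null(tree_env$upgma)) {
      tree_env$upgma
    } else {
      read_newick(file.path(out, "tree_upgma.nwk"))
    }
    if (!is_ultrametric_tree(tr)) abort("informativeness needs an ultrametric tree")
    tr <- normalize_depth(tr)
    sm <- sms[["P123R"]] %||% build_supermatrix(blocks, "P123R")
    res <- pi_profiles_by_partition(sm, tr)
    .write_table(res$profiles, file.path(out, "informativeness.tsv"), header)
    mid <- res$profiles$time[which.min(abs(res$profiles$time - 0.5))][1]
    .write_table(rank_partitions(res$profiles, mid),
                 file.path(out, "pi_ranking.tsv"), header)
  })

  manifest <- list(tool = "mitocomp",
                   version = as.character(utils::packageVersion("mitocomp")),
                   config_hash = cfg_hash, input_hash = input_hash,
                   stages_run = as.list(ran), stages_skipped = as.list(skipped),
                   n_records = length(records), n_blocks = length(blocks),
                   inputs = as.list(inputs))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
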