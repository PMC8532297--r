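test_that("configuration validation enforces the documented invariants", {
  plan <- tibble::tibble(gene = "cox1", type = "PCG", length = 300, rate = 1)
  tr <- "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);"
  cfg <- simulation_config(tr, gene_plan = plan)
  expect_s3_class(cfg, "simulation_config")
  expect_error(simulation_config(tr, gene_plan = dplyr::mutate(plan, length = 301)),
               "multiples of 3")
  expect_error(simulation_config(tr, gene_plan = dplyr::mutate(plan, rate = 0)),
               "positive")
  expect_error(simulation_config(tr, gene_plan = plan,
                                 base_freqs = c(A = .5, C = .2, G = .2, T = .2)),
               "sum to 1")
  tax <- tibble::tibble(sample_id = c("a", "b"), subfamily = "S", tribe = "T",
                        genus = "G", species = c("s1", "s2"),
                        individual = c("a", "b"))
  expect_error(simulation_config(tr, gene_plan = plan, taxonomy = tax),
               "match the tree tips")
})

test_that("simulation is deterministic and a zero-length tree yields identical tips", {
  plan <- tibble::tibble(gene = c("cox1", "rrnS"), type = c("PCG", "rRNA"),
                         length = c(90, 50), rate = c(1, 0.5))
  cfg <- simulation_config("((a:0.05,b:0.05):0.02,c:0.07);", seed = 7,
                           gene_plan = plan)
  s1 <- simulate_set(cfg)
  s2 <- simulate_set(cfg)
  expect_identical(s1$blocks$cox1$matrix, s2$blocks$cox1$matrix)
  expect_identical(s1$records$a$sequence, s2$records$a$sequence)
  s3 <- simulate_set(simulation_config("((a:0.05,b:0.05):0.02,c:0.07);", seed = 8,
                                       gene_plan = plan))
  expect_false(identical(s1$blocks$cox1$matrix, s3$blocks$cox1$matrix))
  # star tree with zero branch lengths: no substitutions at all
  star <- simulate_set(simulation_config("(a:0,b:0,c:0);", seed = 1,
                                         gene_plan = plan))
  expect_equal(star$blocks$cox1$matrix["a", ], star$blocks$cox1$matrix["b", ])
  expect_equal(star$blocks$rrnS$matrix["a", ], star$blocks$rrnS$matrix["c", ])
})

test_that("records assemble blocks in canonical order with consistent features", {
  plan <- tibble::tibble(gene = c("cox1", "nad2", "rrnL", "trnA"),
                         type = c("PCG", "PCG", "rRNA", "tRNA"),
                         length = c(30, 21, 25, 10), rate = 1)
  sim <- simulate_set(simulation_config("(a:0.02,b:0.02);", seed = 3,
                                        gene_plan = plan))
  rec <- sim$records$a
  expect_equal(rec$features$name, c("cox1", "nad2", "rrnL", "trnA"))
  expect_equal(nchar(rec$sequence), 30 + 21 + 25 + 10)
  # every annotated gene extracts back to its block row
  for (g in plan$gene) {
    expect_equal(extract_gene(rec, g),
                 paste(sim$blocks[[g]]$matrix["a", ], collapse = ""))
  }
})

test_that("K2P on simulated pairs matches the generating branch length", {
  # equal base frequencies: HKY reduces to K80 where K2P is consistent
  eq <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  plan <- tibble::tibble(gene = "rrnL", type = "rRNA", length = 10000, rate = 1)
  d_hat <- vapply(1:10, function(s) {
    sim <- simulate_set(simulation_config("(a:0.1,b:0.1);", seed = 100 + s,
                                          gene_plan = plan, base_freqs = eq))
    k2p_matrix(sim$blocks$rrnL)[1, 2]
  }, numeric(1))
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - 0.2), 3 * se + 1e-6)
})

test_that("K2P error shrinks as sequence length grows (estimator consistency)", {
  eq <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  err_at <- function(L, seeds) {
    plan <- tibble::tibble(gene = "rrnL", type = "rRNA", length = L, rate = 1)
    mean(vapply(seeds, function(s) {
      sim <- simulate_set(simulation_config("(a:0.08,b:0.08);", seed = s,
                                            gene_plan = plan, base_freqs = eq))
      abs(k2p_matrix(sim$blocks$rrnL)[1, 2] - 0.16)
    }, numeric(1)))
  }
  expect_lt(err_at(10000, 301:306), err_at(1000, 301:306))
})

test_that("k2p approaches the Jukes-Cantor distance under equal-rate generation", {
  # kappa = 1 with uniform frequencies is exactly JC
  eq <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  plan <- tibble::tibble(gene = "rrnL", type = "rRNA", length = 20000, rate = 1)
  diffs <- vapply(1:5, function(s) {
    sim <- simulate_set(simulation_config("(a:0.1,b:0.1);", seed = 200 + s,
                                          gene_plan = plan, base_freqs = eq,
                                          kappa = 1))
    m <- sim$blocks$rrnL$matrix
    p <- mean(m["a", ] != m["b", ])
    jc <- -0.75 * log(1 - 4 * p / 3)
    k2p_matrix(sim$blocks$rrnL)[1, 2] - jc
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(5) + 5e-4)
})

test_that("codon-position rate classes leave the expected divergence footprint", {
  plan <- tibble::tibble(gene = "cox1", type = "PCG", length = 9000, rate = 1)
  sim <- simulate_set(simulation_config("(a:0.15,b:0.15);", seed = 77,
                                        gene_plan = plan))
  m <- sim$blocks$cox1$matrix
  p_by_pos <- vapply(1:3, function(p) {
    idx <- seq(p, ncol(m), by = 3)
    mean(m["a", idx] != m["b", idx])
  }, numeric(1))
  expect_true(p_by_pos[3] > p_by_pos[1] && p_by_pos[1] > p_by_pos[2])
})

test_that("the study-like config has the documented shape", {
  cfg <- paper_like_config()
  expect_s3_class(cfg, "simulation_config")
  expect_length(cfg$tree$tip.label, 30)
  tx <- cfg$taxonomy
  expect_equal(dplyr::n_distinct(tx$subfamily), 2)
  expect_equal(dplyr::n_distinct(tx$tribe), 6)
  expect_equal(sum(table(tx$species) == 6), 1)   # one six-individual species
  expect_true(is_ultrametric_tree(cfg$tree))
  expect_equal(root_depth(cfg$tree), 0.075, tolerance = 1e-9)
  # conspecific terminal branches stay below 0.002
  consp <- tx$sample_id[tx$species %in% names(which(table(tx$species) == 6))]
  tip_edges <- cfg$tree$edge[, 2] %in% match(consp, cfg$tree$tip.label)
  expect_true(all(cfg$tree$edge.length[tip_edges] <= 0.002))
  plan <- cfg$gene_plan
  expect_equal(sum(plan$type == "PCG"), 13)
  expect_equal(sum(plan$type == "tRNA"), 22)
  expect_equal(plan$gene[which.max(plan$rate)], "nad6")
  expect_equal(plan$gene[which.min(plan$rate[plan$type == "PCG"])], "nad5")
  expect_true(all(plan$length[plan$type == "tRNA"] %in% 65:72))
})

test_that("site-rate estimation recovers the ordering of partition multipliers", {
  tr8 <- read_newick(paste0("(((t1:0.02,t2:0.02):0.02,(t3:0.02,t4:0.02):0.02):0.03,",
                            "((t5:0.02,t6:0.02):0.02,(t7:0.02,t8:0.02):0.02):0.03);"))
  correct <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    plan <- tibble::tibble(gene = c("rrnL", "rrnS", "trnA"),
                           type = c("rRNA", "rRNA", "tRNA"),
                           length = c(300, 300, 300), rate = c(0.5, 1, 2))
    sim <- simulate_set(simulation_config(tr8, seed = 400 + s, gene_plan = plan))
    trn <- normalize_depth(tr8)
    means <- vapply(c("rrnL", "rrnS", "trnA"), function(g) {
      mean(estimate_site_rates(sim$blocks[[g]], trn)$rates$lambda)
    }, numeric(1))
    if (means[["rrnL"]] < means[["rrnS"]] && means[["rrnS"]] < means[["trnA"]]) {
      correct <- correct + 1
    }
  }
  expect_gte(correct, ceiling(0.95 * n_rep))
})
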