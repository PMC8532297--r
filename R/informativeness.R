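# Phylogenetic-informativeness profiling: per-site substitution rates are
# estimated on a fixed ultrametric tree (depth normalized to 1) by
# maximum likelihood under Jukes-Cantor with Felsenstein pruning, then the
# quartet-internode informativeness rho(t; lambda) = 16 lambda^2 t
# exp(-4 lambda t) is summed over sites per partition. rho peaks at
# t = 1/(4 lambda), i.e. a site is most useful at depths matching its rate.

#' Per-site informativeness of a rate at a time depth
#'
#' `rho(t; lambda) = 16 * lambda^2 * t * exp(-4 * lambda * t)`; analytic
#' peak at `t = 1/(4*lambda)` with value `4*lambda/e`.
#'
#' @param lambda nonnegative site rate (on the depth-1 time scale).
#' @param t time depth in `(0, 1]`.
#' @return informativeness value(s).
#' @export
pi_rho <- function(lambda, t) {
  16 * lambda^2 * t * exp(-4 * lambda * t)
}

# Character matrix -> integer states (A,C,G,T -> 1..4; gap/N -> NA), rows
# ordered as the tree's tip labels (tips without data become all-missing).
.states_matrix <- function(m, tree) {
  extra <- setdiff(rownames(m), tree$tip.label)
  if (length(extra)) {
    abort(sprintf("samples absent from the tree: %s", paste(extra, collapse = ", ")))
  }
  out <- matrix(NA_integer_, length(tree$tip.label), ncol(m),
                dimnames = list(tree$tip.label, NULL))
  idx <- match(rownames(m), tree$tip.label)
  codes <- match(m, .DNA_LETTERS)  # non-ACGT -> NA
  out[idx, ] <- matrix(codes, nrow(m), ncol(m))
  out
}

# Vectorized Felsenstein pruning under JC with all branch lengths scaled
# by lambda; returns per-site likelihoods.
.jc_site_likelihood <- function(states, tree, lambda) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  n_site <- ncol(states)
  partial <- vector("list", n_tip + n_node)
  for (tip in seq_len(n_tip)) {
    P <- matrix(0, n_site, 4)
    s <- states[tip, ]
    known <- !is.na(s)
    P[cbind(which(known), s[known])] <- 1
    P[!known, ] <- 1
    partial[[tip]] <- P
  }
  root <- tr$edge[nrow(tr$edge), 1]
  for (i in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    e <- exp(-4 / 3 * lambda * tr$edge.length[i])
    C <- partial[[child]]
    contrib <- (1 - e) / 4 * rowSums(C) + e * C
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib else partial[[parent]] * contrib
  }
  rowSums(partial[[root]]) / 4
}

#' Likelihood of one alignment column under Jukes-Cantor
#'
#' Felsenstein pruning with uniform base frequencies and every branch
#' length multiplied by `lambda`; gaps and `N` are missing data (partial
#' likelihood of ones).
#'
#' @param column named character vector of bases (names = tip labels), or
#'   a single-column character matrix with row names.
#' @param tree rooted ultrametric `phylo` tree covering the column's taxa.
#' @param lambda nonnegative rate multiplier.
#' @return the column likelihood.
#' @export
column_likelihood <- function(column, tree, lambda) {
  if (lambda < 0) abort("lambda must be nonnegative")
  m <- if (is.matrix(column)) toupper(column) else
    matrix(toupper(column), ncol = 1, dimnames = list(names(column), NULL))
  .jc_site_likelihood(.states_matrix(m, tree), tree, lambda)[1]
}

#' Estimate per-site substitution rates on an ultrametric tree
#'
#' Per column, the rate multiplier maximizing the Jukes-Cantor pruning
#' likelihood is found by a coarse log-spaced grid bracket followed by
#' Brent refinement (tolerance `tol`). Invariant columns (or columns with
#' fewer than two non-missing taxa) short-circuit to rate 0; columns whose
#' estimate hits `rate_cap` are flagged so saturation artifacts stay
#' visible. Identical site patterns are collapsed before optimization.
#'
#' @param x an `alignment_block`, `supermatrix`, or character matrix
#'   (samples x sites) with row names matching tree tips.
#' @param tree rooted ultrametric `phylo`; depth is normalized to 1
#'   automatically if it is not already.
#' @param rate_cap maximum allowed rate on the depth-1 scale (default 20).
#' @param tol optimization tolerance (default 1e-6).
#' @param partition label for the resulting rate set.
#' @return object of class `site_rates`: list with `partition`, `rates`
#'   (tibble `site`, `lambda`, `invariant`, `capped`, `n_obs`),
#'   `rate_cap`, `n_invariant`.
#' @export
estimate_site_rates <- function(x, tree, rate_cap = 20, tol = 1e-6,
                                partition = NULL) {
  m <- if (inherits(x, "alignment_block")) {
    partition <- partition %||% x$gene
    x$matrix
  } else if (inherits(x, "supermatrix")) {
    partition <- partition %||% x$name
    x$matrix
  } else {
    partition <- partition %||% "partition"
    toupper(x)
  }
  if (!is_ultrametric_tree(tree)) abort("tree must be ultrametric")
  if (abs(root_depth(tree) - 1) > 1e-6) tree <- normalize_depth(tree)
  states <- .states_matrix(m, tree)
  n_site <- ncol(states)
  n_obs <- colSums(!is.na(states))
  invariant <- vapply(seq_len(n_site), function(j) {
    s <- states[, j]
    length(unique(s[!is.na(s)])) <= 1
  }, logical(1)) | n_obs < 2

  lambda <- numeric(n_site)
  capped <- logical(n_site)
  var_idx <- which(!invariant)
  if (length(var_idx)) {
    key <- apply(states[, var_idx, drop = FALSE], 2, paste, collapse = ".")
    groups <- split(seq_along(var_idx), key)
    reps <- vapply(groups, `[[`, integer(1), 1)
    pat_states <- states[, var_idx[reps], drop = FALSE]
    grid <- exp(seq(log(0.01), log(rate_cap), length.out = 40))
    ll <- vapply(grid, function(lam) {
      log(.jc_site_likelihood(pat_states, tree, lam))
    }, numeric(ncol(pat_states)))
    if (ncol(pat_states) == 1) ll <- matrix(ll, nrow = 1)
    best <- apply(ll, 1, which.max)
    est <- vapply(seq_along(reps), function(p) {
      i <- best[p]
      lo <- if (i == 1) 0 else grid[i - 1]
      hi <- if (i == length(grid)) rate_cap else grid[i + 1]
      one <- pat_states[, p, drop = FALSE]
      stats::optimize(function(lam) .jc_site_likelihood(one, tree, lam),
                      c(lo, hi), maximum = TRUE, tol = tol)$maximum
    }, numeric(1))
    for (k in seq_along(groups)) {
      cols <- var_idx[groups[[k]]]
      lambda[cols] <- est[k]
      capped[cols] <- est[k] >= rate_cap * (1 - 1e-4)
    }
    lambda[capped & lambda > rate_cap] <- rate_cap
  }
  structure(
    list(partition = partition,
         rates = tibble(site = seq_len(n_site), lambda = lambda,
                        invariant = invariant, capped = capped,
                        n_obs = as.integer(n_obs)),
         rate_cap = rate_cap,
         n_invariant = sum(invariant)),
    class = "site_rates")
}

#' @export
print.site_rates <- function(x, ...) {
  cat(sprintf("<site_rates> %s: %d sites (%d invariant, %d capped), rate cap %g\n",
              x$partition, nrow(x$rates), x$n_invariant,
              sum(x$rates$capped), x$rate_cap))
  invisible(x)
}

#' Phylogenetic-informativeness profile of a partition
#'
#' Net informativeness at each time is the sum over sites of
#' [pi_rho()]; per-site informativeness divides by the partition's site
#' count (invariant sites included, contributing zero).
#'
#' @param rates a `site_rates` object, or a numeric vector of per-site
#'   rates.
#' @param times time grid on `(0, 1]`; default 200 uniform points.
#' @param partition label override.
#' @return object of class `pi_profile`: tibble with `partition`, `time`,
#'   `net`, `per_site`; attributes `peak_time` (argmax of net over the
#'   grid) and `n_sites`.
#' @export
pi_profile <- function(rates, times = seq_len(200) / 200, partition = NULL) {
  if (inherits(rates, "site_rates")) {
    partition <- partition %||% rates$partition
    lam <- rates$rates$lambda
  } else {
    partition <- partition %||% "partition"
    lam <- rates
  }
  if (any(times <= 0 | times > 1)) abort("times must lie in (0, 1]")
  L <- length(lam)
  net <- vapply(times, function(t) sum(pi_rho(lam, t)), numeric(1))
  out <- tibble(partition = partition, time = times, net = net,
                per_site = if (L > 0) net / L else 0 * net)
  structure(out, peak_time = if (any(net > 0)) times[which.max(net)] else NA_real_,
            n_sites = L, class = c("pi_profile", class(out)))
}

#' Rank partitions by informativeness at a time depth
#'
#' @param profiles a list of `pi_profile`s or a combined tibble with
#'   columns `partition`, `time`, `net` (and optionally `per_site`).
#' @param t time at which to rank; must lie on the common grid.
#' @param measure `"net"` or `"per_site"`.
#' @return tibble `partition`, value at `t`, sorted descending; ties
#'   broken by label.
#' @export
rank_partitions <- function(profiles, t, measure = c("net", "per_site")) {
  measure <- match.arg(measure)
  tab <- if (is.data.frame(profiles)) profiles else dplyr::bind_rows(profiles)
  hit <- abs(tab$time - t) < 1e-9
  if (!any(hit)) abort(sprintf("t = %g is not on the profile time grid", t))
  tab[hit, ] |>
    dplyr::select("partition", dplyr::all_of(measure)) |>
    dplyr::arrange(dplyr::desc(.data[[measure]]), .data$partition)
}
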