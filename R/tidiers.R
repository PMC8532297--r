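# broom-style accessors for the fitted/derived objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-site rate estimates
#'
#' @param x a `site_rates` object.
#' @param ... ignored.
#' @return tibble with `partition`, `site`, `lambda`, `invariant`,
#'   `capped`, `n_obs`.
#' @export
tidy.site_rates <- function(x, ...) {
  dplyr::mutate(x$rates, partition = x$partition, .before = 1)
}

#' One-row summary of per-site rate estimates
#'
#' @param x a `site_rates` object.
#' @param ... ignored.
#' @return tibble with site counts, invariant/capped counts, mean and max
#'   rate.
#' @export
glance.site_rates <- function(x, ...) {
  tibble(partition = x$partition, n_sites = nrow(x$rates),
         n_invariant = x$n_invariant, n_capped = sum(x$rates$capped),
         mean_lambda = mean(x$rates$lambda), max_lambda = max(x$rates$lambda),
         rate_cap = x$rate_cap)
}

#' Tidy an informativeness profile
#'
#' @param x a `pi_profile`.
#' @param ... ignored.
#' @return plain tibble of `partition`, `time`, `net`, `per_site`.
#' @export
tidy.pi_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("partition", "time", "net", "per_site")])
}

#' One-row summary of an informativeness profile
#'
#' @param x a `pi_profile`.
#' @param ... ignored.
#' @return tibble with `partition`, `peak_time`, `peak_net`, `n_sites`.
#' @export
glance.pi_profile <- function(x, ...) {
  tibble(partition = x$partition[1], peak_time = attr(x, "peak_time"),
         peak_net = max(x$net), n_sites = attr(x, "n_sites"))
}

#' Tidy a sliding diversity profile
#'
#' @param x a `diversity_profile`.
#' @param ... ignored.
#' @return plain tibble of `gene`, `midpoint`, `pi`.
#' @export
tidy.diversity_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene", "midpoint", "pi")])
}

#' One-row summary of a sliding diversity profile
#'
#' @param x a `diversity_profile`.
#' @param ... ignored.
#' @return tibble with genewide `mean_pi`, window geometry and count.
#' @export
glance.diversity_profile <- function(x, ...) {
  tibble(gene = if (nrow(x)) x$gene[1] else NA_character_,
         mean_pi = attr(x, "mean_pi"), window = attr(x, "window"),
         step = attr(x, "step"), n_windows = nrow(x))
}
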