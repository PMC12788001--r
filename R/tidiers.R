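# broom-style tidiers for the package's fitted/derived objects.

#' @describeIn screen_mixture Per-sample verdict table.
#' @param x A `scar_screen` object.
#' @param ... Unused.
#' @export
tidy.scar_screen <- function(x, ...) x$verdicts

#' @describeIn screen_mixture One-row batch summary: product counts, the
#'   adulteration rate, and the adulteration percentage rounded to the
#'   nearest whole percent (the convention of batch surveys).
#' @export
glance.scar_screen <- function(x, ...) {
  n <- nrow(x$verdicts)
  n_adult <- sum(x$verdicts$verdict == "adulterated")
  tibble(
    n_products = n,
    n_adulterated = n_adult,
    n_pure_at_lod = n - n_adult,
    adulteration_rate = n_adult / n,
    adulteration_percent = as.integer(round(100 * n_adult / n))
  )
}

#' @describeIn bootstrap_support Internal-edge support table.
#' @param x A `scar_boottree`.
#' @param ... Unused.
#' @export
tidy.scar_boottree <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  tibble(
    node = seq_along(x$support) + n_tip,
    support = as.numeric(x$support)
  )
}

#' @describeIn bootstrap_support One-row summary of the bootstrapped tree.
#' @export
glance.scar_boottree <- function(x, ...) {
  s <- x$support[!is.na(x$support)]
  tibble(
    n_tips = length(x$tree$tip.label),
    B = x$B,
    seed = x$seed,
    min_support = if (length(s)) min(s) else NA_real_,
    mean_support = if (length(s)) mean(s) else NA_real_
  )
}

#' @describeIn k2p_matrix Long pairwise-distance table.
#' @param x A `scar_k2p` object.
#' @param ... Unused.
#' @export
tidy.scar_k2p <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    taxon_a = x$taxa[idx[, 1]],
    taxon_b = x$taxa[idx[, 2]],
    d = x$d[idx],
    n_sites = x$n[idx]
  )
}

#' @describeIn specificity_matrix One-row summary: dimensions, positive
#'   cells, and whether the matrix is strictly diagonal.
#' @param x A `scar_specificity` tibble.
#' @export
glance.scar_specificity <- function(x, ...) {
  tibble(
    n_pairs = dplyr::n_distinct(x$pair_id),
    n_species = dplyr::n_distinct(x$species),
    n_positive_cells = sum(x$positive),
    n_offtarget_positive = sum(x$positive & x$species != x$target_species),
    diagonal = specificity_is_diagonal(x)
  )
}
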