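# Barcode validation phylogenetics: Kimura two-parameter distances with
# pairwise deletion, Saitou-Nei neighbor-joining with deterministic
# tie-breaking, column-resampling bootstrap, and monophyly testing on the
# outgroup-rooted tree. The distance and tree algorithms are implemented
# here; ape supplies the tree container and is used as an independent
# cross-check in the test suite, never as the implementation.

# encode gapped rows as integers 1..4 (ACGT), NA for gap/N/ambiguity
encode_row <- function(seq) {
  ch <- seq_chars(seq)
  m <- match(ch, SCAR_BASES)
  m
}

k2p_from_encoded <- function(ea, eb) {
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0) {
    abort("no shared ungapped sites (undefined distance)", class = "scar_distance_error")
  }
  a <- ea[ok]; b <- eb[ok]
  diff <- a != b
  # transitions: A<->G (1,3) and C<->T (2,4); purine/pyrimidine parity trick
  transition <- diff & ((a %% 2) == (b %% 2))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    abort("K2P distance saturated (log argument <= 0)", class = "scar_distance_error")
  }
  d <- -0.5 * log(arg1 * sqrt(arg2))
  list(d = d, P = P, Q = Q, n = n)
}

#' Kimura two-parameter distance between two aligned rows
#'
#' Sites where either row carries a gap, `N`, or any ambiguity code are
#' deleted pairwise (ambiguity is treated as missing data, the usual
#' distance-software default). With `P` and `Q` the transition and
#' transversion proportions over the `n` retained sites, the distance is
#' `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`.
#'
#' @param a,b Gapped aligned sequences of equal length.
#' @return One-row tibble: `d`, `P`, `Q`, `n`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")  # d = 0
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("aligned rows must have equal length", class = "scar_precondition_error")
  }
  r <- k2p_from_encoded(encode_row(a), encode_row(b))
  tibble(d = r$d, P = r$P, Q = r$Q, n = r$n)
}

#' K2P distance matrix of an alignment
#'
#' All pairwise [k2p_distance()] values, with the per-pair effective site
#' counts after pairwise deletion.
#'
#' @param alignment Aligned panel tibble (outgroup rows included).
#' @return A `scar_k2p` object: list with `taxa`, symmetric matrix `d`, and
#'   matrix `n` of effective sites. `as.dist()` and `tidy()` methods apply.
#' @export
k2p_matrix <- function(alignment) {
  validate_panel(alignment, require_aligned = TRUE)
  enc <- lapply(alignment$seq, encode_row)
  k <- nrow(alignment)
  d <- matrix(0, k, k, dimnames = list(alignment$id, alignment$id))
  nm <- matrix(NA_integer_, k, k, dimnames = dimnames(d))
  diag(nm) <- vapply(enc, function(e) sum(!is.na(e)), integer(1))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- k2p_from_encoded(enc[[i]], enc[[j]])
      d[i, j] <- d[j, i] <- r$d
      nm[i, j] <- nm[j, i] <- r$n
    }
  }
  structure(list(taxa = alignment$id, d = d, n = nm), class = "scar_k2p")
}

#' @export
as.dist.scar_k2p <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' @export
print.scar_k2p <- function(x, ...) {
  cat(sprintf("K2P distance matrix: %d taxa, mean d = %.4f\n",
              length(x$taxa), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

# newick-escape taxon labels (quote if they contain newick metacharacters)
nwk_label <- function(x) {
  bad <- grepl("[():,;'[:space:]]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with deterministic tie-breaking (the
#' lowest-index pair wins). Negative branch lengths, which NJ can produce,
#' are clamped to zero by default; the unclamped tree is retained in the
#' `"raw_tree"` attribute.
#'
#' @param dm A `scar_k2p` object, a symmetric matrix with dimnames, or a
#'   `dist`.
#' @param clamp_negative Clamp negative branch lengths to 0 (default `TRUE`).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  if (inherits(dm, "scar_k2p")) dm <- dm$d
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  k <- nrow(dm)
  if (k < 3) abort("need >= 3 taxa", class = "scar_precondition_error")
  if (any(!is.finite(dm))) abort("undefined distances", class = "scar_distance_error")

  labels <- nwk_label(rownames(dm))  # current node -> newick subtree string
  D <- dm
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest-index pair among minima: scan column-major upper triangle
    Q[lower.tri(Q)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_lab <- sprintf("(%s:%s,%s:%s)", labels[i], fmt_bl(li, clamp_negative),
                       labels[j], fmt_bl(lj, clamp_negative))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    labels <- c(labels[keep], new_lab)
    rownames(D2) <- colnames(D2) <- seq_len(nrow(D2))
    D <- D2
  }
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- function(clamp) sprintf("(%s:%s,%s:%s,%s:%s);",
                                 labels[1], fmt_bl(lx, clamp),
                                 labels[2], fmt_bl(ly, clamp),
                                 labels[3], fmt_bl(lz, clamp))
  # raw lengths are rebuilt by re-running without clamping; cheap for these sizes
  tree <- ape::read.tree(text = nwk(clamp_negative))
  if (clamp_negative) {
    raw <- nj_tree(dm, clamp_negative = FALSE)
    attr(tree, "raw_tree") <- raw
  }
  tree
}

fmt_bl <- function(x, clamp) {
  if (clamp && x < 0) x <- 0
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing that bipartition. Fully
#' seeded and reproducible. On degenerate alignments with no variable
#' columns every replicate matrix is identical and the deterministic
#' tie-breaking yields the same resolved topology each time, so every
#' support is 100 (the documented behaviour).
#'
#' Replicates whose resampled distance matrix is undefined (saturation or no
#' shared sites) are redrawn, up to `10 * B` attempts.
#'
#' @param alignment Aligned panel tibble.
#' @param B Bootstrap replicates (default 1000, the conventional choice).
#' @param seed Integer seed.
#' @return A `scar_boottree`: list with `tree` (node labels = support
#'   percentages), `support`, `B`, `seed`. `tidy()`/`glance()` apply.
#' @export
bootstrap_support <- function(alignment, B = 1000, seed = 1) {
  if (B < 1) abort("B must be >= 1", class = "scar_precondition_error")
  validate_panel(alignment, require_aligned = TRUE)
  main <- nj_tree(k2p_matrix(alignment))
  L <- nchar(alignment$seq[[1]])
  mat <- alignment_matrix(alignment)
  boot_trees <- withr::with_seed(seed, {
    trees <- vector("list", B)
    attempts <- 0
    b <- 1
    while (b <= B && attempts < 10 * B) {
      attempts <- attempts + 1
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- alignment
      rep_aln$seq <- apply(mat[, cols, drop = FALSE], 1, chars_to_seq)
      t <- tryCatch(nj_tree(k2p_matrix(rep_aln)), scar_distance_error = function(e) NULL)
      if (!is.null(t)) { trees[[b]] <- t; b <- b + 1 }
    }
    if (b <= B) abort("too many undefined bootstrap replicates", class = "scar_distance_error")
    trees
  })
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  support <- 100 * counts / B
  main$node.label <- ifelse(is.na(support), "", format(round(support, 1), trim = TRUE))
  structure(list(tree = main, support = support, B = B, seed = seed,
                 boot_trees = boot_trees),
            class = "scar_boottree")
}

#' Bootstrap support for an arbitrary clade
#'
#' Percentage of bootstrap replicates in which the given taxa form a
#' monophyletic clade on the tree rooted at the outgroup -- the natural way
#' to read "species clade support" off a bootstrapped species panel.
#'
#' @param bt A `scar_boottree` (from [bootstrap_support()]).
#' @param taxa Tip labels of the putative clade.
#' @param outgroup Tip label(s) used for rooting.
#' @return Numeric percentage in `[0, 100]`.
#' @export
clade_support <- function(bt, taxa, outgroup) {
  stopifnot(inherits(bt, "scar_boottree"))
  hits <- vapply(bt$boot_trees, function(t) is_monophyletic(t, taxa, outgroup),
                 logical(1))
  100 * mean(hits)
}

#' @export
print.scar_boottree <- function(x, ...) {
  cat(sprintf("NJ tree with bootstrap support: %d tips, B = %d, seed = %d\n",
              length(x$tree$tip.label), x$B, x$seed))
  s <- x$support[!is.na(x$support)]
  if (length(s)) cat(sprintf("  support: min %.1f, median %.1f, max %.1f\n",
                             min(s), stats::median(s), max(s)))
  invisible(x)
}

#' Test monophyly of a taxon set on an outgroup-rooted tree
#'
#' Roots the tree at the outgroup and asks whether the given leaves form an
#' exclusive clade.
#'
#' @param tree An `ape::phylo` tree (or `scar_boottree`).
#' @param taxa Leaf labels whose monophyly is tested.
#' @param outgroup Leaf label(s) used for rooting; must be disjoint from
#'   `taxa`.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  if (inherits(tree, "scar_boottree")) tree <- tree$tree
  missing <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(missing)) {
    abort(paste0("unknown leaves: ", paste(missing, collapse = ", ")),
          class = "scar_lookup_error")
  }
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) ape::root(tree, outgroup = outgroup[[1]], resolve.root = TRUE)
  )
  ape::is.monophyletic(rooted, taxa)
}

#' Per-species monophyly report for a panel
#'
#' Convenience wrapper: tests, for every target-panel species, whether its
#' accessions form a clade on the tree rooted at the outgroup records.
#'
#' @param tree `ape::phylo` or `scar_boottree` whose tips are panel ids.
#' @param panel The panel tibble the tree was built from.
#' @param outgroup Outgroup tip ids; defaults to the panel's
#'   `role == "outgroup"` records.
#' @return Tibble: `species`, `n_accessions`, `monophyletic`.
#' @export
species_monophyly <- function(tree, panel, outgroup = NULL) {
  if (inherits(tree, "scar_boottree")) tree <- tree$tree
  if (is.null(outgroup)) {
    if (!"role" %in% names(panel) || !any(panel$role == "outgroup")) {
      abort("no outgroup records in panel; supply `outgroup`", class = "scar_config_error")
    }
    outgroup <- panel$id[panel$role == "outgroup"]
  }
  targets <- panel[!panel$id %in% outgroup, ]
  targets |>
    group_by(.data$species) |>
    summarise(
      n_accessions = n(),
      monophyletic = is_monophyletic(tree, .data$id, outgroup),
      .groups = "drop"
    )
}
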