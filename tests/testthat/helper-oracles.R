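# Independent oracles used to verify the package's algorithms. These are
# deliberately naive (loops, exhaustive enumeration, closed forms) and share
# no code with the implementation.

# --- affine-gap global alignment score, Gotoh DP -----------------------------
# a gap of length k costs open + k * extend (same convention as the package)
dp_align_score <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- brute-force primer-site scan -------------------------------------------
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

brute_force_sites <- function(template, primer, max_mm = 3, clamp_len = 2,
                              exempt = integer()) {
  tch <- strsplit(template, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") primer else rc_oracle(primer)
    pch <- strsplit(probe, "")[[1]]
    lp <- length(pch); lt <- length(tch)
    if (lp > lt) next
    for (s in seq_len(lt - lp + 1)) {
      mm <- integer(0)
      for (k in seq_len(lp)) {
        tc <- tch[s + k - 1]
        if (!(tc %in% names(iupac_sets)) || !(pch[k] %in% iupac_sets[[tc]])) {
          mm <- c(mm, k)
        }
      }
      if (length(mm) > max_mm) next
      from3 <- if (strand == "+") lp - mm + 1L else mm
      out[[length(out) + 1]] <- data.frame(
        strand = strand, start = s, end = s + lp - 1L,
        n_mismatches = length(mm),
        clamp_ok = !any(from3 <= clamp_len & !(from3 %in% exempt))
      )
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), start = integer(), end = integer(),
                      n_mismatches = integer(), clamp_ok = logical()))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$start), ]
}

brute_force_amplicons <- function(template, fwd, rev, max_mm = 3,
                                  clamp_len = 2, max_product = 2000) {
  f <- brute_force_sites(template, fwd, max_mm, clamp_len)
  f <- f[f$strand == "+" & f$clamp_ok, , drop = FALSE]
  r <- brute_force_sites(template, rev, max_mm, clamp_len)
  r <- r[r$strand == "-" & r$clamp_ok, , drop = FALSE]
  lens <- integer(0)
  if (nrow(f) && nrow(r)) {
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(r))) {
        L <- r$end[j] - f$start[i] + 1L
        if (L > 0 && L <= max_product) lens <- c(lens, L)
      }
    }
  }
  sort(lens)
}

# --- brute-force minimum-evolution tree search -------------------------------
# all unrooted binary topologies on n labeled leaves (105 for n = 6):
# start from the 3-leaf star (internal node n+1), insert leaves 4..n on
# every existing edge
enumerate_topologies <- function(n) {
  start <- rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3))
  grow <- function(edges, next_leaf, next_internal) {
    if (next_leaf > n) return(list(edges))
    out <- list()
    for (e in seq_len(nrow(edges))) {
      v <- next_internal
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], v), c(v, edges[e, 2]), c(v, next_leaf))
      out <- c(out, grow(new_edges, next_leaf + 1L, next_internal + 1L))
    }
    out
  }
  grow(start, 4L, n + 2L)
}

# leaf-to-leaf paths as an incidence matrix over edges
path_matrix <- function(edges, n) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(setNames(nodes, nodes), function(v) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
    adj[[a]] <- c(adj[[a]], e); adj[[b]] <- c(adj[[b]], e)
  }
  other_end <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    # DFS from leaf a to leaf b recording edges
    target <- pairs[p, 2]
    found <- FALSE
    dfs <- function(v, prev_e, path) {
      if (found) return()
      if (v == target) { A[p, path] <<- 1; found <<- TRUE; return() }
      for (e in adj[[as.character(v)]]) {
        if (!is.null(prev_e) && e == prev_e) next
        dfs(other_end(e, v), e, c(path, e))
      }
    }
    dfs(pairs[p, 1], NULL, integer(0))
  }
  A
}

# OLS minimum-evolution score of a topology for distance matrix dm (n x n)
ols_me_length <- function(edges, dm) {
  n <- nrow(dm)
  A <- path_matrix(edges, n)
  d <- dm[t(combn(n, 2))]
  b <- solve(crossprod(A), crossprod(A, d))
  sum(b)
}

brute_force_me_tree <- function(dm) {
  n <- nrow(dm)
  topos <- enumerate_topologies(n)
  scores <- vapply(topos, ols_me_length, numeric(1), dm = dm)
  best <- topos[[which.min(scores)]]
  # convert edge matrix to newick via ape: build phylo object
  nodes <- sort(unique(as.vector(best)))
  phy <- list(edge = best, Nnode = length(nodes) - n,
              tip.label = rownames(dm))
  # ape wants internal nodes numbered n+1..; ours already are
  class(phy) <- "phylo"
  phy$edge.length <- rep(1, nrow(best))
  ape::reorder.phylo(phy, "cladewise")
}
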