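# Multiple alignment: Needleman-Wunsch pairwise core (affine gaps) plus a
# center-star merge ("once a gap, always a gap"). ITS-like panels are short
# and closely related, so center-star is adequate and easy to verify;
# externally aligned FASTA is accepted verbatim.

scar_subst_matrix <- function(match = 1, mismatch = -1) {
  ab <- setdiff(SCAR_ALPHABET, "-")
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match  # ambiguity codes score as mismatch unless identical
  m
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment under affine-gap scoring. A gap of
#' length k scores `gap_open + k * gap_extend`. Ambiguity codes score as a
#' mismatch unless the symbols are identical (conservative for diagnostic-site
#' calling).
#'
#' @param a,b DNA strings (non-empty, ungapped).
#' @param match,mismatch,gap_open,gap_extend Scores (defaults +1/-1/-5/-1).
#' @return List with `a`, `b` (gapped aligned strings) and `score`.
#' @examples
#' pairwise_align("ACGT", "AGT")
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) abort("empty sequence", class = "scar_precondition_error")
  check_alphabet(c(a, b), allow_gaps = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = scar_subst_matrix(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap_extend
  )
  list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

# all-vs-one alignment scores, vectorized in C
star_scores <- function(seqs, params) {
  n <- length(seqs)
  sm <- scar_subst_matrix(params$match, params$mismatch)
  total <- numeric(n)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = seqs[-i], subject = seqs[[i]], type = "global",
      substitutionMatrix = sm, gapOpening = -params$gap_open,
      gapExtension = -params$gap_extend, scoreOnly = TRUE
    )
    total[i] <- sum(sc)
  }
  total
}

# merge one pairwise alignment (center_aln/new_aln) into the running master
# alignment, inserting gaps on whichever side lacks them
merge_star <- function(master_center, master_rows, center_aln, new_aln) {
  la <- length(master_center)
  lb <- length(center_aln)
  a <- 1L; b <- 1L
  idx_a <- integer(0); idx_b <- integer(0)
  while (a <= la || b <= lb) {
    ca <- if (a <= la) master_center[[a]] else NULL
    cb <- if (b <= lb) center_aln[[b]] else NULL
    if (!is.null(ca) && ca == "-") {
      idx_a <- c(idx_a, a); idx_b <- c(idx_b, 0L); a <- a + 1L
    } else if (!is.null(cb) && cb == "-") {
      idx_a <- c(idx_a, 0L); idx_b <- c(idx_b, b); b <- b + 1L
    } else {
      idx_a <- c(idx_a, a); idx_b <- c(idx_b, b); a <- a + 1L; b <- b + 1L
    }
  }
  take <- function(row, idx) {
    out <- rep("-", length(idx))
    out[idx > 0] <- row[idx[idx > 0]]
    out
  }
  list(
    center = take(master_center, idx_a),
    rows = map(master_rows, take, idx = idx_a),
    new_row = take(new_aln, idx_b)
  )
}

#' Center-star multiple alignment of a panel
#'
#' Picks the center sequence maximizing the summed pairwise alignment scores,
#' aligns every other sequence to it, and merges under "once a gap, always a
#' gap". If the input is already aligned (all sequences of equal length and
#' containing gaps) it is accepted verbatim. Row order is preserved and
#' degapping any row recovers its input sequence exactly.
#'
#' @param panel Panel tibble (see [read_panel()]).
#' @inheritParams pairwise_align
#' @return The panel tibble with gapped `seq` of equal width (an alignment).
#' @export
center_star_align <- function(panel, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  validate_panel(panel)
  n <- nrow(panel)
  if (n == 1) return(panel)
  widths <- nchar(panel$seq)
  if (length(unique(widths)) == 1 && any(grepl("-", panel$seq, fixed = TRUE))) {
    return(panel)  # pre-aligned input, accept verbatim
  }
  params <- list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend)
  seqs <- panel$seq
  center <- which.max(star_scores(seqs, params))
  sm <- scar_subst_matrix(match, mismatch)
  master_center <- seq_chars(seqs[[center]])
  others <- setdiff(seq_len(n), center)
  rows <- list()
  for (j in others) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[[j]], subject = seqs[[center]], type = "global",
      substitutionMatrix = sm, gapOpening = -gap_open, gapExtension = -gap_extend
    )
    m <- merge_star(master_center, rows,
                    seq_chars(as.character(Biostrings::alignedSubject(pa))),
                    seq_chars(as.character(Biostrings::alignedPattern(pa))))
    master_center <- m$center
    rows <- c(m$rows, list(m$new_row))
  }
  out <- character(n)
  out[center] <- chars_to_seq(master_center)
  out[others] <- map_chr(rows, chars_to_seq)
  panel$seq <- out
  validate_panel(panel, require_aligned = TRUE)
  panel
}

#' Per-column allele tallies by species
#'
#' Tabulates, for every alignment column, how many sequences of each species
#' carry each symbol. Gaps are counted as their own symbol `-`; ambiguity
#' codes are counted as themselves, never expanded.
#'
#' @param alignment Aligned panel tibble (equal-length gapped sequences).
#' @param include_outgroup Count records with role `"outgroup"`? Default
#'   `FALSE`: diagnostic-site discovery compares the target panel only.
#' @return Tibble with columns `column` (1-based), `species`, `base`, `count`
#'   and `species_n` (total rows of that species); attributes
#'   `alignment_length` and `species_n`.
#' @export
column_profiles <- function(alignment, include_outgroup = FALSE) {
  validate_panel(alignment, require_aligned = TRUE)
  if (!include_outgroup && "role" %in% names(alignment)) {
    alignment <- filter(alignment, .data$role != "outgroup")
  }
  if (nrow(alignment) == 0) abort("no target-panel records", class = "scar_precondition_error")
  m <- alignment_matrix(alignment)
  L <- ncol(m)
  prof <- tibble(
    column = rep(seq_len(L), each = nrow(m)),
    species = rep(alignment$species, times = L),
    base = as.vector(m)
  ) |>
    count(.data$column, .data$species, .data$base, name = "count")
  sp_n <- table(alignment$species)
  prof$species_n <- as.integer(sp_n[prof$species])
  attr(prof, "alignment_length") <- L
  attr(prof, "species_n") <- setNames(as.integer(sp_n), names(sp_n))
  class(prof) <- c("scar_profiles", class(prof))
  prof
}

# deterministic symbol ranking for consensus tie-breaks:
# higher count first, then A<C<G<T, then ambiguity codes, then gap
consensus_pick <- function(base, count) {
  ord <- order(-count, match(base, c(SCAR_BASES, setdiff(SCAR_ALPHABET, c(SCAR_BASES, "-")), "-")))
  base[ord[1]]
}

#' Per-species consensus symbol at every column
#'
#' Majority symbol within each species at each column, with a deterministic
#' tie-break (bases before ambiguity codes before gaps, then alphabetical).
#'
#' @param profiles Output of [column_profiles()].
#' @return Tibble `column`, `species`, `consensus`.
#' @export
species_consensus <- function(profiles) {
  profiles |>
    as_tibble() |>
    group_by(.data$column, .data$species) |>
    summarise(consensus = consensus_pick(.data$base, .data$count), .groups = "drop")
}

#' Overall consensus sequence of an alignment
#'
#' @param profiles Output of [column_profiles()].
#' @return Single gapped character string; an all-gap column yields `-`.
#' @export
consensus_sequence <- function(profiles) {
  cons <- profiles |>
    as_tibble() |>
    group_by(.data$column, .data$base) |>
    summarise(count = sum(.data$count), .groups = "drop_last") |>
    summarise(consensus = consensus_pick(.data$base, .data$count), .groups = "drop") |>
    arrange(.data$column)
  chars_to_seq(cons$consensus)
}
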