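# 3'-anchored (ARMS-style) primer design at diagnostic sites. The 3' terminus
# sits on the species-specific allele so polymerase extension fails on
# off-target templates; deliberate destabilizing substitutions near the 3'
# end raise specificity further.

# SantaLucia/Allawi unified nearest-neighbor parameters
# (dH kcal/mol, dS cal/(mol*K)) for duplex propagation 5'->3'
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

tm_wallace <- function(seq) {
  ch <- seq_chars(seq)
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

# nearest-neighbor Tm with SantaLucia entropy salt correction;
# dnac1/dnac2 in nM, Na in mM
tm_nn <- function(seq, dnac1 = 25, dnac2 = 25, Na = 50) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 2) abort("need >= 2 nt for nearest-neighbor Tm", class = "scar_precondition_error")
  steps <- paste0(ch[-n], ch[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (end in c(ch[1], ch[n])) {  # terminal initiation terms
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfcomp <- identical(chars_to_seq(ch), revcomp(chars_to_seq(ch)))
  if (selfcomp) {
    ds <- ds - 1.4
    conc <- dnac1 * 1e-9
  } else {
    conc <- (dnac1 - dnac2 / 2) * 1e-9
  }
  ds <- ds + 0.368 * (n - 1) * log(Na / 1000)  # salt correction
  R <- 1.987
  dh * 1000 / (ds + R * log(conc)) - 273.15
}

#' Estimate primer melting temperature
#'
#' `wallace`: the rule-of-thumb `2(A+T) + 4(G+C)`. `nn`: nearest-neighbor
#' thermodynamics with the unified SantaLucia parameter set, entropy-based
#' monovalent salt correction, and duplex concentration term; defaults are
#' 25 nM primer and complement and 50 mM Na+. Both are deterministic.
#'
#' @param seq Primer sequence(s), 5'->3', pure ACGT.
#' @param method `"wallace"` or `"nn"` (default).
#' @param dnac1,dnac2 Strand concentrations in nM (`nn` only).
#' @param Na Monovalent cation concentration in mM (`nn` only).
#' @return Melting temperature(s) in degrees Celsius.
#' @examples
#' tm_estimate("AAAA", method = "wallace")  # 8
#' tm_estimate("CATGCAACAGAACGGCCATCTTCT")
#' @export
tm_estimate <- function(seq, method = c("nn", "wallace"),
                        dnac1 = 25, dnac2 = 25, Na = 50) {
  method <- match.arg(method)
  if (any(!grepl("^[ACGT]+$", seq))) {
    abort("Tm estimation requires pure ACGT sequences", class = "scar_precondition_error")
  }
  vapply(seq, function(s) {
    if (method == "wallace") tm_wallace(s) else tm_nn(s, dnac1, dnac2, Na)
  }, numeric(1), USE.NAMES = FALSE)
}

empty_subs <- function() tibble(pos_from_3prime = integer(),
                                original = character(), new = character())

#' Enumerate 3'-anchored primer candidates at SSN sites
#'
#' For every SSN site and every length in `length_range`, emits a candidate
#' primer read off the target species' consensus whose 3' terminus sits
#' exactly on the diagnostic column. Forward candidates run leftward from the
#' site; reverse candidates cover the site and downstream columns and are
#' returned reverse-complemented 5'->3'. Candidates whose footprint would
#' contain an alignment gap or a non-ACGT consensus symbol, or would run off
#' the alignment edge, are silently not emitted.
#'
#' @param alignment Aligned panel tibble.
#' @param ssn_sites Tibble from [find_ssn_sites()] (any subset of rows).
#' @param length_range Integer vector `c(min, max)` primer length, default
#'   18-28 nt (the usual SCAR primer range).
#' @param strand `"forward"`, `"reverse"` or `"both"`.
#' @return Tibble of candidates: `target_species`, `strand`,
#'   `aln_3prime_column`, `seq_5to3`, `length`, `tm_C`, `gc_frac`, and
#'   list-column `substitutions` (empty; see [introduce_mismatches()]).
#' @export
enumerate_anchored_primers <- function(alignment, ssn_sites,
                                       length_range = c(18, 28),
                                       strand = c("both", "forward", "reverse")) {
  strand <- match.arg(strand)
  strands <- if (strand == "both") c("forward", "reverse") else strand
  profiles <- column_profiles(alignment)
  L <- attr(profiles, "alignment_length")
  cons <- species_consensus(profiles)

  out <- list()
  for (i in seq_len(nrow(ssn_sites))) {
    site <- ssn_sites[i, ]
    sp_cons <- cons$consensus[cons$species == site$target_species]
    for (st in strands) {
      for (len in seq(length_range[1], length_range[2])) {
        cols <- if (st == "forward") seq(site$column - len + 1, site$column)
                else seq(site$column, site$column + len - 1)
        if (cols[1] < 1 || cols[length(cols)] > L) next
        span <- sp_cons[cols]
        if (any(!span %in% SCAR_BASES)) next
        seq5 <- if (st == "forward") chars_to_seq(span) else revcomp(chars_to_seq(span))
        out[[length(out) + 1]] <- tibble(
          target_species = site$target_species,
          strand = st,
          aln_3prime_column = site$column,
          seq_5to3 = seq5,
          length = len
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(target_species = character(), strand = character(),
                  aln_3prime_column = integer(), seq_5to3 = character(),
                  length = integer(), tm_C = numeric(), gc_frac = numeric(),
                  substitutions = list()))
  }
  res <- bind_rows(out)
  res$tm_C <- tm_estimate(res$seq_5to3)
  res$gc_frac <- gc_fraction(res$seq_5to3)
  res$substitutions <- rep(list(empty_subs()), nrow(res))
  res
}

#' Introduce deliberate destabilizing substitutions near the 3' end
#'
#' Replaces `n_subs` bases inside a window counted from the 3' end with their
#' transversion partner (A<->C, G<->T), the maximally destabilizing change.
#' The default window is positions 2-4, leaving the diagnostic 3' terminus
#' untouched; widen the window to position 1 to allow terminal substitutions.
#' Positions are filled 3'-proximal first. Primer length never changes and
#' every change is recorded in the `substitutions` annotation.
#'
#' @param primers Candidate tibble from [enumerate_anchored_primers()].
#' @param n_subs Number of substitutions per primer (0-3; 0 is the identity).
#' @param window Integer `c(lo, hi)`: eligible positions from the 3' end.
#' @return The tibble with modified `seq_5to3`, refreshed `tm_C`/`gc_frac`
#'   and populated `substitutions` list-column
#'   (`pos_from_3prime`, `original`, `new`).
#' @export
introduce_mismatches <- function(primers, n_subs = 1, window = c(2, 4)) {
  if (n_subs < 0 || n_subs > 3) {
    abort("n_subs must be between 0 and 3", class = "scar_precondition_error")
  }
  if (n_subs == 0 || nrow(primers) == 0) return(primers)
  res <- primers
  for (i in seq_len(nrow(res))) {
    len <- nchar(res$seq_5to3[[i]])
    cand <- seq(max(1, window[1]), min(len, window[2]))
    if (length(cand) < n_subs) {
      abort("substitution window too small for requested n_subs",
            class = "scar_infeasible_error")
    }
    pos <- head(cand, n_subs)
    ch <- seq_chars(res$seq_5to3[[i]])
    idx <- len - pos + 1  # 5'-based index of each 3'-counted position
    orig <- ch[idx]
    ch[idx] <- SCAR_TRANSVERSION[orig]
    res$seq_5to3[[i]] <- chars_to_seq(ch)
    res$substitutions[[i]] <- bind_rows(
      res$substitutions[[i]],
      tibble(pos_from_3prime = as.integer(pos), original = orig,
             new = unname(SCAR_TRANSVERSION[orig]))
    )
  }
  res$tm_C <- tm_estimate(res$seq_5to3)
  res$gc_frac <- gc_fraction(res$seq_5to3)
  res
}

# map alignment columns to 1-based degapped positions on a gapped consensus
degapped_positions <- function(cons_chars) {
  pos <- cumsum(cons_chars != "-")
  pos[cons_chars == "-"] <- NA_integer_
  pos
}

#' Pair forward and reverse candidates under an amplicon-size cap
#'
#' Combines forward and reverse candidates of the same target species into
#' primer pairs. The expected amplicon is measured on the degapped target
#' consensus from the forward primer's 5' position through the reverse
#' primer's 5' position, inclusive of both primer footprints (the convention
#' that matches gel-measured SCAR product sizes). Pairs are filtered to
#' `0 < amplicon < max_amplicon` and balanced melting temperatures, then
#' sorted by a composite preference: amplicon inside `preferred_range`
#' first, then smallest Tm difference, then shortest amplicon.
#'
#' @param fwd,rev Candidate tibbles (forward / reverse strand).
#' @param alignment Aligned panel tibble (to place footprints on the degapped
#'   target consensus).
#' @param max_amplicon Exclusive upper bound on amplicon length (default 500,
#'   the small-amplicon design rule).
#' @param tm_tolerance Maximum |Tm(fwd) - Tm(rev)| in degrees C.
#' @param preferred_range Favoured amplicon interval (default 150-500 bp).
#' @return Tibble of pairs: `pair_id`, `target_species`, fwd/rev sequences
#'   and annotations, `expected_amplicon_bp`, `recommended_annealing_C`
#'   (min pair Tm - 3, a starting point for gradient PCR, not an empirical
#'   optimum).
#' @export
pair_primers <- function(fwd, rev, alignment, max_amplicon = 500,
                         tm_tolerance = 5, preferred_range = c(150, 500)) {
  profiles <- column_profiles(alignment)
  cons <- species_consensus(profiles)
  empty <- tibble(pair_id = character(), target_species = character(),
                  fwd_seq = character(), rev_seq = character(),
                  fwd_3prime_column = integer(), rev_3prime_column = integer(),
                  fwd_tm_C = numeric(), rev_tm_C = numeric(),
                  fwd_substitutions = list(), rev_substitutions = list(),
                  expected_amplicon_bp = integer(),
                  recommended_annealing_C = numeric())
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(empty)

  out <- list()
  for (sp in intersect(unique(fwd$target_species), unique(rev$target_species))) {
    sp_cons <- cons$consensus[cons$species == sp]
    dpos <- degapped_positions(sp_cons)
    f <- filter(fwd, .data$target_species == sp, .data$strand == "forward")
    r <- filter(rev, .data$target_species == sp, .data$strand == "reverse")
    if (nrow(f) == 0 || nrow(r) == 0) next
    grid <- tidyr::expand_grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
    fwd5 <- dpos[f$aln_3prime_column - f$length + 1]  # 5' end of fwd footprint
    rev5 <- dpos[r$aln_3prime_column + r$length - 1]  # 5' end of rev footprint
    amp <- rev5[grid$ri] - fwd5[grid$fi] + 1
    dtm <- abs(f$tm_C[grid$fi] - r$tm_C[grid$ri])
    keep <- !is.na(amp) & amp > 0 & amp < max_amplicon & dtm <= tm_tolerance
    if (!any(keep)) next
    grid <- grid[keep, ]; amp <- amp[keep]; dtm <- dtm[keep]
    out[[length(out) + 1]] <- tibble(
      target_species = sp,
      fwd_seq = f$seq_5to3[grid$fi],
      rev_seq = r$seq_5to3[grid$ri],
      fwd_3prime_column = f$aln_3prime_column[grid$fi],
      rev_3prime_column = r$aln_3prime_column[grid$ri],
      fwd_tm_C = f$tm_C[grid$fi],
      rev_tm_C = r$tm_C[grid$ri],
      fwd_substitutions = f$substitutions[grid$fi],
      rev_substitutions = r$substitutions[grid$ri],
      expected_amplicon_bp = as.integer(amp),
      in_preferred = amp >= preferred_range[1] & amp <= preferred_range[2],
      tm_diff = dtm
    )
  }
  if (!length(out)) return(empty)
  res <- bind_rows(out) |>
    arrange(.data$target_species, dplyr::desc(.data$in_preferred),
            .data$tm_diff, .data$expected_amplicon_bp) |>
    group_by(.data$target_species) |>
    mutate(pair_id = sprintf("%s_p%02d",
                             gsub("[^A-Za-z0-9]+", "-", .data$target_species[1]),
                             row_number())) |>
    ungroup() |>
    mutate(recommended_annealing_C = pmin(.data$fwd_tm_C, .data$rev_tm_C) - 3) |>
    select("pair_id", "target_species", "fwd_seq", "rev_seq",
           "fwd_3prime_column", "rev_3prime_column", "fwd_tm_C", "rev_tm_C",
           "fwd_substitutions", "rev_substitutions", "expected_amplicon_bp",
           "recommended_annealing_C")
  res
}

#' Build primer pairs from a primer table
#'
#' Groups a primer table (e.g. [descurainia_primers()]) by target species and
#' pairs each forward primer (name containing an F token) with the reverse
#' primer (R token), carrying over the published amplicon size and annealing
#' temperature where present.
#'
#' @param primer_table Tibble from [read_primer_table()].
#' @return Pair tibble compatible with the in-silico PCR functions:
#'   `pair_id`, `target_species`, `fwd_seq`, `rev_seq`, `fwd_subs`,
#'   `rev_subs` (annotated substitution positions from the 3' end),
#'   `expected_amplicon_bp`, `annealing_C`.
#' @export
primer_pairs_from_table <- function(primer_table) {
  primer_table |>
    group_by(.data$target_species) |>
    summarise(
      pair_id = paste(.data$primer_name[grepl("F", .data$primer_name)][1],
                      .data$primer_name[grepl("R", .data$primer_name)][1], sep = "/"),
      fwd_seq = .data$seq_5to3[grepl("F", .data$primer_name)][1],
      rev_seq = .data$seq_5to3[grepl("R", .data$primer_name)][1],
      fwd_subs = list(.data$substituted_positions[grepl("F", .data$primer_name)][[1]]),
      rev_subs = list(.data$substituted_positions[grepl("R", .data$primer_name)][[1]]),
      expected_amplicon_bp = if ("expected_amplicon_bp" %in% names(primer_table))
        .data$expected_amplicon_bp[!is.na(.data$expected_amplicon_bp)][1] else NA_integer_,
      annealing_C = if ("annealing_C" %in% names(primer_table))
        .data$annealing_C[!is.na(.data$annealing_C)][1] else NA_real_,
      .groups = "drop"
    ) |>
    select("pair_id", "target_species", "fwd_seq", "rev_seq",
           "fwd_subs", "rev_subs", "expected_amplicon_bp", "annealing_C")
}
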