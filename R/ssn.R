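# Species-specific nucleotide (SSN) discovery: alignment columns whose allele
# is (near-)fixed in the target species and (near-)absent from every other
# species in the panel. This is the deterministic column logic of SCAR/ARMS
# marker development, not a population-genetic diagnosability statistic.

# per-column target summary: modal base among target rows and its frequency
target_allele_stats <- function(profiles, target) {
  profiles |>
    as_tibble() |>
    filter(.data$species == target) |>
    group_by(.data$column) |>
    summarise(
      target_allele = consensus_pick(.data$base, .data$count),
      target_fixation = max(.data$count[.data$base == consensus_pick(.data$base, .data$count)]) /
        .data$species_n[1],
      .groups = "drop"
    )
}

#' Find species-specific nucleotide (SSN) sites
#'
#' Scans per-column allele profiles for columns where the target species'
#' modal allele has within-species frequency at least `1 - tau_intra` and
#' frequency at most `tau_off` in every other species. With the strict
#' defaults (`tau_intra = tau_off = 0`) the allele must be fixed in the
#' target and absent off-target. Columns where the target allele is a gap are
#' never SSNs (a primer cannot anchor on absence); by default a column
#' containing any ambiguity code in any species is disqualified, since
#' clone-derived barcode sequences should be unambiguous.
#'
#' @param profiles Output of [column_profiles()], or an aligned panel tibble
#'   (profiles are computed on the fly).
#' @param target Target species name (must occur in the profiles).
#' @param tau_intra Tolerated within-target minor-allele fraction, in
#'   `[0, 0.5)`. Non-zero values accommodate intraspecific variation without
#'   discarding the species.
#' @param tau_off Tolerated off-target frequency of the allele, in `[0, 0.5)`.
#' @param exclude_ambiguous Disqualify columns containing IUPAC ambiguity
#'   codes (default `TRUE`).
#' @return Tibble sorted by `column`: `column`, `target_species`,
#'   `target_allele`, `target_fixation`, `max_offtarget_freq`, `gap_context`
#'   (any species has a gap in this column).
#' @export
find_ssn_sites <- function(profiles, target, tau_intra = 0, tau_off = 0,
                           exclude_ambiguous = TRUE) {
  if (!inherits(profiles, "scar_profiles") && "seq" %in% names(profiles)) {
    profiles <- column_profiles(profiles)
  }
  if (!(tau_intra >= 0 && tau_intra < 0.5 && tau_off >= 0 && tau_off < 0.5)) {
    abort("tau_intra and tau_off must lie in [0, 0.5)", class = "scar_precondition_error")
  }
  prof <- as_tibble(profiles)
  if (!target %in% prof$species) {
    abort(paste0("unknown species: ", target), class = "scar_lookup_error")
  }
  tgt <- target_allele_stats(profiles, target)

  col_flags <- prof |>
    group_by(.data$column) |>
    summarise(
      gap_context = any(.data$base == "-"),
      has_ambiguity = any(!.data$base %in% c(SCAR_BASES, "-")),
      .groups = "drop"
    )

  off <- prof |>
    filter(.data$species != target) |>
    left_join(select(tgt, "column", "target_allele"), by = "column") |>
    group_by(.data$column, .data$species) |>
    summarise(freq = sum(.data$count[.data$base == .data$target_allele[1]]) /
                .data$species_n[1], .groups = "drop_last") |>
    summarise(max_offtarget_freq = max(.data$freq), .groups = "drop")

  out <- tgt |>
    left_join(off, by = "column") |>
    left_join(col_flags, by = "column") |>
    mutate(max_offtarget_freq = dplyr::coalesce(.data$max_offtarget_freq, 0)) |>
    filter(
      .data$target_allele %in% SCAR_BASES,
      .data$target_fixation >= 1 - tau_intra,
      .data$max_offtarget_freq <= tau_off,
      !(exclude_ambiguous & .data$has_ambiguity)
    ) |>
    mutate(target_species = target) |>
    select("column", "target_species", "target_allele", "target_fixation",
           "max_offtarget_freq", "gap_context") |>
    arrange(.data$column)
  out
}

#' Find low-homology diagnostic windows
#'
#' Slides a window along the alignment and reports every placement where the
#' target species' consensus differs from the consensus of *every* other
#' species at `min_diff` or more columns. Columns where the target is
#' polymorphic beyond `tau_intra` are excluded from the diagnostic count, so
#' intraspecific variation does not fake divergence.
#'
#' @inheritParams find_ssn_sites
#' @param window_len Window width in columns (`window_len >= min_diff >= 1`).
#' @param min_diff Minimum diagnostic columns against each non-target species.
#' @return Tibble: `start`, `end` (1-based inclusive columns),
#'   `target_species`, `n_diagnostic_columns` (minimum across non-target
#'   species) and list-column `distinct_from`.
#' @export
find_low_homology_windows <- function(profiles, target, window_len = 20,
                                      min_diff = 2, tau_intra = 0) {
  if (!inherits(profiles, "scar_profiles") && "seq" %in% names(profiles)) {
    profiles <- column_profiles(profiles)
  }
  if (!(window_len >= min_diff && min_diff >= 1)) {
    abort("need window_len >= min_diff >= 1", class = "scar_precondition_error")
  }
  L <- attr(profiles, "alignment_length")
  if (window_len > L) {
    abort("window_len exceeds alignment length", class = "scar_precondition_error")
  }
  prof <- as_tibble(profiles)
  if (!target %in% prof$species) {
    abort(paste0("unknown species: ", target), class = "scar_lookup_error")
  }
  tgt <- target_allele_stats(profiles, target)
  defined <- rep(FALSE, L)
  defined[tgt$column] <- tgt$target_allele %in% SCAR_BASES &
    tgt$target_fixation >= 1 - tau_intra
  tallele <- rep(NA_character_, L)
  tallele[tgt$column] <- tgt$target_allele

  others <- setdiff(unique(prof$species), target)
  cons <- species_consensus(profiles)
  # per-species indicator of "diagnostic difference" at each column
  diff_mat <- vapply(others, function(sp) {
    sc <- rep(NA_character_, L)
    rows <- cons[cons$species == sp, ]
    sc[rows$column] <- rows$consensus
    defined & !is.na(sc) & sc != tallele
  }, logical(L))
  if (is.null(dim(diff_mat))) diff_mat <- matrix(diff_mat, ncol = length(others))

  cum <- rbind(0, apply(diff_mat, 2, cumsum))
  starts <- seq_len(L - window_len + 1)
  counts <- cum[starts + window_len, , drop = FALSE] - cum[starts, , drop = FALSE]
  min_counts <- apply(counts, 1, min)
  keep <- which(min_counts >= min_diff)
  tibble(
    start = starts[keep],
    end = starts[keep] + window_len - 1L,
    target_species = target,
    n_diagnostic_columns = as.integer(min_counts[keep]),
    distinct_from = rep(list(others), length(keep))
  )
}
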