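# In-silico PCR under a positional mismatch model with a 3'-clamp rule.
# A primer binds a template site iff total mismatches <= max_mm AND there is
# no mismatch within clamp_len positions of the primer's 3' end -- the model
# of why 3'-anchored SSN primers fail to extend on off-target templates.
# Deliberate design substitutions count as mismatches on the target template
# too; the defaults (max_mm = 3, clamp_len = 2) are declared calibration
# parameters of the model, chosen so that engineered primers still amplify
# their targets while any diagnostic 3' mismatch is decisive.

# mismatch profile of a pure-ACGT probe laid along template[s..e]; template
# ambiguity codes match any compatible base
mismatch_profile <- function(template_chars, s, probe_chars) {
  idx <- seq(s, s + length(probe_chars) - 1)
  !iupac_compatible(template_chars[idx], probe_chars)
}

scan_one_strand <- function(template, primer, strand, max_mm) {
  # returns tibble(start, end, n_mismatches, mm_from_3p list) for one strand
  probe <- if (strand == "+") primer else revcomp(primer)
  lt <- nchar(template); lp <- nchar(probe)
  if (lp > lt) {
    return(tibble(start = integer(), end = integer(),
                  n_mismatches = integer(), mm_from_3p = list()))
  }
  hits <- Biostrings::matchPattern(Biostrings::DNAString(probe),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mm, with.indels = FALSE,
                                   fixed = "subject")
  if (length(hits) == 0) {
    return(tibble(start = integer(), end = integer(),
                  n_mismatches = integer(), mm_from_3p = list()))
  }
  tch <- seq_chars(template)
  pch <- seq_chars(probe)
  starts <- Biostrings::start(hits)
  rows <- map(starts, function(s) {
    mm <- which(mismatch_profile(tch, s, pch))
    # position from the primer's 3' end: plus strand 3' is the rightmost
    # probe base; minus strand 3' is the leftmost (probe is the revcomp)
    from3 <- if (strand == "+") lp - mm + 1L else mm
    list(n = length(mm), from3 = sort(from3))
  })
  tibble(
    start = as.integer(starts),
    end = as.integer(starts + lp - 1L),
    n_mismatches = map_int(rows, "n"),
    mm_from_3p = map(rows, "from3")
  )
}

#' Find primer binding sites on templates
#'
#' Scans both strands of every template for sites where the primer anneals
#' under the positional mismatch model: at most `max_mm` mismatches in total
#' and (`clamp_ok`) none within `clamp_len` positions of the primer's 3'
#' end. Sites failing the clamp are still reported, flagged
#' `clamp_ok = FALSE`; only clamp-passing sites support amplification.
#' IUPAC ambiguity codes on the template match any compatible primer base.
#'
#' Deliberate design substitutions are expected to mismatch *every*
#' template, including the target, so annotated positions (a
#' `substituted_positions` list-column on `primers`, or the `clamp_exempt`
#' argument) are exempt from the clamp test while still counting toward the
#' `max_mm` budget. This keeps the diagnostic 3' terminus decisive without
#' disqualifying engineered primers on their own targets.
#'
#' @param templates Panel tibble (columns `id`, `seq`), or a single named
#'   character vector of sequences.
#' @param primers Tibble with columns `primer_name` (or `pair_id`) and a
#'   sequence column `seq_5to3` (optionally `substituted_positions`, a
#'   list-column of 1-based positions from the 3' end), or a single primer
#'   string.
#' @param max_mm Maximum total mismatches per site (default 3).
#' @param clamp_len 3'-clamp width in nt (default 2).
#' @param clamp_exempt Integer positions (from the 3' end) exempt from the
#'   clamp test for every primer lacking its own annotation.
#' @return Tibble: `template_id`, `primer_name`, `strand` (`+` forward,
#'   `-` reverse), `start`, `end` (1-based inclusive on the forward strand),
#'   `n_mismatches`, list-column `mismatch_positions_from_3prime`, `clamp_ok`.
#' @export
find_binding_sites <- function(templates, primers, max_mm = 3, clamp_len = 2,
                               clamp_exempt = integer()) {
  if (max_mm < 0 || clamp_len < 1) {
    abort("need max_mm >= 0 and clamp_len >= 1", class = "scar_precondition_error")
  }
  if (is.character(templates)) {
    templates <- tibble(id = names(templates) %||% paste0("t", seq_along(templates)),
                        seq = toupper(unname(templates)))
  }
  if (is.character(primers)) {
    primers <- tibble(primer_name = names(primers) %||% paste0("p", seq_along(primers)),
                      seq_5to3 = toupper(unname(primers)))
  }
  pname <- primers[[intersect(c("primer_name", "pair_id"), names(primers))[1]]]
  pseq <- toupper(gsub("\\s+", "", primers$seq_5to3))
  check_alphabet(pseq, pname, allow_gaps = FALSE, what = "primer")
  exempts <- if ("substituted_positions" %in% names(primers)) {
    map(primers$substituted_positions, ~ as.integer(.x %||% integer()))
  } else {
    rep(list(as.integer(clamp_exempt)), length(pseq))
  }

  out <- list()
  for (ti in seq_len(nrow(templates))) {
    for (pi in seq_along(pseq)) {
      for (st in c("+", "-")) {
        sites <- scan_one_strand(templates$seq[[ti]], pseq[[pi]], st, max_mm)
        if (nrow(sites) == 0) next
        sites$template_id <- templates$id[[ti]]
        sites$primer_name <- pname[[pi]]
        sites$strand <- st
        sites$exempt <- rep(list(exempts[[pi]]), nrow(sites))
        out[[length(out) + 1]] <- sites
      }
    }
  }
  if (!length(out)) {
    return(tibble(template_id = character(), primer_name = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_mismatches = integer(),
                  mismatch_positions_from_3prime = list(), clamp_ok = logical()))
  }
  bind_rows(out) |>
    mutate(clamp_ok = map2(.data$mm_from_3p, .data$exempt,
                           ~ !any(.x <= clamp_len & !.x %in% .y)) |> unlist()) |>
    select(-"exempt") |>
    rename(mismatch_positions_from_3prime = "mm_from_3p") |>
    select("template_id", "primer_name", "strand", "start", "end",
           "n_mismatches", "mismatch_positions_from_3prime", "clamp_ok") |>
    arrange(.data$template_id, .data$primer_name, .data$start)
}

#' Predict PCR amplicons for primer pairs
#'
#' Combines clamp-passing forward-primer sites on the plus strand with
#' reverse-primer sites on the minus strand into facing, productive
#' configurations. Product length is measured on the forward strand from the
#' forward site's first base through the reverse site's last base, inclusive
#' of both primer footprints (the gel convention). Substitution annotations
#' on the pairs (`fwd_substitutions`/`rev_substitutions` from
#' [pair_primers()], or `fwd_subs`/`rev_subs` integer list-columns) are
#' passed through as clamp exemptions (see [find_binding_sites()]).
#'
#' @param templates Panel tibble or named character vector.
#' @param pairs Pair tibble (`pair_id`, `fwd_seq`, `rev_seq`), e.g. from
#'   [pair_primers()] or [primer_pairs_from_table()].
#' @param max_product Maximum product length in bp (default 2000).
#' @inheritParams find_binding_sites
#' @return Tibble: `pair_id`, `template_id`, `start`, `end`, `length_bp`,
#'   `fwd_mismatches`, `rev_mismatches`.
#' @export
predict_amplicons <- function(templates, pairs, max_mm = 3, clamp_len = 2,
                              max_product = 2000) {
  if (is.character(templates)) {
    templates <- tibble(id = names(templates) %||% paste0("t", seq_along(templates)),
                        seq = toupper(unname(templates)))
  }
  pair_subs <- function(k, side) {
    ann <- pairs[[paste0(side, "_substitutions")]]
    if (!is.null(ann) && is.data.frame(ann[[k]])) {
      return(as.integer(ann[[k]]$pos_from_3prime))
    }
    vec <- pairs[[paste0(side, "_subs")]]
    if (!is.null(vec)) return(as.integer(vec[[k]] %||% integer()))
    integer(0)
  }
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    fsites <- find_binding_sites(
      templates,
      tibble(primer_name = "fwd", seq_5to3 = pairs$fwd_seq[[k]],
             substituted_positions = list(pair_subs(k, "fwd"))),
      max_mm = max_mm, clamp_len = clamp_len) |>
      filter(.data$strand == "+", .data$clamp_ok)
    rsites <- find_binding_sites(
      templates,
      tibble(primer_name = "rev", seq_5to3 = pairs$rev_seq[[k]],
             substituted_positions = list(pair_subs(k, "rev"))),
      max_mm = max_mm, clamp_len = clamp_len) |>
      filter(.data$strand == "-", .data$clamp_ok)
    if (nrow(fsites) == 0 || nrow(rsites) == 0) next
    for (tid in unique(fsites$template_id)) {
      f <- filter(fsites, .data$template_id == tid)
      r <- filter(rsites, .data$template_id == tid)
      if (nrow(r) == 0) next
      grid <- tidyr::expand_grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
      len <- r$end[grid$ri] - f$start[grid$fi] + 1L
      keep <- len > 0 & len <= max_product
      if (!any(keep)) next
      grid <- grid[keep, ]; len <- len[keep]
      out[[length(out) + 1]] <- tibble(
        pair_id = pairs$pair_id[[k]],
        template_id = tid,
        start = f$start[grid$fi],
        end = r$end[grid$ri],
        length_bp = as.integer(len),
        fwd_mismatches = f$n_mismatches[grid$fi],
        rev_mismatches = r$n_mismatches[grid$ri]
      )
    }
  }
  if (!length(out)) {
    return(tibble(pair_id = character(), template_id = character(),
                  start = integer(), end = integer(), length_bp = integer(),
                  fwd_mismatches = integer(), rev_mismatches = integer()))
  }
  bind_rows(out) |> arrange(.data$pair_id, .data$template_id, .data$start)
}

#' Panel-wide specificity matrix of primer pairs
#'
#' Runs every primer pair against every panel accession and summarises the
#' predicted bands per pair x species: the in-silico analogue of running all
#' specificity gels at once. A species is "positive" for a pair if at least
#' one of its accessions yields at least one amplicon. Per-accession detail
#' is retained in the `detail` attribute.
#'
#' @param panel Panel tibble.
#' @param pairs Pair tibble (`pair_id`, `target_species`, `fwd_seq`,
#'   `rev_seq`).
#' @inheritParams predict_amplicons
#' @return A `scar_specificity` tibble: `pair_id`, `target_species` (of the
#'   pair), `species` (template), `n_accessions`, `n_positive`, `positive`,
#'   and list-column `amplicon_bp` (sorted unique band sizes).
#' @export
specificity_matrix <- function(panel, pairs, max_mm = 3, clamp_len = 2,
                               max_product = 2000) {
  validate_panel(panel)
  amps <- predict_amplicons(panel, pairs, max_mm = max_mm,
                            clamp_len = clamp_len, max_product = max_product)
  detail <- left_join(amps, select(panel, "id", "species"),
                      by = c(template_id = "id"))
  grid <- tidyr::expand_grid(pair_id = pairs$pair_id,
                             species = unique(panel$species))
  counts <- panel |> count(.data$species, name = "n_accessions")
  pos <- detail |>
    group_by(.data$pair_id, .data$species) |>
    summarise(n_positive = dplyr::n_distinct(.data$template_id),
              amplicon_bp = list(sort(unique(.data$length_bp))), .groups = "drop")
  res <- grid |>
    left_join(select(pairs, "pair_id", "target_species"), by = "pair_id") |>
    left_join(counts, by = "species") |>
    left_join(pos, by = c("pair_id", "species")) |>
    mutate(
      n_positive = dplyr::coalesce(.data$n_positive, 0L),
      amplicon_bp = map(.data$amplicon_bp, ~ if (is.null(.x)) integer() else .x),
      positive = .data$n_positive > 0
    ) |>
    select("pair_id", "target_species", "species", "n_accessions",
           "n_positive", "positive", "amplicon_bp") |>
    arrange(.data$pair_id, .data$species)
  attr(res, "detail") <- detail
  class(res) <- c("scar_specificity", class(res))
  res
}

#' Is a specificity matrix strictly diagonal?
#'
#' `TRUE` iff every pair is positive for its own target species and negative
#' for every other species -- the pass criterion for a species-specific
#' SCAR panel.
#'
#' @param sm A `scar_specificity` tibble.
#' @return Logical scalar.
#' @export
specificity_is_diagonal <- function(sm) {
  all(sm$positive == (sm$species == sm$target_species))
}
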