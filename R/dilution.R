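# Sensitivity (limit-of-detection) arithmetic and adulterant screening.
# Template masses are carried internally as femtograms, which keeps the
# ten-fold decade series exact in double arithmetic.

MASS_UNIT_FG <- c(fg = 1, pg = 1e3, ng = 1e6, ug = 1e9)

#' Parse template masses to femtograms
#'
#' Accepts strings like `"10 ng"`, `"100fg"`, `"1 pg"` (units fg/pg/ng/ug)
#' or a numeric vector with an explicit `unit`.
#'
#' @param x Character vector of masses with units, or numeric.
#' @param unit Unit for numeric input (default `"ng"`).
#' @return Numeric vector of masses in femtograms.
#' @export
parse_mass <- function(x, unit = "ng") {
  if (is.numeric(x)) {
    if (!unit %in% names(MASS_UNIT_FG)) abort("unknown mass unit", class = "scar_format_error")
    return(x * MASS_UNIT_FG[[unit]])
  }
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*([a-z]+)\\s*$", tolower(x)))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("cannot parse mass: ", paste(x[bad], collapse = ", ")),
          class = "scar_format_error")
  }
  val <- as.numeric(vapply(m, `[[`, character(1), 2))
  un <- vapply(m, `[[`, character(1), 3)
  if (any(!un %in% names(MASS_UNIT_FG))) {
    abort(paste0("unknown mass unit in: ", paste(x[!un %in% names(MASS_UNIT_FG)], collapse = ", ")),
          class = "scar_format_error")
  }
  unname(val * MASS_UNIT_FG[un])
}

#' Express a template mass as percent of the reference reaction
#'
#' `percent = mass / reference * 100`, computed on exact femtogram values so
#' the standard ten-fold dilution decades print exactly (10 ng of a 10 ng
#' assay is 100%, 10 pg is 0.1%, 100 fg is 0.001%).
#'
#' @param mass Mass (string with unit, or numeric femtograms from
#'   [parse_mass()]).
#' @param reference_mass Reference assay input (default `"10 ng"`).
#' @return Numeric percent.
#' @examples
#' mass_to_percent(c("10 ng", "10 pg", "100 fg"))
#' @export
mass_to_percent <- function(mass, reference_mass = "10 ng") {
  mass_fg <- if (is.character(mass)) parse_mass(mass) else mass
  ref_fg <- if (is.character(reference_mass)) parse_mass(reference_mass) else reference_mass
  if (any(mass_fg <= 0) || ref_fg <= 0) {
    abort("masses must be positive", class = "scar_precondition_error")
  }
  mass_fg / ref_fg * 100
}

#' The standard ten-fold sensitivity series
#'
#' @return Character vector `"10 ng"` down to `"100 fg"` (100% to 0.001% of
#'   a 10 ng reaction).
#' @export
dilution_series_default <- function() {
  c("10 ng", "1 ng", "100 pg", "10 pg", "1 pg", "100 fg")
}

#' Simulate a serial-dilution sensitivity experiment
#'
#' Determines which points of a descending dilution series are detected by an
#' assay with the given limit of detection. The default deterministic model
#' flags a point iff its mass is at least `lod_mass`. The stochastic mode
#' draws template copies per replicate as Poisson(mass / mass_per_copy) and
#' detects iff at least `min_copies` are present, modelling sampling noise
#' near the detection limit; it is fully seeded.
#'
#' @param lod_mass Limit of detection (string with unit or femtograms).
#' @param series Descending masses (default [dilution_series_default()]).
#' @param replicates Replicates per point (default 3, the usual design).
#' @param mode `"threshold"` (deterministic) or `"stochastic"`.
#' @param seed Integer seed for the stochastic mode.
#' @param mass_per_copy Mass of one template copy (stochastic mode); default
#'   `"1 pg"`, a configurable stand-in for genome size, no more.
#' @param min_copies Copies needed for a detectable product (default 3).
#' @param reference_mass Reference for the percent scale.
#' @return A `scar_dilution` tibble: `mass`, `mass_fg`, `percent_of_assay`,
#'   `replicate`, `detected`.
#' @export
simulate_dilution_series <- function(lod_mass, series = dilution_series_default(),
                                     replicates = 3,
                                     mode = c("threshold", "stochastic"),
                                     seed = NULL, mass_per_copy = "1 pg",
                                     min_copies = 3, reference_mass = "10 ng") {
  mode <- match.arg(mode)
  if (replicates < 1) abort("replicates must be >= 1", class = "scar_precondition_error")
  mass_fg <- if (is.character(series)) parse_mass(series) else series
  if (is.unsorted(rev(mass_fg))) {
    abort("series must be descending", class = "scar_precondition_error")
  }
  lod_fg <- if (is.character(lod_mass)) parse_mass(lod_mass) else lod_mass
  res <- tidyr::expand_grid(i = seq_along(mass_fg), replicate = seq_len(replicates)) |>
    mutate(
      mass = (if (is.character(series)) series else as.character(series))[.data$i],
      mass_fg = mass_fg[.data$i],
      percent_of_assay = mass_to_percent(.data$mass_fg, reference_mass)
    ) |>
    select(-"i")
  if (mode == "threshold") {
    res$detected <- res$mass_fg >= lod_fg
  } else {
    copy_fg <- if (is.character(mass_per_copy)) parse_mass(mass_per_copy) else mass_per_copy
    draw <- function() rpois(nrow(res), res$mass_fg / copy_fg) >= min_copies
    res$detected <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  res <- select(res, "mass", "mass_fg", "percent_of_assay", "replicate", "detected")
  class(res) <- c("scar_dilution", class(res))
  res
}

#' Published detection limits of the Descurainiae Semen SCAR assay
#'
#' Empirical limits of detection of the six species-specific primer pairs,
#' on the percent scale of a 10 ng reaction: 10 pg (0.1%) for *D. sophia*
#' and *E. macilentum*, 1 pg (0.01%) for *L. virginicum*, 100 pg (1.0%) for
#' the remaining species.
#'
#' @return Tibble: `species`, `lod_mass`, `lod_percent`, `lod_fraction`.
#' @export
descurainia_lods <- function() {
  tibble(
    species = c("Descurainia sophia", "Lepidium densiflorum",
                "Lepidium virginicum", "Erysimum cheiranthoides",
                "Erysimum macilentum", "Draba nemorosa"),
    lod_mass = c("10 pg", "100 pg", "1 pg", "100 pg", "10 pg", "100 pg")
  ) |>
    mutate(lod_percent = mass_to_percent(.data$lod_mass),
           lod_fraction = .data$lod_percent / 100)
}

#' Screen mixed samples for adulterant species
#'
#' Applies per-species detection thresholds (LOD mass fractions) to sample
#' compositions: a species is flagged detected in a sample iff its mass
#' fraction is at least that assay's LOD fraction. A sample's verdict is
#' `"adulterated"` if any non-target species is detected and
#' `"pure at LOD"` otherwise -- never "absent", since a fraction below the
#' LOD is simply not detectable.
#'
#' @param samples Long tibble: `sample_id`, `species`, `fraction` (per-sample
#'   fractions must be non-negative and sum to 1).
#' @param lod_fractions Named numeric vector species -> LOD fraction (e.g.
#'   0.001 for an 0.1% LOD), or a tibble with `species` and `lod_fraction`
#'   columns such as [descurainia_lods()]. Every species present in
#'   `samples` needs a calibrated LOD.
#' @param target_species The authentic species of the product.
#' @return A `scar_screen` object; `tidy()` gives per-sample verdicts,
#'   `glance()` the batch summary including the adulteration percentage
#'   (rounded to the nearest whole percent, as batch surveys report it).
#' @export
screen_mixture <- function(samples, lod_fractions,
                           target_species = "Descurainia sophia") {
  samples <- as_tibble(samples)
  need <- c("sample_id", "species", "fraction")
  if (!all(need %in% names(samples))) {
    abort(paste0("samples needs columns: ", paste(need, collapse = ", ")),
          class = "scar_format_error")
  }
  if (is.data.frame(lod_fractions)) {
    lod_fractions <- setNames(lod_fractions$lod_fraction, lod_fractions$species)
  }
  if (any(samples$fraction < 0)) {
    abort("fractions must be non-negative", class = "scar_precondition_error")
  }
  sums <- samples |> group_by(.data$sample_id) |>
    summarise(s = sum(.data$fraction), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-8)) {
    abort(paste0("fractions must sum to 1 in: ",
                 paste(sums$sample_id[abs(sums$s - 1) > 1e-8], collapse = ", ")),
          class = "scar_precondition_error")
  }
  present <- unique(samples$species[samples$fraction > 0])
  missing_lod <- setdiff(present, names(lod_fractions))
  if (length(missing_lod)) {
    abort(paste0("no LOD calibration for: ", paste(missing_lod, collapse = ", ")),
          class = "scar_config_error")
  }
  detail <- samples |>
    mutate(
      lod_fraction = unname(lod_fractions[.data$species]),
      detected = .data$fraction >= .data$lod_fraction & .data$fraction > 0,
      is_target = .data$species == target_species
    )
  verdicts <- detail |>
    group_by(.data$sample_id) |>
    summarise(
      target_detected = any(.data$detected & .data$is_target),
      adulterant_detected = any(.data$detected & !.data$is_target),
      adulterants = list(sort(unique(.data$species[.data$detected & !.data$is_target]))),
      verdict = ifelse(any(.data$detected & !.data$is_target),
                       "adulterated", "pure at LOD"),
      .groups = "drop"
    )
  structure(
    list(detail = detail, verdicts = verdicts, target_species = target_species,
         lod_fractions = lod_fractions),
    class = "scar_screen"
  )
}

#' @export
print.scar_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("SCAR mixture screen: %d products, target %s\n",
              g$n_products, x$target_species))
  cat(sprintf("  adulterated: %d (%d%%), pure at LOD: %d\n",
              g$n_adulterated, g$adulteration_percent,
              g$n_products - g$n_adulterated))
  invisible(x)
}
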