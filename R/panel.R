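#' Read a labeled species panel from FASTA
#'
#' Reads a (plain or aligned) multi-FASTA of barcode sequences and attaches a
#' species label to every record. Labels come either from a sidecar table
#' (`labels`) or from a regular expression applied to the FASTA headers
#' (`species_pattern`), because FASTA/GenBank headers vary too much for a
#' fixed convention.
#'
#' @param path FASTA file (unaligned or aligned; gaps `-` allowed).
#' @param labels One of: a data frame with columns `id`, `species` and
#'   optionally `role`; a named character vector (names = record ids, values =
#'   species); or a path to a TSV with those columns.
#' @param species_pattern Alternative to `labels`: a regex with one capture
#'   group; the species is the capture applied to the full FASTA header.
#' @param outgroup Character vector of species names (or record ids) to flag
#'   with role `"outgroup"`; all other records get `"target_panel"`.
#'
#' @return A tibble with columns `id`, `species`, `seq` (uppercase), `role` --
#'   the panel format consumed by every other function in the package.
#'   Input order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "ACGAACGT"), fa)
#' read_panel(fa, labels = c(s1 = "Species one", s2 = "Species two"))
#' @export
read_panel <- function(path, labels = NULL, species_pattern = NULL,
                       outgroup = character()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "scar_format_error")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("cannot parse FASTA: ", conditionMessage(e)),
                                            class = "scar_format_error"))
  if (length(set) == 0) abort("empty FASTA file", class = "scar_format_error")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "scar_format_error")
  }
  seqs <- toupper(as.character(set))
  check_alphabet(seqs, ids)

  role <- rep("target_panel", length(ids))
  if (!is.null(species_pattern)) {
    m <- regmatches(headers, regexec(species_pattern, headers))
    species <- vapply(m, function(x) if (length(x) >= 2) x[[2]] else NA_character_,
                      character(1))
  } else if (!is.null(labels)) {
    lab <- normalize_labels(labels)
    idx <- match(ids, lab$id)
    species <- lab$species[idx]
    if ("role" %in% names(lab)) {
      role <- ifelse(is.na(idx) | is.na(lab$role[idx]), role, lab$role[idx])
    }
  } else {
    abort("supply either `labels` or `species_pattern`", class = "scar_label_error")
  }
  if (anyNA(species) || any(!nzchar(species))) {
    abort(paste0("unlabeled records: ",
                 paste(ids[is.na(species) | !nzchar(species)], collapse = ", ")),
          class = "scar_label_error")
  }
  if (length(outgroup)) role[species %in% outgroup | ids %in% outgroup] <- "outgroup"
  panel <- tibble(id = ids, species = species, seq = unname(seqs), role = role)
  validate_panel(panel)
  panel
}

normalize_labels <- function(labels) {
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- readr::read_tsv(labels, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(labels)) {
    labels <- tibble(id = names(labels), species = unname(labels))
  }
  labels <- as_tibble(labels)
  if (!all(c("id", "species") %in% names(labels))) {
    abort("label table needs `id` and `species` columns", class = "scar_label_error")
  }
  labels
}

#' Validate a species panel
#'
#' Checks the panel invariants: unique non-empty ids, non-empty species
#' labels, sequences in the IUPAC DNA alphabet (gaps allowed only when
#' `require_aligned` finds equal lengths), known roles.
#'
#' @param panel Panel tibble (see [read_panel()]).
#' @param require_aligned If `TRUE`, additionally require all sequences to
#'   have identical (gapped) length.
#' @return The panel, invisibly; aborts on violation.
#' @export
validate_panel <- function(panel, require_aligned = FALSE) {
  stopifnot(is.data.frame(panel))
  need <- c("id", "species", "seq")
  if (!all(need %in% names(panel))) {
    abort(paste0("panel must have columns: ", paste(need, collapse = ", ")),
          class = "scar_format_error")
  }
  if (nrow(panel) == 0) abort("empty panel", class = "scar_format_error")
  if (anyDuplicated(panel$id)) abort("duplicate record ids", class = "scar_format_error")
  if (any(is.na(panel$species) | !nzchar(panel$species))) {
    abort("every record needs a species label", class = "scar_label_error")
  }
  if (any(is.na(panel$seq) | !nzchar(panel$seq))) {
    abort("empty sequence in panel", class = "scar_format_error")
  }
  check_alphabet(panel$seq, panel$id)
  if ("role" %in% names(panel) &&
      !all(panel$role %in% c("target_panel", "outgroup"))) {
    abort("role must be 'target_panel' or 'outgroup'", class = "scar_format_error")
  }
  if (require_aligned && length(unique(nchar(panel$seq))) != 1) {
    abort("panel is not aligned (unequal sequence lengths)", class = "scar_format_error")
  }
  invisible(panel)
}

#' Write a panel to FASTA (plus optional label sidecar)
#'
#' @param panel Panel tibble.
#' @param path Output FASTA path.
#' @param labels_path Optional TSV path for the `id`/`species`/`role` sidecar.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, labels_path = NULL) {
  validate_panel(panel)
  set <- Biostrings::BStringSet(setNames(panel$seq, panel$id))
  Biostrings::writeXStringSet(set, path)
  if (!is.null(labels_path)) {
    readr::write_tsv(panel[, intersect(c("id", "species", "role"), names(panel))],
                     labels_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a SCAR primer table
#'
#' Reads a TSV transcription of a published primer table. Expected columns:
#' `target_species`, `primer_name`, `seq_5to3`, and optionally
#' `substituted_positions` (comma-separated 1-based positions counted from the
#' 3' end), `expected_amplicon_bp`, `annealing_C`. Whitespace inside printed
#' primer sequences (triplet spacing) is stripped.
#'
#' @param path TSV file with a header row.
#' @return Tibble with one row per primer; `substituted_positions` is a
#'   list-column of integer vectors (possibly empty).
#' @export
read_primer_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("target_species", "primer_name", "seq_5to3")
  if (!all(need %in% names(tbl))) {
    abort(paste0("primer table needs columns: ", paste(need, collapse = ", ")),
          class = "scar_format_error")
  }
  tbl$seq_5to3 <- toupper(gsub("\\s+", "", tbl$seq_5to3))
  bad <- !grepl("^[ACGT]+$", tbl$seq_5to3)
  if (any(bad)) {
    abort(paste0("non-ACGT primer sequence: ", paste(tbl$primer_name[bad], collapse = ", ")),
          class = "scar_format_error")
  }
  subs <- tbl$substituted_positions %||% rep(NA_character_, nrow(tbl))
  tbl$substituted_positions <- map(seq_len(nrow(tbl)), function(i) {
    x <- subs[[i]]
    if (is.na(x) || !nzchar(trimws(x))) return(integer())
    pos <- as.integer(strsplit(trimws(x), "\\s*,\\s*")[[1]])
    if (anyNA(pos) || any(pos < 1 | pos > nchar(tbl$seq_5to3[[i]]))) {
      abort(paste0("substituted position out of range for ", tbl$primer_name[[i]]),
            class = "scar_format_error")
    }
    pos
  })
  if ("expected_amplicon_bp" %in% names(tbl)) {
    tbl$expected_amplicon_bp <- as.integer(tbl$expected_amplicon_bp)
  }
  if ("annealing_C" %in% names(tbl)) tbl$annealing_C <- as.numeric(tbl$annealing_C)
  tbl$length <- nchar(tbl$seq_5to3)
  arrange(tbl, factor(.data$target_species, levels = unique(.data$target_species)))
}

#' Published SCAR primer set for the Descurainiae Semen assay
#'
#' The six species-specific primer pairs (12 primers) of the rDNA-ITS SCAR
#' assay that discriminates *Descurainia sophia* from its five seed
#' adulterants, transcribed from the published table including the annotated
#' deliberate substitutions near each 3' end, expected amplicon sizes and
#' empirical annealing temperatures.
#'
#' @return Tibble as from [read_primer_table()].
#' @export
descurainia_primers <- function() {
  read_primer_table(system.file("extdata", "descurainia_scar_primers.tsv",
                                package = "scarkit", mustWork = TRUE))
}

#' Universal rDNA-ITS amplification primers
#'
#' The classic universal primer pair flanking the full ITS1-5.8S-ITS2
#' interval of plant nuclear ribosomal DNA, used to normalize panels to a
#' common interval.
#'
#' @return Named character vector with elements `ITS1` and `ITS4` (5'->3').
#' @export
its_universal_primers <- function() {
  c(ITS1 = "TCCGTAGGTGAACCTGCGG", ITS4 = "TCCTCCGCTTATTGATATGC")
}

#' Extract the interval amplified by a universal primer pair
#'
#' Locates the forward primer site and the reverse primer site (given 5'->3',
#' binding the reverse strand) on each sequence and trims the record to the
#' full amplicon: from the first base of the forward site through the last
#' base of the reverse-complemented reverse site, inclusive. Used to
#' normalize heterogeneous panels (e.g. GenBank downloads) to a common
#' barcode interval.
#'
#' @param panel Panel tibble (unaligned sequences).
#' @param fwd,rev Primer sequences 5'->3' (default: the universal ITS pair).
#' @param max_mm Mismatches tolerated when locating each site (default 0).
#' @return The panel with `seq` replaced by the extracted interval and added
#'   integer columns `interval_start`, `interval_end` (1-based, inclusive, on
#'   the input sequence). Records missing either site abort with their ids
#'   listed (never silently dropped).
#' @export
extract_amplicon_interval <- function(panel,
                                      fwd = its_universal_primers()[["ITS1"]],
                                      rev = its_universal_primers()[["ITS4"]],
                                      max_mm = 0) {
  validate_panel(panel)
  fwd <- toupper(gsub("\\s+", "", fwd))
  rev <- toupper(gsub("\\s+", "", rev))
  rc_rev <- revcomp(rev)
  res <- map(seq_len(nrow(panel)), function(i) {
    s <- panel$seq[[i]]
    f <- Biostrings::matchPattern(Biostrings::DNAString(fwd), Biostrings::DNAString(s),
                                  max.mismatch = max_mm, fixed = "subject")
    if (length(f) == 0) return(NULL)
    fs <- Biostrings::start(f)[1]
    r <- Biostrings::matchPattern(Biostrings::DNAString(rc_rev), Biostrings::DNAString(s),
                                  max.mismatch = max_mm, fixed = "subject")
    r_end <- Biostrings::end(r)
    r_end <- r_end[r_end > fs]
    if (length(r_end) == 0) return(NULL)
    re <- max(r_end)
    list(start = fs, end = re, seq = substr(s, fs, re))
  })
  missing <- panel$id[vapply(res, is.null, logical(1))]
  if (length(missing)) {
    abort(paste0("primer site(s) not found in: ", paste(missing, collapse = ", ")),
          class = "scar_notfound_error")
  }
  panel$interval_start <- map_int(res, ~ as.integer(.x$start))
  panel$interval_end <- map_int(res, ~ as.integer(.x$end))
  panel$seq <- map_chr(res, "seq")
  panel
}
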