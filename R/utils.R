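# Shared sequence helpers. Sequences are plain uppercase character strings in
# IUPAC alphabet; '-' marks an alignment gap.

SCAR_BASES <- c("A", "C", "G", "T")

SCAR_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

SCAR_ALPHABET <- c(names(SCAR_IUPAC), "-")

# transversion partner used for deliberate destabilizing substitutions
SCAR_TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

degap <- function(x) gsub("-", "", x, fixed = TRUE)

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
check_alphabet <- function(seqs, ids = NULL, allow_gaps = TRUE, what = "sequence") {
  allowed <- if (allow_gaps) SCAR_ALPHABET else setdiff(SCAR_ALPHABET, "-")
  bad <- !grepl(sprintf("^[%s]+$", paste(gsub("-", "\\\\-", allowed), collapse = "")), seqs)
  if (any(bad)) {
    label <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else which(bad)
    abort(sprintf("invalid %s alphabet in: %s", what, paste(label, collapse = ", ")),
          class = "scar_format_error")
  }
  invisible(TRUE)
}

# TRUE where a pure-ACGT probe base is compatible with a (possibly ambiguous)
# template base; gaps are never compatible
iupac_compatible <- function(template_char, probe_char) {
  mapply(function(t, p) {
    if (t == "-" || p == "-") return(FALSE)
    p %in% SCAR_IUPAC[[t]]
  }, template_char, probe_char, USE.NAMES = FALSE)
}

alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
  rownames(m) <- alignment$id
  m
}

gc_fraction <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)
  vapply(ch, function(x) mean(x %in% c("G", "C")), numeric(1))
}
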