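# Shared fixtures, built once per test run and cached: panels are generated
# in code (no stored data) and reused across test files to keep the suite
# fast.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# study-condition panel: 6 species, 4/3/7/3/4/6 accessions, ~710 bp,
# no intraspecific noise or indels
paper_like <- function() {
  cached("paper_like", function() {
    g <- generate_panel(panel_spec(seed = 101))
    aln <- center_star_align(g$panel)
    list(g = g, panel = g$panel, aln = aln, prof = column_profiles(aln))
  })
}

# one selected substituted primer pair per species on the paper-like panel
paper_like_pairs <- function() {
  cached("paper_like_pairs", function() {
    fx <- paper_like()
    species <- unique(fx$panel$species[fx$panel$role == "target_panel"])
    purrr::map_dfr(species, function(sp) {
      ssn <- find_ssn_sites(fx$prof, sp)
      cand <- introduce_mismatches(enumerate_anchored_primers(fx$aln, ssn),
                                   n_subs = 1)
      head(pair_primers(cand[cand$strand == "forward", ],
                        cand[cand$strand == "reverse", ], fx$aln), 1)
    })
  })
}

# small fast panel for phylogenetics (shorter sequences, fewer accessions)
small_panel <- function() {
  cached("small_panel", function() {
    g <- generate_panel(panel_spec(
      n_species = 4, accessions_per_species = c(3, 2, 3, 2),
      ancestor_length = 300, interspecies_divergence = 0.06,
      n_ssn_per_species = 4, seed = 202
    ))
    list(g = g, panel = g$panel, aln = center_star_align(g$panel))
  })
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# tiny helper to make an aligned panel tibble from raw gapped strings
toy_alignment <- function(seqs, species, role = "target_panel") {
  tibble::tibble(id = paste0("r", seq_along(seqs)), species = species,
                 seq = seqs, role = role)
}
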