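# Seeded generator of ITS-like species panels with known ground truth:
# an ancestral sequence evolves along a random species tree (Kimura-style
# 2:1 transition bias so K2P estimation is well-posed), guaranteed-diagnostic
# substitutions are implanted per species with collision checking, and
# intraspecific noise plus short indels are added last. Every record carries
# a replayable edit log, which is what makes recovery tests exact.

TRANSITION_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_ALT <- list(A = c("C", "T"), C = c("A", "G"),
                         G = c("C", "T"), T = c("A", "G"))

#' Specify a synthetic ITS-like panel
#'
#' The defaults emulate the Descurainiae Semen study panel: six species with
#' 4/3/7/3/4/6 accessions, ~710 bp sequences bracketed by the universal ITS
#' primer sites, a few percent interspecific divergence, no intraspecific
#' variation, and a handful of implanted diagnostic substitutions per
#' species.
#'
#' @param n_species Number of target species.
#' @param accessions_per_species Integer vector of per-species accession
#'   counts (recycled if length 1).
#' @param species_names Optional species names (defaults `"Species 01"` ...).
#' @param ancestor_length Ancestor length in nt (>= 200 when universal sites
#'   are embedded).
#' @param interspecies_divergence Expected root-to-tip substitutions/site
#'   along the species tree.
#' @param n_ssn_per_species Guaranteed-diagnostic substitutions implanted
#'   per species.
#' @param intraspecific_rate Per-site substitution probability per accession.
#' @param indel_rate Expected indels per site per accession (kept small).
#' @param max_indel_len Maximum indel length in nt.
#' @param embed_universal_sites Embed the ITS1 site at the 5' end and the
#'   ITS4 site at the 3' end (protected from mutation)?
#' @param n_outgroup Number of divergent outgroup records (role
#'   `"outgroup"`, one pseudo-species each).
#' @param outgroup_divergence Root-to-outgroup substitutions/site.
#' @param ti_tv Transition:transversion ratio of the mutation process.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `scar_panel_spec` list.
#' @export
panel_spec <- function(n_species = 6,
                       accessions_per_species = c(4, 3, 7, 3, 4, 6),
                       species_names = NULL,
                       ancestor_length = 710,
                       interspecies_divergence = 0.04,
                       n_ssn_per_species = 8,
                       intraspecific_rate = 0,
                       indel_rate = 0,
                       max_indel_len = 3,
                       embed_universal_sites = TRUE,
                       n_outgroup = 2,
                       outgroup_divergence = 0.15,
                       ti_tv = 2,
                       seed = 1) {
  if (n_species < 2) abort("need >= 2 species", class = "scar_spec_error")
  accessions_per_species <- rep_len(accessions_per_species, n_species)
  rates <- c(interspecies_divergence, intraspecific_rate, indel_rate,
             outgroup_divergence)
  if (any(rates < 0 | rates >= 1)) {
    abort("rates must lie in [0, 1)", class = "scar_spec_error")
  }
  if (embed_universal_sites && ancestor_length < 200) {
    abort("ancestor_length must be >= 200 with embedded universal sites",
          class = "scar_spec_error")
  }
  if (is.null(species_names)) species_names <- sprintf("Species %02d", seq_len(n_species))
  structure(
    list(n_species = n_species, accessions_per_species = accessions_per_species,
         species_names = species_names, ancestor_length = ancestor_length,
         interspecies_divergence = interspecies_divergence,
         n_ssn_per_species = n_ssn_per_species,
         intraspecific_rate = intraspecific_rate, indel_rate = indel_rate,
         max_indel_len = max_indel_len,
         embed_universal_sites = embed_universal_sites,
         n_outgroup = n_outgroup, outgroup_divergence = outgroup_divergence,
         ti_tv = ti_tv, seed = seed),
    class = "scar_panel_spec"
  )
}

draw_new_base <- function(base, ti_tv) {
  if (runif(1) < ti_tv / (ti_tv + 2)) TRANSITION_MAP[[base]]
  else sample(TRANSVERSION_ALT[[base]], 1)
}

apply_subs <- function(chars, subs) {
  if (nrow(subs) == 0) return(chars)
  if (any(subs$pos < 1 | subs$pos > length(chars))) {
    abort("edit position out of range", class = "scar_replay_error")
  }
  chars[subs$pos] <- subs$to
  chars
}

apply_indels <- function(chars, indels) {
  if (nrow(indels) == 0) return(chars)
  ord <- order(-indels$pos)
  for (i in ord) {
    pos <- indels$pos[[i]]; len <- indels$len[[i]]
    if (indels$type[[i]] == "del") {
      if (pos < 1 || pos + len - 1 > length(chars)) {
        abort("deletion out of range", class = "scar_replay_error")
      }
      chars <- chars[-seq(pos, pos + len - 1)]
    } else {
      if (pos < 0 || pos > length(chars)) {
        abort("insertion out of range", class = "scar_replay_error")
      }
      ins <- seq_chars(indels$bases[[i]])
      chars <- append(chars, ins, after = pos)
    }
  }
  chars
}

materialize_record <- function(ancestor_chars, species_edits, rec) {
  chars <- apply_subs(ancestor_chars, species_edits)
  chars <- apply_subs(chars, rec$subs)
  chars <- apply_indels(chars, rec$indels)
  chars_to_seq(chars)
}

#' Generate a synthetic panel with ground truth
#'
#' See [panel_spec()] for the generative model. Diagnostic substitutions are
#' implanted after interspecific evolution, only at columns still invariant
#' across all species (collision checking), so they are fixed in-species and
#' absent off-species by construction. Intraspecific noise and indels avoid
#' the implanted columns and the embedded universal primer sites, which
#' keeps the recorded truth exactly valid.
#'
#' @param spec A `scar_panel_spec`.
#' @return List with `panel` (tibble as from [read_panel()]) and `truth`
#'   (`scar_panel_truth`: ancestor, species tree, per-species edits, implanted
#'   SSN table in ancestor coordinates, and a per-record replayable edit log).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "scar_panel_spec"))
  L <- spec$ancestor_length
  withr::with_seed(spec$seed, {
    ancestor <- sample(SCAR_BASES, L, replace = TRUE)
    protected <- integer(0)
    if (spec$embed_universal_sites) {
      its <- its_universal_primers()
      fwd <- seq_chars(its[["ITS1"]])
      rev_rc <- seq_chars(revcomp(its[["ITS4"]]))
      ancestor[seq_along(fwd)] <- fwd
      ancestor[seq(L - length(rev_rc) + 1, L)] <- rev_rc
      protected <- c(seq_along(fwd), seq(L - length(rev_rc) + 1, L))
    }

    # species tree + interspecific evolution along its edges
    tree <- ape::rcoal(spec$n_species, tip.label = spec$species_names)
    depth <- max(ape::node.depth.edgelength(tree))
    if (depth > 0) tree$edge.length <- tree$edge.length * spec$interspecies_divergence / depth
    nnode <- max(tree$edge)
    seqs <- vector("list", nnode)
    root <- spec$n_species + 1
    seqs[[root]] <- ancestor
    eligible <- setdiff(seq_len(L), protected)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      chars <- seqs[[parent]]
      hits <- eligible[runif(length(eligible)) < ord$edge.length[e]]
      for (pos in hits) chars[pos] <- draw_new_base(chars[pos], spec$ti_tv)
      seqs[[child]] <- chars
    }
    species_seqs <- seqs[seq_len(spec$n_species)]
    names(species_seqs) <- tree$tip.label
    species_seqs <- species_seqs[spec$species_names]

    # implant guaranteed-diagnostic substitutions with collision checking
    ssn_rows <- list()
    taken <- integer(0)
    if (spec$n_ssn_per_species > 0) {
      for (sp in spec$species_names) {
        base_mat <- do.call(rbind, species_seqs)
        invariant <- which(apply(base_mat, 2, function(col) length(unique(col)) == 1))
        pool <- setdiff(invariant, c(protected, taken))
        if (length(pool) < spec$n_ssn_per_species) {
          abort("too many diagnostic sites requested for this length/divergence",
                class = "scar_spec_error")
        }
        pos <- sort(sample(pool, spec$n_ssn_per_species))
        for (p in pos) {
          old <- species_seqs[[sp]][[p]]
          new <- SCAR_TRANSVERSION[[old]]
          species_seqs[[sp]][[p]] <- new
          ssn_rows[[length(ssn_rows) + 1]] <- tibble(
            species = sp, position = p, allele = new, background = old
          )
        }
        taken <- c(taken, pos)
      }
    }
    ssn_sites <- if (length(ssn_rows)) bind_rows(ssn_rows) else
      tibble(species = character(), position = integer(),
             allele = character(), background = character())
    frozen <- c(protected, ssn_sites$position)  # never touched again

    # species-level edit logs relative to the ancestor
    species_edits <- map(species_seqs, function(chars) {
      diff <- which(chars != ancestor)
      tibble(pos = diff, to = chars[diff])
    })

    # accessions: intraspecific noise + indels, all logged
    ids <- character(0); sp_col <- character(0); role <- character(0)
    records <- list()
    for (si in seq_len(spec$n_species)) {
      sp <- spec$species_names[[si]]
      noise_pool <- setdiff(seq_len(L), frozen)
      for (ai in seq_len(spec$accessions_per_species[[si]])) {
        id <- sprintf("s%02da%02d", si, ai)
        hits <- noise_pool[runif(length(noise_pool)) < spec$intraspecific_rate]
        subs <- tibble(
          pos = as.integer(hits),
          to = vapply(hits, function(p) draw_new_base(species_seqs[[sp]][[p]], spec$ti_tv),
                      character(1))
        )
        n_ind <- rpois(1, spec$indel_rate * L)
        indels <- tibble(type = character(), pos = integer(),
                         len = integer(), bases = character())
        if (n_ind > 0) {
          for (k in seq_len(n_ind)) {
            len <- sample.int(spec$max_indel_len, 1)
            type <- sample(c("del", "ins"), 1)
            ok <- if (type == "del") {
              setdiff(seq_len(L - len + 1),
                      unlist(lapply(frozen, function(f) seq(f - len + 1, f))))
            } else noise_pool
            if (!length(ok)) next
            pos <- sample(ok, 1)
            bases <- if (type == "ins") chars_to_seq(sample(SCAR_BASES, len, replace = TRUE)) else ""
            indels <- bind_rows(indels, tibble(type = type, pos = as.integer(pos),
                                               len = as.integer(len), bases = bases))
          }
        }
        records[[id]] <- list(species = sp, subs = subs, indels = indels)
        ids <- c(ids, id); sp_col <- c(sp_col, sp); role <- c(role, "target_panel")
      }
    }
    # outgroups share a divergent stem (two congeneric outgroup species),
    # so they root the tree as a clade
    if (spec$n_outgroup > 0) {
      og_stem <- ancestor
      hits <- eligible[runif(length(eligible)) < 0.6 * spec$outgroup_divergence]
      for (pos in hits) og_stem[pos] <- draw_new_base(og_stem[pos], spec$ti_tv)
      for (oi in seq_len(spec$n_outgroup)) {
        id <- sprintf("og%02d", oi)
        sp <- sprintf("Outgroup %02d", oi)
        chars <- og_stem
        hits <- eligible[runif(length(eligible)) < 0.4 * spec$outgroup_divergence]
        for (pos in hits) chars[pos] <- draw_new_base(chars[pos], spec$ti_tv)
        diff <- which(chars != ancestor)
        species_edits[[sp]] <- tibble(pos = diff, to = chars[diff])
        records[[id]] <- list(species = sp,
                              subs = tibble(pos = integer(), to = character()),
                              indels = tibble(type = character(), pos = integer(),
                                              len = integer(), bases = character()))
        ids <- c(ids, id); sp_col <- c(sp_col, sp); role <- c(role, "outgroup")
      }
    }

    truth <- structure(
      list(spec = spec, ancestor = chars_to_seq(ancestor), tree = tree,
           species_edits = species_edits, ssn_sites = ssn_sites,
           records = records, ids = ids),
      class = "scar_panel_truth"
    )
    panel <- replay_truth(truth)
    list(panel = panel, truth = truth)
  })
}

#' Replay a truth log into a panel
#'
#' Deterministically rebuilds every record from the stored ancestor plus the
#' species-level and record-level edit logs -- the determinism audit for the
#' generator. No random numbers are drawn.
#'
#' @param truth A `scar_panel_truth`.
#' @return Panel tibble identical to the generated one.
#' @export
replay_truth <- function(truth) {
  if (!inherits(truth, "scar_panel_truth") ||
      !all(c("ancestor", "species_edits", "records", "ids") %in% names(truth))) {
    abort("corrupted truth log", class = "scar_replay_error")
  }
  anc <- seq_chars(truth$ancestor)
  seqs <- vapply(truth$ids, function(id) {
    rec <- truth$records[[id]]
    if (is.null(rec)) abort("corrupted truth log: missing record", class = "scar_replay_error")
    edits <- truth$species_edits[[rec$species]] %||% tibble(pos = integer(), to = character())
    materialize_record(anc, edits, rec)
  }, character(1))
  tibble(
    id = truth$ids,
    species = vapply(truth$ids, function(id) truth$records[[id]]$species, character(1)),
    seq = unname(seqs),
    role = vapply(truth$ids, function(id) {
      if (grepl("^og", id)) "outgroup" else "target_panel"
    }, character(1))
  )
}

#' All truly diagnostic columns of a generated panel
#'
#' Recounts, directly on the truth's species-level sequences, every ancestor
#' position where one species' base differs from the base of *every* other
#' species -- the complete set of species-specific nucleotides, which
#' includes both the implanted sites and any private substitutions that
#' happened to fix on a terminal branch during interspecific evolution.
#' This is the correct reference set for precision/recall of SSN discovery
#' on panels without intraspecific noise.
#'
#' @param truth A `scar_panel_truth`.
#' @return Tibble: `species`, `position` (ancestor coordinates), `allele`,
#'   `implanted` (was this site deliberately implanted?).
#' @export
diagnostic_columns_from_truth <- function(truth) {
  stopifnot(inherits(truth, "scar_panel_truth"))
  anc <- seq_chars(truth$ancestor)
  sp_seq <- map(truth$species_edits[truth$spec$species_names], ~ apply_subs(anc, .x))
  mat <- do.call(rbind, sp_seq)
  rownames(mat) <- names(sp_seq)
  rows <- list()
  for (sp in rownames(mat)) {
    others <- mat[setdiff(rownames(mat), sp), , drop = FALSE]
    diag_pos <- which(vapply(seq_len(ncol(mat)), function(j) {
      all(others[, j] != mat[sp, j])
    }, logical(1)))
    if (length(diag_pos)) {
      rows[[sp]] <- tibble(species = sp, position = diag_pos,
                           allele = mat[sp, diag_pos])
    }
  }
  res <- if (length(rows)) bind_rows(rows) else
    tibble(species = character(), position = integer(), allele = character())
  res |>
    left_join(mutate(truth$ssn_sites, implanted = TRUE),
              by = c("species", "position", "allele")) |>
    mutate(implanted = !is.na(.data$implanted)) |>
    select("species", "position", "allele", "implanted") |>
    arrange(.data$species, .data$position)
}

#' @export
print.scar_panel_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic panel spec: %d species (%s accessions) x ~%d bp, divergence %.3f, %d SSN/species, seed %d\n",
    x$n_species, paste(x$accessions_per_species, collapse = "/"),
    x$ancestor_length, x$interspecies_divergence, x$n_ssn_per_species, x$seed))
  invisible(x)
}
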