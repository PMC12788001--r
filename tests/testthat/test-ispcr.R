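# in-silico PCR: binding-site model, amplicon prediction, specificity matrix

test_that("an embedded exact match is found once per strand orientation", {
  primer <- "ACGGATCCTAGGCATGCAAT"
  template <- paste0(random_seq(40), primer, random_seq(40))
  sites <- find_binding_sites(c(tpl = template), c(p = primer))
  plus <- sites[sites$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 41)
  expect_equal(plus$end, 60)
  expect_equal(plus$n_mismatches, 0)
  expect_true(plus$clamp_ok)
})

test_that("a 3'-terminal mismatch disqualifies the site (clamp rule)", {
  primer <- "ACGGATCCTAGGCATGCAAT"
  bad <- paste0(substr(primer, 1, 19), "C")  # terminal T -> C on the template
  template <- paste0(random_seq(30), bad, random_seq(30))
  sites <- find_binding_sites(c(tpl = template), c(p = primer))
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$n_mismatches, 1)
  expect_false(any(plus$clamp_ok))
  # but an annotated engineered position is exempt from the clamp
  sites2 <- find_binding_sites(
    c(tpl = template),
    tibble::tibble(primer_name = "p", seq_5to3 = primer,
                   substituted_positions = list(1L)))
  expect_true(all(sites2$clamp_ok[sites2$strand == "+"]))
})

test_that("template ambiguity codes match compatible primer bases", {
  primer <- "ACGTACGTACGTACGTAC"
  template <- paste0("TTTT", sub("G", "R", primer), "TTTT")  # R matches A/G
  sites <- find_binding_sites(c(t = template), c(p = primer))
  # the intended site (offset 5) carries zero mismatches: R is compatible
  expect_true(any(sites$strand == "+" & sites$start == 5 &
                    sites$n_mismatches == 0))
})

test_that("binding sites equal an exhaustive brute-force scan on random instances", {
  withr::local_seed(41)
  for (i in 1:100) {
    template <- random_seq(120)
    primer <- random_seq(18)
    # half the time embed a mutated copy so hits actually occur
    if (i %% 2 == 0) {
      at <- sample(1:(120 - 18), 1)
      copy <- strsplit(primer, "")[[1]]
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        idx <- sample(18, nmut)
        copy[idx] <- vapply(copy[idx], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      }
      substr(template, at, at + 17) <- paste(copy, collapse = "")
    }
    got <- find_binding_sites(c(t = template), c(p = primer))
    exp <- brute_force_sites(template, primer)
    got <- got[order(got$strand, got$start), ]
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      expect_equal(got$strand, exp$strand)
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$n_mismatches, exp$n_mismatches)
      expect_equal(got$clamp_ok, exp$clamp_ok)
    }
  }
})

test_that("a primer longer than the template yields no sites", {
  expect_equal(nrow(find_binding_sites(c(t = "ACGT"), c(p = "ACGTACGTACGT"))), 0)
})

test_that("constructed templates give products of fwd + N + rev length", {
  fwd <- "GATTACAGATTACAGGCAT"
  rev <- "CCATGGTAGCTAGCTTGCA"
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  pairs <- tibble::tibble(pair_id = "p1", fwd_seq = fwd, rev_seq = rev)
  for (N in c(0, 10, 100)) {
    tpl <- paste0(fwd, if (N > 0) random_seq(N) else "", rc(rev))
    amp <- predict_amplicons(c(t = tpl), pairs)
    expect_equal(amp$length_bp, nchar(fwd) + N + nchar(rev))
  }
  # missing reverse site -> no product
  amp <- predict_amplicons(c(t = paste0(fwd, random_seq(50))), pairs)
  expect_equal(nrow(amp), 0)
})

test_that("amplicons equal the brute-force oracle on random instances", {
  withr::local_seed(43)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (i in 1:30) {
    fwd <- random_seq(18); rev <- random_seq(18)
    template <- paste0(random_seq(30), fwd, random_seq(sample(10:120, 1)),
                       rc(rev), random_seq(30))
    got <- predict_amplicons(c(t = template),
                             tibble::tibble(pair_id = "p", fwd_seq = fwd,
                                            rev_seq = rev))
    expect_equal(sort(got$length_bp), brute_force_amplicons(template, fwd, rev))
  }
})

test_that("universal (non-diagnostic) primers light up the whole panel row", {
  fx <- paper_like()
  its <- its_universal_primers()
  pairs <- tibble::tibble(pair_id = "universal", target_species = "Species 01",
                          fwd_seq = unname(its["ITS1"]), rev_seq = unname(its["ITS4"]))
  sm <- specificity_matrix(fx$panel, pairs)
  expect_true(all(sm$positive))
  expect_false(specificity_is_diagonal(sm))
})

test_that("designed pairs give a strictly diagonal specificity matrix", {
  fx <- paper_like()
  pairs <- paper_like_pairs()
  sm <- specificity_matrix(fx$panel, pairs)
  expect_true(specificity_is_diagonal(sm))
  g <- glance(sm)
  expect_equal(g$n_offtarget_positive, 0)
  expect_equal(g$n_positive_cells, 6)
  # every accession of each target species amplifies, with a single band size
  on_target <- sm[sm$species == sm$target_species, ]
  expect_true(all(on_target$n_positive == on_target$n_accessions))
  expect_true(all(vapply(on_target$amplicon_bp, length, 1L) == 1))
})
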