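# 3'-anchored primer design, deliberate mismatches, Tm, pairing

test_that("Wallace Tm follows 2(A+T) + 4(G+C)", {
  expect_equal(tm_estimate("AAAA", method = "wallace"), 8)
  expect_equal(tm_estimate("GGGG", method = "wallace"), 16)
  expect_equal(tm_estimate("ACGT", method = "wallace"), 12)
  expect_error(tm_estimate("ACGN"), class = "scar_precondition_error")
})

test_that("nearest-neighbor Tm reproduces an independent implementation", {
  # expected values computed once with a published nearest-neighbor
  # implementation (unified parameter set, 25 nM strands, 50 mM Na+)
  frozen <- c(
    CATGCAACAGAACGGCCATCTTCT = 58.0162,
    GTCATCAAGAGCTTTCGGACAAACA = 56.0926,
    GTGGGCCGGTTTCCTAACAGACT = 58.5725,
    CAGCACAGCATTCGCGTCC = 56.8041,
    ATGCGTACGTTAGCCAGTTAGCAA = 57.0304,
    GGCCGGAATTCCAGATTACAGGCA = 59.0509,
    TTTTAAAACGCGCGCGATATATAT = 52.4153,
    ACGT = -52.3605
  )
  got <- tm_estimate(names(frozen), method = "nn")
  expect_equal(got, unname(frozen), tolerance = 0.001)
})

test_that("anchored candidates put the diagnostic allele at the 3' terminus", {
  fx <- paper_like()
  ssn <- find_ssn_sites(fx$prof, "Species 02")
  cand <- enumerate_anchored_primers(fx$aln, ssn)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$length >= 18 & cand$length <= 28))
  by_col <- setNames(ssn$target_allele, ssn$column)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fwd <- cand[cand$strand == "forward", ]
  expect_true(all(substr(fwd$seq_5to3, fwd$length, fwd$length) ==
                    by_col[as.character(fwd$aln_3prime_column)]))
  rev <- cand[cand$strand == "reverse", ]
  expect_true(all(substr(rev$seq_5to3, rev$length, rev$length) ==
                    comp[by_col[as.character(rev$aln_3prime_column)]]))
})

test_that("candidate coordinates are exact and edge sites yield empty sets", {
  aln <- toy_alignment(rep(random_seq(200), 2), c("t", "t"))
  site <- tibble::tibble(column = 100L, target_species = "t",
                         target_allele = substr(aln$seq[1], 100, 100),
                         target_fixation = 1, max_offtarget_freq = 0,
                         gap_context = FALSE)
  cand <- enumerate_anchored_primers(aln, site, length_range = c(20, 20),
                                     strand = "forward")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$seq_5to3, substr(aln$seq[1], 81, 100))

  site$column <- 5L
  expect_equal(nrow(enumerate_anchored_primers(aln, site, strand = "forward")), 0)
})

test_that("introduce_mismatches changes exactly n_subs bases inside the window", {
  withr::local_seed(12)
  for (i in 1:20) {
    primer <- tibble::tibble(
      target_species = "t", strand = "forward", aln_3prime_column = 50L,
      seq_5to3 = random_seq(22), length = 22L, tm_C = 60, gc_frac = 0.5,
      substitutions = list(tibble::tibble(pos_from_3prime = integer(),
                                          original = character(), new = character()))
    )
    n <- sample(1:3, 1)
    out <- introduce_mismatches(primer, n_subs = n, window = c(2, 4))
    expect_equal(nchar(out$seq_5to3), 22)
    diff <- which(strsplit(primer$seq_5to3, "")[[1]] != strsplit(out$seq_5to3, "")[[1]])
    expect_equal(length(diff), n)                 # Hamming distance = n_subs
    expect_true(all((22 - diff + 1) %in% 2:4))    # all inside the window
    expect_equal(sort(out$substitutions[[1]]$pos_from_3prime), sort(22 - diff + 1))
  }
})

test_that("mismatch injection edge cases behave", {
  primer <- tibble::tibble(
    target_species = "t", strand = "forward", aln_3prime_column = 50L,
    seq_5to3 = "ACGTACGTACGTACGTACGT", length = 20L, tm_C = 60, gc_frac = 0.5,
    substitutions = list(tibble::tibble(pos_from_3prime = integer(),
                                        original = character(), new = character()))
  )
  expect_identical(introduce_mismatches(primer, n_subs = 0), primer)
  expect_error(introduce_mismatches(primer, n_subs = 3, window = c(2, 3)),
               class = "scar_infeasible_error")
  # terminal-position substitution is possible when the window includes 1
  out <- introduce_mismatches(primer, n_subs = 1, window = c(1, 1))
  expect_equal(out$substitutions[[1]]$pos_from_3prime, 1L)
})

test_that("amplicon size is inclusive of both primer footprints", {
  s <- random_seq(600)
  aln <- toy_alignment(rep(s, 2), c("t", "t"))
  mk <- function(strand, col3, len) {
    cols <- if (strand == "forward") (col3 - len + 1):col3 else col3:(col3 + len - 1)
    seq5 <- substr(s, min(cols), max(cols))
    if (strand == "reverse") {
      seq5 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq5)))
    }
    tibble::tibble(target_species = "t", strand = strand,
                   aln_3prime_column = as.integer(col3), seq_5to3 = seq5,
                   length = as.integer(len), tm_C = tm_estimate(seq5),
                   gc_frac = 0.5,
                   substitutions = list(tibble::tibble(pos_from_3prime = integer(),
                                                       original = character(),
                                                       new = character())))
  }
  # fwd occupies 100..123 (5' at 100), rev 5' end at 515
  pairs <- pair_primers(mk("forward", 123, 24), mk("reverse", 491, 25), aln,
                        tm_tolerance = 30)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$expected_amplicon_bp, 416L)
  expect_equal(pairs$recommended_annealing_C,
               min(pairs$fwd_tm_C, pairs$rev_tm_C) - 3)

  # everything above the cap is dropped
  expect_equal(nrow(pair_primers(mk("forward", 123, 24), mk("reverse", 491, 25),
                                 aln, max_amplicon = 400, tm_tolerance = 30)), 0)
})

test_that("designed pairs respect the size cap and carry diagnostic 3' ends", {
  fx <- paper_like()
  pairs <- paper_like_pairs()
  expect_equal(nrow(pairs), 6)
  expect_true(all(pairs$expected_amplicon_bp > 0 &
                    pairs$expected_amplicon_bp < 500))
  ssn_all <- purrr::map_dfr(unique(pairs$target_species),
                            ~ find_ssn_sites(fx$prof, .x))
  key <- paste(ssn_all$target_species, ssn_all$column)
  expect_true(all(paste(pairs$target_species, pairs$fwd_3prime_column) %in% key))
  expect_true(all(paste(pairs$target_species, pairs$rev_3prime_column) %in% key))
})

test_that("published primers carry 3'-proximal substitution annotations", {
  tbl <- descurainia_primers()
  subs <- tbl$substituted_positions
  names(subs) <- tbl$primer_name
  # every annotated primer has a substitution within 4 nt of the 3' end
  annotated <- subs[vapply(subs, length, 1L) > 0]
  expect_equal(length(annotated), 11)  # all but the D. sophia forward primer
  expect_true(all(vapply(annotated, function(p) any(p <= 4), logical(1))))
  # the D. nemorosa forward primer substitutes the 3' terminus itself
  expect_true(1L %in% subs[["DN F2"]])
  expect_true(all(unlist(subs) >= 1))
  expect_true(all(unlist(Map(function(p, l) p <= l, subs, tbl$length))))
})
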