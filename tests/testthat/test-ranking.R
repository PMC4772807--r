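# Minimal hand-built annotation for scoring tests.
make_ann <- function(id = "p1", protein = strrep("A", 100),
                     signal_present = FALSE, signal_end = NA,
                     n_sites = 0, peptides = list(), features = list()) {
  sig <- structure(list(present = signal_present,
                        cleave_after = if (signal_present) signal_end else NA,
                        score = 1, source = "heuristic", warning = FALSE),
                   class = "signal_prediction")
  sites <- lapply(seq_len(n_sites), function(i) {
    list(start = 90 + i, end = 90 + i, kind = "monobasic", motif = "R",
         confidence = "extended")
  })
  structure(list(protein_id = id, protein = protein, mode = "denovo",
                 signal = sig, sites = sites, peptides = peptides,
                 features = features,
                 family_hits = data.frame(peptide = integer(0),
                                          family = character(0)),
                 score = NULL),
            class = "precursor_annotation")
}

make_pep <- function(seq, coords, amide = FALSE, copy_id = 1L) {
  structure(list(seq = seq, precursor_coords = coords, cterm_amide = amide,
                 nterm_pyroglu = FALSE, cys_positions = integer(0),
                 max_disulfides = 0L, sulfation_candidates = integer(0),
                 copy_id = copy_id), class = "mature_peptide")
}

test_that("score is an exact weighted sum with sensible zeros", {
  bare <- make_ann()
  b <- score_precursor(bare)
  expect_equal(b$total, 0)
  expect_equal(b$total, sum(b$features * b$weights))

  # adding one amidation Gly with weight 1 raises the total by exactly 1
  one <- make_ann(peptides = list(make_pep("QWYT", c(30, 34), amide = TRUE)))
  expect_equal(score_precursor(one)$total - score_precursor(
    make_ann(peptides = list(make_pep("QWYT", c(30, 34)))))$total, 1)

  expect_error(score_weights(per_site = -1), "non-negative")
  expect_error(score_weights(length_penalty = 0.5), "<= 0")
})

test_that("scores equal an independent dot-product oracle on fuzzed annotations", {
  withr::local_seed(66)
  w <- score_weights()
  for (rep in 1:100) {
    n_pep <- sample(0:6, 1)
    sig <- sample(c(TRUE, FALSE), 1)
    plen <- sample(80:700, 1)
    pos <- 30
    peptides <- list()
    for (i in seq_len(n_pep)) {
      len <- sample(4:10, 1)
      peptides[[i]] <- make_pep(random_protein(len), c(pos, pos + len - 1),
                                amide = sample(c(TRUE, FALSE), 1),
                                copy_id = sample(1:2, 1))
      pos <- pos + len + 2
    }
    ann <- make_ann(protein = random_protein(plen), signal_present = sig,
                    signal_end = 22, n_sites = sample(0:14, 1),
                    peptides = peptides)
    got <- score_precursor(ann, w)$total
    # independent arithmetic
    pep_res <- sum(vapply(peptides, function(p)
      diff(p$precursor_coords) + 1, 0))
    post <- plen - if (sig) 22 else 0
    copies <- vapply(peptides, `[[`, 0L, "copy_id")
    maxcopy <- if (length(copies)) max(table(copies)) else 0
    expected <- 3 * sig + 1 * min(length(ann$sites), 10) +
      1 * sum(vapply(peptides, `[[`, NA, "cterm_amide")) +
      2 * (if (post > 0) pep_res / post else 0) +
      2 * max(0, maxcopy - 1) + 0 - 0.01 * max(0, plen - 500)
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("ranking is deterministic with documented tie-breaks", {
  a5 <- make_ann("a", n_sites = 5)
  a3 <- make_ann("b", n_sites = 3)
  r <- rank_candidates(list(a3, a5), top_n = 10)
  expect_equal(vapply(r, `[[`, "", "protein_id"), c("a", "b"))

  # equal totals: more amidation glycines first, then id order
  t1 <- make_ann("z", n_sites = 1,
                 peptides = list(make_pep("AAAA", c(30, 34), amide = TRUE)))
  t2 <- make_ann("y", n_sites = 2)
  t3 <- make_ann("x", n_sites = 2)
  r2 <- rank_candidates(list(t2, t1, t3), top_n = 10)
  expect_equal(vapply(r2, `[[`, "", "protein_id"), c("z", "x", "y"))

  # permutation restriction and top_n truncation
  withr::local_seed(12)
  many <- lapply(1:600, function(i) make_ann(sprintf("p%03d", i),
                                             n_sites = sample(0:9, 1)))
  r3 <- rank_candidates(many)
  expect_length(r3, 500)
  expect_true(all(vapply(r3, `[[`, "", "protein_id") %in%
                    sprintf("p%03d", 1:600)))
  scores <- vapply(r3, `[[`, 0, "score")
  expect_true(all(diff(scores) <= 0))
})

test_that("adding evidence never lowers the score (monotonicity)", {
  base <- make_ann("m", n_sites = 2,
                   peptides = list(make_pep("QWYT", c(30, 34))))
  more_sites <- make_ann("m", n_sites = 3,
                         peptides = list(make_pep("QWYT", c(30, 34))))
  expect_gte(score_precursor(more_sites)$total, score_precursor(base)$total)
  with_sig <- make_ann("m", signal_present = TRUE, signal_end = 20,
                       n_sites = 2,
                       peptides = list(make_pep("QWYT", c(30, 34))))
  expect_gte(score_precursor(with_sig)$total, score_precursor(base)$total)
})

test_that("planted precursors separate from decoys under default weights", {
  for (s in c(21, 22, 23)) {
    st <- synthetic_transcriptome(seed = s)
    res <- discover(st$contigs, require_signal = FALSE, require_sites = 0)
    scores <- vapply(res$annotations, `[[`, 0, "score")
    # planted = the ORF of a planted precursor protein; decoys = ORFs on
    # the generated decoy contigs (incidental ORFs on precursor contigs
    # are neither and are gated out of the pipeline by the signal filter)
    planted <- vapply(res$annotations, function(a) {
      ctg <- sub("_orf[0-9]+$", "", a$protein_id)
      ctg %in% names(st$truths) &&
        identical(a$protein, st$truths[[ctg]]$protein)
    }, NA)
    decoy <- grepl("^decoy_", vapply(res$annotations, `[[`, "", "protein_id"))
    expect_true(min(scores[planted]) > max(scores[decoy]))
  }
})
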