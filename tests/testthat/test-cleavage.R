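test_that("dibasic sites flanking a peptide are found", {
  prot <- paste0(strrep("A", 20), "NGFFYG", "KR", "SQ", strrep("A", 10))
  sites <- find_cleavage_sites(prot, signal_end = 20)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$motif, "KR")
  expect_equal(sites[[1]]$kind, "dibasic")
  expect_equal(sites[[1]]$confidence, "canonical")
  expect_equal(sites[[1]]$start, 27)   # immediately after the G

  expect_length(find_cleavage_sites(strrep("A", 40), 10), 0)
})

test_that("runs of basics are split deterministically, not nested", {
  prot <- paste0(strrep("A", 10), "KRR", strrep("A", 5), "KKKK",
                 strrep("A", 5))
  sites <- find_cleavage_sites(prot, 0)
  expect_equal(vapply(sites, `[[`, "", "kind"), c("tribasic", "tribasic"))
  # KKKK: leftmost three as tribasic; the lone remainder is not monobasic-
  # eligible in de novo mode
  expect_equal(vapply(sites, `[[`, "", "motif"), c("KRR", "KKK"))

  no3 <- find_cleavage_sites(prot, 0, cleavage_rules(allow_tribasic = FALSE))
  expect_equal(vapply(no3, `[[`, "", "motif"), c("KR", "KK", "KK"))
})

test_that("monobasic R requires an even-spaced upstream basic", {
  # R at 15 with K at 13 (2 upstream)
  prot <- paste0(strrep("A", 12), "K", "A", "R", strrep("A", 10))
  expect_length(find_cleavage_sites(prot, 0), 0)  # off in de novo mode
  on <- find_cleavage_sites(prot, 0, cleavage_rules(monobasic_mode = TRUE))
  kinds <- vapply(on, `[[`, "", "kind")
  expect_true("monobasic" %in% kinds)
  mono <- on[[which(kinds == "monobasic")]]
  expect_equal(c(mono$start, mono$end), c(15, 15))
  # a lone K is never monobasic, and an R with no upstream basic is not
  expect_length(find_cleavage_sites(paste0(strrep("A", 10), "R",
                                           strrep("A", 10)), 0,
                                    cleavage_rules(monobasic_mode = TRUE)), 0)
})

test_that("site calls agree with a regex oracle on random proteins", {
  withr::local_seed(101)
  for (rep in 1:200) {
    prot <- random_protein(200)
    sig <- sample(0:30, 1)
    mono <- rep %% 2 == 0
    got <- find_cleavage_sites(prot, sig,
                               cleavage_rules(monobasic_mode = mono))
    expect_equal(site_keys_of(got), oracle_sites(prot, sig, mono))
  }
})

test_that("segmentation tiles the protein exactly", {
  prot <- paste0(strrep("A", 10), "KR", strrep("B", 0), strrep("A", 10))
  # one central KR -> exactly 2 segments
  sites <- find_cleavage_sites(prot, 0)
  segs <- segment_between_sites(prot, 0, sites)
  expect_length(segs, 2)
  # zero sites -> one segment, everything after the signal
  segs1 <- segment_between_sites(strrep("A", 30), 5, list())
  expect_length(segs1, 1)
  expect_equal(segs1[[1]]$seq, strrep("A", 25))

  withr::local_seed(202)
  for (rep in 1:200) {
    prot <- random_protein(sample(30:150, 1))
    sig <- sample(0:15, 1)
    mono <- rep %% 2 == 0
    sites <- find_cleavage_sites(prot, sig,
                                 cleavage_rules(monobasic_mode = mono))
    segs <- segment_between_sites(prot, sig, sites)
    # reconstruction: signal + interleaved sites/segments = protein
    pieces <- c(
      list(list(start = 1, end = sig,
                seq = substr(prot, 1, sig))),
      lapply(sites, function(s) list(start = s$start, end = s$end,
                                     seq = s$motif)),
      segs)
    pieces <- pieces[order(vapply(pieces, `[[`, 0, "start"))]
    pieces <- Filter(function(p) nchar(p$seq) > 0, pieces)
    expect_equal(paste0(vapply(pieces, `[[`, "", "seq"), collapse = ""),
                 prot)
    # monobasic off never increases segment count
    if (mono) {
      sites0 <- find_cleavage_sites(prot, sig, cleavage_rules())
      segs0 <- segment_between_sites(prot, sig, sites0)
      expect_lte(length(segs0), length(segs))
    }
  }
})

test_that("overlapping sites are rejected", {
  expect_error(segment_between_sites(strrep("A", 20), 0, list(
    list(start = 5, end = 6, kind = "dibasic", motif = "KR"),
    list(start = 6, end = 7, kind = "dibasic", motif = "RR"))),
    "Overlapping")
})
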