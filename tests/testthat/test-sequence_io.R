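test_that("read_fasta parses, normalises and validates records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "atgc", ">c2 some description", "ACGU", "NNAC"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[["c1"]]$seq, "ATGC")          # uppercased
  expect_equal(recs[["c2"]]$seq, "ACGTNNAC")      # U -> T, lines joined
  expect_equal(names(recs), c("c1", "c2"))        # order preserved

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_length(read_fasta(empty), 0)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta(dup), "Duplicate")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACRT"), bad)  # R = rejected ambiguity code
  expect_error(read_fasta(bad), "line 4")
})

test_that("write_fasta / read_fasta round-trips (id, seq)", {
  withr::local_seed(11)
  recs <- lapply(1:5, function(i) {
    list(id = paste0("ctg", i), seq = random_dna(sample(40:220, 1)))
  })
  names(recs) <- vapply(recs, `[[`, "", "id")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 50)
  back <- read_fasta(f)
  expect_equal(lapply(unclass(back), `[`, c("id", "seq")),
               lapply(recs, `[`, c("id", "seq")))
})

test_that("six_frame_orfs finds forward and reverse ORFs with correct coords", {
  one <- six_frame_orfs(list(id = "c", seq = "ATGGCTAAATAA"), min_len = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$protein, "MAK")
  expect_equal(one$strand, "+")
  expect_equal(one$frame, 0)
  expect_false(one$partial5)
  expect_equal(c(one$nt_start, one$nt_end), c(0, 9))

  rev <- six_frame_orfs(list(id = "c", seq = "TTATTTAGCCAT"), min_len = 1)
  expect_equal(rev$protein, "MAK")
  expect_equal(rev$strand, "-")

  expect_equal(nrow(six_frame_orfs(list(id = "n", seq = strrep("N", 90)),
                                   min_len = 1)), 0)
})

test_that("six_frame_orfs agrees with a brute-force enumerator on random contigs", {
  withr::local_seed(42)
  for (rep in 1:25) {
    ctg <- list(id = "r", seq = random_dna(300))
    got <- six_frame_orfs(ctg, min_len = 20)
    expect_equal(orf_keys(got), oracle_orfs(ctg$seq, 20))
  }
})

test_that("ORF calls are strand-symmetric and re-translate to the protein", {
  withr::local_seed(7)
  gc <- Biostrings::GENETIC_CODE
  for (rep in 1:10) {
    seq <- random_dna(240)
    a <- six_frame_orfs(list(id = "x", seq = seq), min_len = 10)
    b <- six_frame_orfs(list(id = "x", seq = revcomp_chr(seq)), min_len = 10)
    # revcomp swaps strand and mirrors coordinates
    L <- nchar(seq)
    mirrored <- sprintf("%s|%d|%d|%s",
                        ifelse(b$strand == "+", "-", "+"),
                        L - b$nt_end, L - b$nt_start, b$protein)
    expect_setequal(sprintf("%s|%d|%d|%s", a$strand, a$nt_start, a$nt_end,
                            a$protein), mirrored)
    for (i in seq_len(nrow(a))) {
      expect_false(grepl("\\*", a$protein[i]))
      span <- substr(seq, a$nt_start[i] + 1, a$nt_end[i])
      if (a$strand[i] == "-") span <- revcomp_chr(span)
      cods <- substring(span, seq(1, nchar(span), 3), seq(3, nchar(span), 3))
      expect_equal(paste0(unname(gc[cods]), collapse = ""), a$protein[i])
    }
  }
})

test_that("partial ORFs at contig edges are reported when allowed", {
  # no start codon, runs into both edges in frame 0
  ctg <- list(id = "p", seq = strrep("GCT", 30))
  expect_equal(nrow(six_frame_orfs(ctg, min_len = 5)), 0)
  got <- six_frame_orfs(ctg, min_len = 5, allow_partial = TRUE)
  fwd0 <- got[got$strand == "+" & got$frame == 0, ]
  expect_equal(fwd0$protein, strrep("A", 30))
  expect_true(fwd0$partial5)
  expect_true(fwd0$partial3)
})

test_that("GFF3 export projects residue coordinates phase-correctly", {
  # peptide at residues 25-33 of a frame-0 + strand ORF starting at nt 0
  orf <- list(contig_id = "c", strand = "+", nt_start = 0, nt_end = 300)
  expect_equal(residues_to_nt(orf, 25, 33), c(73, 99))
  # minus strand: per-residue brute-force mapping
  orfm <- list(contig_id = "c", strand = "-", nt_start = 12, nt_end = 312)
  for (r in c(1, 2, 50, 100)) {
    nt <- residues_to_nt(orfm, r, r)
    # residue r corresponds to codon r counted from nt_end downwards
    expect_equal(nt, c(312 - 3 * r + 1, 312 - 3 * (r - 1)))
  }

  expect_equal(write_gff3(list(), list()), "##gff-version 3")

  st <- synthetic_transcriptome(seed = 5)
  res <- discover(st$contigs)
  g <- write_gff3(res$annotations, res$orfs)
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(g, f)
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), length(g) - 1)   # round-trips through a parser
  expect_true(all(BiocGenerics::start(gr) >= 1))

  bad_ann <- res$annotations[[1]]
  bad_ann$protein_id <- "nonexistent"
  expect_error(write_gff3(list(bad_ann), res$orfs), "unknown ORF")
})
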