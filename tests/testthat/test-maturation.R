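test_that("amidation and pyroglutamate rules reproduce known mature forms", {
  p <- mature("QWYTG")
  expect_equal(p$seq, "QWYT")
  expect_true(p$cterm_amide)
  expect_true(p$nterm_pyroglu)
  expect_equal(peptide_notation(p), "pQWYT-NH2")

  p <- mature("NGFFYG")
  expect_equal(peptide_notation(p), "NGFFY-NH2")

  p <- mature("CLVQDCPEGG")
  expect_equal(p$seq, "CLVQDCPEG")        # single-G donation
  expect_true(p$cterm_amide)
  expect_equal(p$cys_positions, c(1, 6))
  expect_equal(p$max_disulfides, 1)

  p <- mature("AFGDFSF")
  expect_equal(p$seq, "AFGDFSF")
  expect_false(p$cterm_amide)

  # pyroGlu can be disabled; sulfation is opt-in
  expect_false(mature("QWYTG", pyroglu = FALSE)$nterm_pyroglu)
  expect_equal(mature("DYGHGLFWG", flag_sulfation = TRUE)$sulfation_candidates,
               2)
  expect_length(mature("DYGHGLFWG")$sulfation_candidates, 0)
})

test_that("maturation is idempotent once amidation is applied", {
  withr::local_seed(31)
  for (rep in 1:100) {
    s <- random_protein(sample(3:20, 1))
    m1 <- mature(s)
    if (!endsWith(m1$seq, "G")) {
      m2 <- mature(m1$seq)
      expect_equal(m2$seq, m1$seq)
      expect_false(m2$cterm_amide && !m1$cterm_amide && endsWith(s, "G") == FALSE)
    }
    expect_equal(m1$max_disulfides, length(m1$cys_positions) %/% 2)
  }
})

test_that("identical peptides within a precursor share a copy_id", {
  st <- synthetic_transcriptome(seed = 4)
  trh <- st$truths[["synthetic_multi_copy"]]
  copies <- vapply(trh$peptides, `[[`, 0L, "copy_id")
  seqs <- vapply(trh$peptides, `[[`, "", "seq")
  expect_equal(length(unique(copies[seqs == "QWYT"])), 1)
  expect_equal(sum(tabulate(copies)), length(trh$peptides))
  expect_equal(max(tabulate(copies)), 11)
})

test_that("neurophysin detection requires exactly 14 downstream cysteines", {
  tail14 <- paste0(strrep("AC", 14), strrep("S", 10))
  prot <- paste0(strrep("A", 40), "KR", tail14)
  f <- detect_neurophysin(prot, 43)
  expect_equal(f$kind, "neurophysin_domain")
  expect_equal(f$coords, c(43, nchar(prot)))

  tail13 <- paste0(strrep("AC", 13), strrep("S", 12))
  expect_null(detect_neurophysin(paste0(strrep("A", 40), "KR", tail13), 43))

  withr::local_seed(17)
  for (rep in 1:50) {
    prot <- random_protein(100)
    hint <- sample(30:60, 1)
    region <- substr(prot, hint, 100)
    expected <- sum(strsplit(region, "")[[1]] == "C") == 14
    expect_equal(!is.null(detect_neurophysin(prot, hint)), expected)
  }
})

test_that("acidic spacers are detected by count and fraction", {
  expect_true(detect_acidic_spacer("ADSEPEGDALSEMADLESQFNSA"))
  expect_false(detect_acidic_spacer("AAAA"))
  # six acidic residues but diluted below the 20% fraction
  expect_false(detect_acidic_spacer(paste0(strrep("A", 40), "DEDEDE")))
  withr::local_seed(23)
  for (rep in 1:100) {
    s <- random_protein(sample(5:40, 1))
    n_acid <- sum(strsplit(s, "")[[1]] %in% c("D", "E"))
    expect_equal(detect_acidic_spacer(s),
                 n_acid >= 6 && n_acid / nchar(s) >= 0.2)
  }
})

test_that("insulin/relaxin layout is recognised from cysteine spacing", {
  arch <- default_architectures()$insulin_layout
  prot <- paste0("M", strrep("L", 20), "SQA", paste(arch, collapse = "KR"))
  sites <- find_cleavage_sites(prot, 24)
  feats <- detect_insulin_architecture(prot, 24, sites)
  expect_equal(vapply(feats, `[[`, "", "kind"),
               c("insulin_B_chain", "C_peptide", "insulin_A_chain"))
  # coordinates cover the three segments in order
  expect_equal(feats[[1]]$coords[1], 25)

  expect_length(detect_insulin_architecture(strrep("A", 80), 0, list()), 0)

  # motifs cross-checked against the family-motif patterns
  b <- substr(prot, feats[[1]]$coords[1], feats[[1]]$coords[2])
  a <- substr(prot, feats[[3]]$coords[1], feats[[3]]$coords[2])
  expect_true("insulin-B-chain" %in% classify(b))
  expect_true("insulin-A-chain" %in% classify(a))
})
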