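# Reverse-translation table: amino acid -> synonymous codons.
.codons_for <- function() {
  tab <- .codon_table()
  split(names(tab), unname(tab))
}

.sample_codons <- function(protein) {
  tab <- .codons_for()
  aa <- strsplit(protein, "")[[1]]
  vapply(aa, function(a) {
    cs <- tab[[a]]
    cs[[sample.int(length(cs), 1)]]
  }, "")
}

.random_seq <- function(n, alphabet) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Build a signal peptide that the heuristic recognises with a unique
# cleavage boundary: M + n-region {K,N,Q} + h-region {L,I,F} (no small
# residues, so no earlier candidate passes the -3/-1 rule) + c-region SQA.
.synth_signal <- function(cleave_after = NULL) {
  p0 <- if (is.null(cleave_after)) sample(18:26, 1) else cleave_after
  hlen <- 9
  nlen <- p0 - 4 - hlen  # after M, before h-region
  stopifnot(nlen >= 1)
  paste0("M", .random_seq(nlen, c("K", "N", "Q")),
         .random_seq(hlen, c("L", "I", "F")), "SQA")
}

#' Default planted precursor architectures
#'
#' Each architecture is a list of peptide segments laid out as
#' `signal | seg1 | KR | seg2 | KR | ... | segN`, mirroring classic
#' precursor layouts: a multi-copy precursor (one long peptide plus 11
#' copies of a Gly-extended tetrapeptide, TRH-like), an amidated
#' disulfide-bearing peptide followed by a 14-cysteine neurophysin-like
#' tail (vasopressin/oxytocin-like), an insulin/relaxin B|C|A layout, and
#' an acidic-spacer precursor. Every structural detector therefore has a
#' positive control.
#'
#' @return Named list of character vectors (the ordered segments).
#' @export
default_architectures <- function() {
  neurophysin_tail <- paste0("AVLDTE",
                             paste(rep(c("CMSG", "ACDP"), 7), collapse = ""),
                             "NYLPSP")
  # 14 cysteines, no K/R, does not end in G
  stopifnot(lengths(regmatches(neurophysin_tail,
                               gregexpr("C", neurophysin_tail))) == 14)
  list(
    multi_copy = c("QYPGGAPIGLDG", rep("QWYTG", 11)),
    neurophysin = c("CLVQDCPEGG", neurophysin_tail),
    insulin_layout = c("QTDACNAFDLLSTMQSCSNELAP",       # B-chain C.{11}C
                       "SGGDMTEAELSQYVDSLQTEWS",        # C-peptide
                       "GIVDECCENACSVDEALSYC"),         # A-chain CC.{3}C.{8}C
    acidic_spacer = c("ADSEPEGDALSEMADLESQFNSA",        # 6+ D/E in 23
                      "NSCVAFTPCMMSDHAECWNACAPGFSCDPC") # 6-Cys payload
  )
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Plants precursor genes (signal peptide passing the built-in heuristic by
#' construction, peptide segments alternating with KR dibasic sites)
#' reverse-translated with uniform synonymous codon choice into contigs
#' with flanking UTRs and an in-frame upstream stop, plus length-matched
#' decoy ORFs with no signal/cleavage architecture. Decoys and incidental
#' ORFs are rejection-sampled so that no unplanted ORF presents
#' precursor-like architecture and no decoy contains a planted peptide
#' sequence. Regeneration with the same seed is byte-identical.
#'
#' @param seed Integer seed (all randomness derives from it; the caller's
#'   RNG state is preserved).
#' @param architectures Named list of peptide-segment layouts (default
#'   [default_architectures()]).
#' @param n_decoys Number of decoy contigs (default 6).
#' @param decoy_len Decoy protein length (residues).
#' @return A list of class `synthetic_truth`: `contigs` (a `contig_set`),
#'   `truths` (map contig_id -> `precursor_annotation`), `params`.
#' @export
synthetic_transcriptome <- function(seed, architectures = default_architectures(),
                                    n_decoys = 6, decoy_len = 90) {
  stopifnot(!missing(seed))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  planted_peps <- unique(unlist(architectures))
  if (any(grepl("[KR]", planted_peps))) {
    stop("Planted peptide contains K/R: incompatible with a dibasic-only ",
         "cleavage grammar")
  }
  contigs <- list()
  truths <- list()

  embed_protein <- function(protein) {
    codons <- .sample_codons(protein)
    utr5 <- paste0(.random_seq(3 * sample(8:15, 1), c("A", "C", "G", "T")), "TAA")
    utr3 <- .random_seq(3 * sample(8:15, 1), c("A", "C", "G", "T"))
    paste0(utr5, paste0(codons, collapse = ""), "TAA", utr3)
  }

  clean_contig <- function(nt, planted_protein = NULL) {
    # no unplanted ORF may look precursor-like
    orfs <- six_frame_orfs(list(id = "tmp", seq = nt), min_len = 60)
    for (i in seq_len(nrow(orfs))) {
      p <- orfs$protein[[i]]
      if (!is.null(planted_protein) && p == planted_protein) next
      sig <- predict_signal(p)
      if (isTRUE(sig$present)) return(FALSE)
      if (!is.null(planted_protein)) next
      for (pep in planted_peps) {
        if (grepl(pep, p, fixed = TRUE)) return(FALSE)
      }
    }
    TRUE
  }

  for (arch_name in names(architectures)) {
    segs <- architectures[[arch_name]]
    ok <- FALSE
    for (attempt in 1:100) {
      signal <- .synth_signal()
      protein <- paste0(signal, paste(segs, collapse = "KR"))
      sig_pred <- predict_signal(protein)
      if (!isTRUE(sig_pred$present) ||
          sig_pred$cleave_after != nchar(signal)) next
      nt <- embed_protein(protein)
      if (!clean_contig(nt, protein)) next
      ok <- TRUE
      break
    }
    if (!ok) stop("Failed to generate architecture '", arch_name, "'")
    id <- paste0("synthetic_", arch_name)
    contigs[[id]] <- list(id = id, seq = nt)
    truths[[id]] <- annotate_protein(protein, protein_id = id,
                                     mode = "denovo", signal = sig_pred)
  }

  for (d in seq_len(n_decoys)) {
    ok <- FALSE
    for (attempt in 1:200) {
      body <- .random_seq(decoy_len - 1,
                          c("A", "D", "E", "G", "H", "N", "P", "Q", "S", "T",
                            "V", "Y", "L", "I", "F", "M", "W", "C"))
      protein <- paste0("M", body)
      if (isTRUE(predict_signal(protein)$present)) next
      if (any(vapply(planted_peps, function(p) grepl(p, protein, fixed = TRUE),
                     NA))) next
      nt <- embed_protein(protein)
      if (!clean_contig(nt)) next
      ok <- TRUE
      break
    }
    if (!ok) stop("Failed to generate decoy ", d)
    id <- paste0("decoy_", d)
    contigs[[id]] <- list(id = id, seq = nt)
  }

  structure(list(
    contigs = structure(contigs, class = "contig_set", type = "nucleotide"),
    truths = truths,
    params = list(seed = seed, n_decoys = n_decoys,
                  architectures = names(architectures),
                  cleavage_dialect = "KR")), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic transcriptome: %d contig(s) (%d planted precursor(s), %d decoy(s)), seed %d\n",
              length(x$contigs), length(x$truths),
              length(x$contigs) - length(x$truths), x$params$seed))
  invisible(x)
}

.peptide_keys <- function(ann, contig_id) {
  vapply(ann$peptides, function(p) {
    paste(contig_id, p$precursor_coords[1], p$precursor_coords[2], p$seq,
          sep = ":")
  }, "")
}

.site_keys <- function(ann, contig_id) {
  vapply(ann$sites, function(s) {
    paste(contig_id, s$start, s$end, s$motif, sep = ":")
  }, "")
}

#' Evaluate pipeline output against synthetic ground truth
#'
#' Peptide-level scoring uses exact coordinate-and-sequence match within
#' the precursor protein; site-level likewise on (coords, motif).
#'
#' @param result A `discovery_result` (from [discover()]) or list of
#'   `precursor_annotation`s whose ids are `<contig_id>_orf<k>`.
#' @param truth A `synthetic_truth`.
#' @return Data.frame with rows `peptide` and `site`: `tp`, `n_pred`,
#'   `n_truth`, `precision`, `recall`, `f1`, `empty_prediction` flag
#'   (precision reported as 0 when there are no predictions).
#' @export
evaluate_predictions <- function(result, truth) {
  anns <- if (inherits(result, "discovery_result")) result$annotations else result
  pred_pep <- character(0); pred_site <- character(0)
  for (a in anns) {
    contig <- sub("_orf[0-9]+$", "", a$protein_id)
    pred_pep <- c(pred_pep, .peptide_keys(a, contig))
    pred_site <- c(pred_site, .site_keys(a, contig))
  }
  true_pep <- character(0); true_site <- character(0)
  for (id in names(truth$truths)) {
    true_pep <- c(true_pep, .peptide_keys(truth$truths[[id]], id))
    true_site <- c(true_site, .site_keys(truth$truths[[id]], id))
  }
  row <- function(pred, tru) {
    tp <- sum(pred %in% tru)
    prec <- if (length(pred)) tp / length(pred) else 0
    rec <- if (length(tru)) tp / length(tru) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(tp = tp, n_pred = length(pred), n_truth = length(tru),
               precision = prec, recall = rec, f1 = f1,
               empty_prediction = length(pred) == 0)
  }
  out <- rbind(row(pred_pep, true_pep), row(pred_site, true_site))
  rownames(out) <- c("peptide", "site")
  out
}
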