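#' Annotate a precursor protein
#'
#' Runs the full single-protein annotation: signal-peptide prediction (or an
#' imported prediction), cleavage-site detection, segment excision, peptide
#' maturation, structural feature detection (neurophysin domain, acidic
#' spacers, insulin/relaxin layout), family classification and composite
#' scoring.
#'
#' Two operating modes reflect two uses of the toolkit. De novo mode
#' (default) maximises precision in blind scans: monobasic cleavage sites
#' are off and matured peptides shorter than 3 residues are discarded.
#' Curation mode maximises agreement with expert annotation of known
#' precursors: monobasic sites on, no length floor.
#'
#' @param protein Amino-acid string.
#' @param protein_id Identifier for the annotation.
#' @param mode `"denovo"` or `"curation"`.
#' @param signal A precomputed `signal_prediction` (e.g. imported); when
#'   `NULL` the built-in heuristic is used.
#' @param signal_pars,rules,registry,weights Stage parameters.
#' @param min_peptide_len Length floor for matured peptides in de novo mode.
#' @return A list of class `precursor_annotation`: `protein_id`, `protein`,
#'   `mode`, `signal`, `sites`, `peptides`, `features`, `family_hits`
#'   (data.frame of peptide index + family), `score`.
#' @export
annotate_protein <- function(protein, protein_id = "protein",
                             mode = c("denovo", "curation"),
                             signal = NULL,
                             signal_pars = signal_params(),
                             rules = NULL,
                             registry = default_family_registry(),
                             weights = score_weights(),
                             min_peptide_len = 3) {
  mode <- match.arg(mode)
  protein <- toupper(protein)
  if (is.null(rules)) {
    rules <- cleavage_rules(monobasic_mode = (mode == "curation"))
  }
  if (is.null(signal)) signal <- predict_signal(protein, signal_pars)
  sig_end <- if (isTRUE(signal$present)) signal$cleave_after else 0L
  sites <- find_cleavage_sites(protein, sig_end, rules)
  segs <- segment_between_sites(protein, sig_end, sites)
  peptides <- lapply(segs, mature)
  if (mode == "denovo" && length(peptides)) {
    keep <- vapply(peptides, function(p) nchar(p$seq) >= min_peptide_len, NA)
    peptides <- peptides[keep]
  }
  peptides <- .assign_copies(peptides)

  features <- list()
  # acidic spacers among raw segments
  for (s in segs) {
    if (detect_acidic_spacer(s)) {
      features[[length(features) + 1]] <- list(
        kind = "acidic_spacer", coords = c(s$start, s$end),
        evidence = sprintf("%d acidic residues in %d",
                           lengths(regmatches(s$seq, gregexpr("[DE]", s$seq))),
                           nchar(s$seq)))
    }
  }
  # neurophysin domain downstream of the last cleavage site
  if (length(sites)) {
    last_end <- sites[[length(sites)]]$end
    np <- detect_neurophysin(protein, last_end + 1)
    if (!is.null(np)) features[[length(features) + 1]] <- np
  }
  ins <- detect_insulin_architecture(protein, sig_end, sites)
  for (f in ins) features[[length(features) + 1]] <- f

  # family classification (multi-label), with CCK-conditional sulfation
  fam_idx <- integer(0); fam_name <- character(0)
  for (i in seq_along(peptides)) {
    fams <- classify(peptides[[i]], registry)
    if ("CCK-type" %in% fams) {
      aa <- strsplit(peptides[[i]]$seq, "")[[1]]
      peptides[[i]]$sulfation_candidates <- which(aa == "Y")
    }
    if (length(fams)) {
      fam_idx <- c(fam_idx, rep(i, length(fams)))
      fam_name <- c(fam_name, fams)
    }
  }

  ann <- structure(list(
    protein_id = protein_id, protein = protein, mode = mode,
    signal = signal, sites = sites, peptides = peptides,
    features = features,
    family_hits = data.frame(peptide = fam_idx, family = fam_name,
                             stringsAsFactors = FALSE),
    score = NULL), class = "precursor_annotation")
  ann$score <- score_precursor(ann, weights)$total
  ann
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat(sprintf("Precursor annotation: %s (%d residues, %s mode, score %.2f)\n",
              x$protein_id, nchar(x$protein), x$mode, x$score))
  print(x$signal)
  cat(sprintf("Cleavage sites: %d; peptides: %d; features: %d\n",
              length(x$sites), length(x$peptides), length(x$features)))
  invisible(x)
}

#' @export
summary.precursor_annotation <- function(object, ...) {
  x <- object
  print(x)
  if (length(x$peptides)) {
    cat("\nPredicted mature peptides:\n")
    for (i in seq_along(x$peptides)) {
      p <- x$peptides[[i]]
      fams <- x$family_hits$family[x$family_hits$peptide == i]
      cat(sprintf("  %2d. %4d-%-4d %-30s%s\n", i, p$precursor_coords[1],
                  p$precursor_coords[2], peptide_notation(p),
                  if (length(fams)) paste0("  [", paste(fams, collapse = ", "), "]") else ""))
    }
  }
  for (f in x$features) {
    cat(sprintf("Feature: %s at %d-%d (%s)\n", f$kind, f$coords[1],
                f$coords[2], f$evidence))
  }
  invisible(x)
}

#' De novo neuropeptide precursor discovery over contigs
#'
#' The full pipeline: six-frame ORF extraction, signal-peptide prediction,
#' cleavage-site detection, peptide maturation, feature detection, family
#' classification, composite scoring and ranking.
#'
#' @param contigs A `contig_set` (from [read_fasta()]) or list of
#'   `list(id=, seq=)` records.
#' @param min_len Minimum ORF protein length (residues).
#' @param allow_partial Passed to [six_frame_orfs()].
#' @param top_n Size of the ranked candidate list.
#' @param signal_table Optional named list of imported `signal_prediction`s
#'   (keyed by protein id `<contig>_orf<k>`), overriding the heuristic.
#' @param require_signal Keep only candidates with a predicted signal
#'   peptide (the defining gate for a secreted precursor).
#' @param require_sites Keep only candidates with at least this many
#'   cleavage sites.
#' @param ... Passed to [annotate_protein()].
#' @return A list of class `discovery_result`: `orfs` (data.frame with
#'   `protein_id` column), `annotations` (ranked list), `table` (ranked
#'   summary data.frame).
#' @export
discover <- function(contigs, min_len = 60, allow_partial = FALSE,
                     top_n = 500, signal_table = NULL,
                     require_signal = TRUE, require_sites = 1, ...) {
  all_orfs <- list()
  for (ct in contigs) {
    o <- six_frame_orfs(ct, min_len = min_len, allow_partial = allow_partial)
    if (nrow(o)) all_orfs[[length(all_orfs) + 1]] <- o
  }
  orfs <- if (length(all_orfs)) do.call(rbind, all_orfs) else
    six_frame_orfs(list(id = "x", seq = "A"), min_len = 1)[0, ]
  if (nrow(orfs)) {
    orfs$protein_id <- paste0(orfs$contig_id, "_orf",
                              ave(seq_len(nrow(orfs)), orfs$contig_id,
                                  FUN = seq_along))
  } else {
    orfs$protein_id <- character(0)
  }
  anns <- list()
  for (i in seq_len(nrow(orfs))) {
    pid <- orfs$protein_id[[i]]
    sig <- if (!is.null(signal_table) && pid %in% names(signal_table)) {
      signal_table[[pid]]
    } else NULL
    ann <- annotate_protein(orfs$protein[[i]], protein_id = pid,
                            signal = sig, ...)
    if (require_signal && !isTRUE(ann$signal$present)) next
    if (length(ann$sites) < require_sites) next
    anns[[length(anns) + 1]] <- ann
  }
  ranked <- rank_candidates(anns, top_n = top_n)
  tab <- if (length(ranked)) {
    data.frame(
      rank = seq_along(ranked),
      protein_id = vapply(ranked, `[[`, "", "protein_id"),
      length = vapply(ranked, function(a) nchar(a$protein), 0L),
      signal_end = vapply(ranked, function(a) {
        if (isTRUE(a$signal$present)) a$signal$cleave_after else NA_integer_
      }, 0L),
      n_sites = vapply(ranked, function(a) length(a$sites), 0L),
      n_peptides = vapply(ranked, function(a) length(a$peptides), 0L),
      n_amide = vapply(ranked, function(a) {
        sum(vapply(a$peptides, `[[`, NA, "cterm_amide"))
      }, 0L),
      score = vapply(ranked, `[[`, 0, "score"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(rank = integer(0), protein_id = character(0),
               length = integer(0), signal_end = integer(0),
               n_sites = integer(0), n_peptides = integer(0),
               n_amide = integer(0), score = numeric(0))
  }
  structure(list(orfs = orfs, annotations = ranked, table = tab),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("Discovery result: %d ORF(s) scanned, %d candidate(s) ranked\n",
              nrow(x$orfs), length(x$annotations)))
  if (nrow(x$table)) print(head(x$table, 10), row.names = FALSE)
  invisible(x)
}
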