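#' Apply post-translational maturation rules to a raw excised segment
#'
#' Models the two classical processing steps downstream of prohormone
#' convertase cleavage: peptidyl-glycine alpha-amidation (a segment ending
#' in G loses that single G and gains a C-terminal amide) and cyclisation of
#' an N-terminal glutamine to pyroglutamate (flag only; the sequence is
#' unchanged). Cysteines are indexed and disulfide capacity computed;
#' tyrosines are flagged as sulfation candidates only when the sulfation
#' rule is enabled (by default it is applied downstream to CCK-type
#' peptides only).
#'
#' @param segment A raw segment `list(start, end, seq)` from
#'   [segment_between_sites()], or a plain amino-acid string.
#' @param pyroglu Apply the N-terminal pyroglutamate rule.
#' @param flag_sulfation Flag tyrosine positions as sulfation candidates.
#' @return A list of class `mature_peptide`: `seq`, `precursor_coords`
#'   (range of the raw segment), `cterm_amide`, `nterm_pyroglu`,
#'   `cys_positions`, `max_disulfides`, `sulfation_candidates`, `copy_id`.
#' @export
mature <- function(segment, pyroglu = TRUE, flag_sulfation = FALSE) {
  if (is.character(segment)) segment <- list(start = 1L,
                                             end = nchar(segment),
                                             seq = segment)
  stopifnot(nzchar(segment$seq))
  s <- toupper(segment$seq)
  amide <- FALSE
  if (substr(s, nchar(s), nchar(s)) == "G" && nchar(s) > 1) {
    s <- substr(s, 1, nchar(s) - 1)
    amide <- TRUE
  }
  pq <- pyroglu && substr(s, 1, 1) == "Q"
  aa <- strsplit(s, "")[[1]]
  cys <- which(aa == "C")
  sulf <- if (flag_sulfation) which(aa == "Y") else integer(0)
  structure(list(
    seq = s,
    precursor_coords = c(segment$start, segment$end),
    cterm_amide = amide,
    nterm_pyroglu = pq,
    cys_positions = cys,
    max_disulfides = length(cys) %/% 2L,
    sulfation_candidates = sulf,
    copy_id = NA_integer_), class = "mature_peptide")
}

#' Render a mature peptide in conventional notation
#'
#' E.g. `pQWYT-NH2` for a pyroglutamated, amidated peptide.
#' @param peptide A `mature_peptide`.
#' @return Single string.
#' @export
peptide_notation <- function(peptide) {
  paste0(if (peptide$nterm_pyroglu) "p" else "", peptide$seq,
         if (peptide$cterm_amide) "-NH2" else "")
}

#' @export
print.mature_peptide <- function(x, ...) {
  cat(peptide_notation(x))
  if (length(x$cys_positions)) {
    cat(sprintf("  [%d Cys, <=%d disulfide(s)]", length(x$cys_positions),
                x$max_disulfides))
  }
  if (length(x$sulfation_candidates)) {
    cat(sprintf("  [sulfation: Y at %s]",
                paste(x$sulfation_candidates, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}

# Assign copy_id: identical sequences within one precursor share an id.
.assign_copies <- function(peptides) {
  if (!length(peptides)) return(peptides)
  seqs <- vapply(peptides, `[[`, "", "seq")
  ids <- match(seqs, unique(seqs))
  for (i in seq_along(peptides)) peptides[[i]]$copy_id <- ids[[i]]
  peptides
}

#' Detect a C-terminal neurophysin domain
#'
#' Neurophysins, the carrier domains that follow vasopressin/oxytocin-type
#' peptides in their precursors, carry a conserved complement of 14
#' cysteine residues. The region downstream of the last cleavage site is
#' reported as a neurophysin domain exactly when it contains 14 cysteines.
#'
#' @param protein Amino-acid string (length >= 60).
#' @param start_hint 1-based index of the first residue after the last
#'   cleavage site.
#' @return A feature `list(kind = "neurophysin_domain", coords, evidence)`,
#'   or `NULL`.
#' @export
detect_neurophysin <- function(protein, start_hint) {
  n <- nchar(protein)
  if (n < 60 || start_hint > n) return(NULL)
  region <- substr(protein, start_hint, n)
  ncys <- lengths(regmatches(region, gregexpr("C", region)))
  if (ncys != 14) return(NULL)
  list(kind = "neurophysin_domain", coords = c(start_hint, n),
       evidence = "14 cysteine residues in C-terminal region")
}

#' Detect an acidic spacer segment
#'
#' Acidic (D/E-rich) inter-peptide segments are presumed non-bioactive
#' spacers within precursors.
#'
#' @param segment Raw segment (list with `seq`, or string).
#' @param min_acidic Minimum count of D+E (default 6).
#' @param min_fraction Minimum acidic fraction of the segment (default 0.2).
#' @return `TRUE` when both thresholds hold.
#' @export
detect_acidic_spacer <- function(segment, min_acidic = 6, min_fraction = 0.2) {
  s <- if (is.character(segment)) segment else segment$seq
  n <- nchar(s)
  if (n == 0) return(FALSE)
  n_acid <- lengths(regmatches(s, gregexpr("[DE]", s)))
  n_acid >= min_acidic && n_acid / n >= min_fraction
}

#' Detect an insulin/relaxin-superfamily precursor layout
#'
#' Labels the B-chain (two cysteines with the superfamily spacing motif
#' CxxxxxxxxxxxC), the connecting C-peptide (between two dibasic sites) and
#' the A-chain (four cysteines with the motif CCxxxCxxxxxxxxC) among the
#' segments of a precursor.
#'
#' @param protein Amino-acid string.
#' @param signal_end 1-based index of the signal's last residue (0 if none).
#' @param sites Output of [find_cleavage_sites()].
#' @return List of features `list(kind, coords, evidence)` in precursor
#'   order; empty when the motifs are absent.
#' @export
detect_insulin_architecture <- function(protein, signal_end, sites) {
  segs <- segment_between_sites(protein, signal_end, sites)
  if (length(segs) < 3) return(list())
  has_a <- function(s) grepl("CC.{3}C.{8}C", s)
  has_b <- function(s) grepl("C.{11}C", s) && !has_a(s)
  b_idx <- which(vapply(segs, function(x) has_b(x$seq), NA))
  a_idx <- which(vapply(segs, function(x) has_a(x$seq), NA))
  if (!length(b_idx) || !length(a_idx)) return(list())
  b <- min(b_idx); a <- max(a_idx)
  if (a <= b + 1) return(list())
  feats <- list(
    list(kind = "insulin_B_chain", coords = c(segs[[b]]$start, segs[[b]]$end),
         evidence = "cysteine motif CxxxxxxxxxxxC"))
  for (k in (b + 1):(a - 1)) {
    feats[[length(feats) + 1]] <- list(
      kind = "C_peptide", coords = c(segs[[k]]$start, segs[[k]]$end),
      evidence = "connecting peptide between dibasic sites")
  }
  feats[[length(feats) + 1]] <- list(
    kind = "insulin_A_chain", coords = c(segs[[a]]$start, segs[[a]]$end),
    evidence = "cysteine motif CCxxxCxxxxxxxxC")
  feats
}
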