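#' Default weights for the composite precursor-likeness score
#'
#' A transparent, evidence-monotone surrogate for trained precursor models:
#' every feature counts hallmark evidence of neuropeptide-precursor
#' architecture, so adding evidence can only raise the score.
#'
#' @param has_signal Weight for a predicted signal peptide (0/1 feature).
#' @param per_site Weight per cleavage site (feature capped at `site_cap`).
#' @param site_cap Cap on the cleavage-site count feature.
#' @param per_amide_gly Weight per C-terminal amidation glycine.
#' @param peptide_coverage Weight for the fraction of post-signal residues
#'   inside predicted peptides.
#' @param per_extra_copy Weight per peptide copy beyond the first of the
#'   most-repeated peptide (multi-copy precursors are strong candidates).
#' @param acidic_spacer Weight for presence of an acidic spacer segment.
#' @param length_penalty Weight (negative) per residue of protein length
#'   over `length_cap`.
#' @param length_cap Residue count above which the length penalty applies.
#' @return A named list of class `score_weights`.
#' @export
score_weights <- function(has_signal = 3.0, per_site = 1.0, site_cap = 10,
                          per_amide_gly = 1.0, peptide_coverage = 2.0,
                          per_extra_copy = 2.0, acidic_spacer = 0.5,
                          length_penalty = -0.01, length_cap = 500) {
  w <- list(has_signal = has_signal, per_site = per_site, site_cap = site_cap,
            per_amide_gly = per_amide_gly, peptide_coverage = peptide_coverage,
            per_extra_copy = per_extra_copy, acidic_spacer = acidic_spacer,
            length_penalty = length_penalty, length_cap = length_cap)
  pos <- c("has_signal", "per_site", "per_amide_gly", "peptide_coverage",
           "per_extra_copy", "acidic_spacer")
  if (any(unlist(w[pos]) < 0)) {
    stop("Weights for positive evidence features must be non-negative")
  }
  if (length_penalty > 0) stop("length_penalty weight must be <= 0")
  structure(w, class = "score_weights")
}

#' Score a precursor annotation
#'
#' Computes the composite precursor-likeness score as an exact weighted sum
#' of architecture features.
#'
#' @param annotation A [precursor_annotation] object.
#' @param weights A [score_weights()] list.
#' @return A list of class `score_breakdown` with `features`, `weights`
#'   (applied weight per feature) and `total`.
#' @export
score_precursor <- function(annotation, weights = score_weights()) {
  sig <- as.numeric(isTRUE(annotation$signal$present))
  n_sites <- min(length(annotation$sites), weights$site_cap)
  n_amide <- sum(vapply(annotation$peptides, `[[`, NA, "cterm_amide"))
  prot_len <- nchar(annotation$protein)
  post_signal <- prot_len - (if (sig > 0) annotation$signal$cleave_after else 0)
  pep_res <- sum(vapply(annotation$peptides, function(p) {
    p$precursor_coords[2] - p$precursor_coords[1] + 1
  }, 0))
  coverage <- if (post_signal > 0) pep_res / post_signal else 0
  copies <- vapply(annotation$peptides, `[[`, 0L, "copy_id")
  max_copies <- if (length(copies)) max(tabulate(copies)) else 0
  extra_copies <- max(0, max_copies - 1)
  spacer <- as.numeric(any(vapply(annotation$features, function(f) {
    f$kind == "acidic_spacer"
  }, NA)))
  if (is.na(spacer)) spacer <- 0
  over_len <- max(0, prot_len - weights$length_cap)
  features <- c(has_signal = sig, n_sites = n_sites, n_amide_gly = n_amide,
                peptide_coverage = coverage, extra_copies = extra_copies,
                has_acidic_spacer = spacer, over_length = over_len)
  w <- c(has_signal = weights$has_signal, n_sites = weights$per_site,
         n_amide_gly = weights$per_amide_gly,
         peptide_coverage = weights$peptide_coverage,
         extra_copies = weights$per_extra_copy,
         has_acidic_spacer = weights$acidic_spacer,
         over_length = weights$length_penalty)
  structure(list(features = features, weights = w,
                 total = sum(w * features)), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("Precursor-likeness score:", format(x$total, digits = 4), "\n")
  df <- data.frame(feature = names(x$features), value = unname(x$features),
                   weight = unname(x$weights),
                   contribution = unname(x$features * x$weights))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rank candidate precursors
#'
#' Sorts annotations by composite score (descending), breaking ties by the
#' number of amidation glycines (descending) then protein id (ascending),
#' and truncates to the top `top_n` (default 500, the conventional size of
#' a curation short-list).
#'
#' @param annotations List of [precursor_annotation] objects (with scores
#'   already attached, or they are computed with default weights).
#' @param top_n Number of candidates to keep.
#' @param weights Passed to [score_precursor()] when scores are missing.
#' @return The ranked, truncated list of annotations; each carries its
#'   `score` and `rank`.
#' @export
rank_candidates <- function(annotations, top_n = 500,
                            weights = score_weights()) {
  stopifnot(top_n >= 1)
  if (!length(annotations)) return(list())
  for (i in seq_along(annotations)) {
    if (is.null(annotations[[i]]$score)) {
      annotations[[i]]$score <- score_precursor(annotations[[i]], weights)$total
    }
  }
  totals <- vapply(annotations, `[[`, 0, "score")
  n_amide <- vapply(annotations, function(a) {
    sum(vapply(a$peptides, `[[`, NA, "cterm_amide"))
  }, 0)
  ids <- vapply(annotations, `[[`, "", "protein_id")
  ord <- order(-totals, -n_amide, ids)
  out <- annotations[ord]
  out <- head(out, top_n)
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}
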