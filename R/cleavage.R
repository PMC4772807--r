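#' Rules for prohormone-convertase cleavage-site detection
#'
#' @param pairs Accepted dibasic pairs. KR is flagged `canonical`; other
#'   pairs `extended`.
#' @param allow_tribasic Report runs of three basics as a single tribasic
#'   site (runs of four or more: leftmost three as tribasic, remainder
#'   re-examined).
#' @param monobasic_mode When `TRUE`, a lone R is reported as a monobasic
#'   site if another basic residue (K/R) lies 2, 4 or 6 positions upstream.
#'   Off by default (de novo mode); enabled in curation mode.
#' @return A list of class `cleavage_rules`.
#' @export
cleavage_rules <- function(pairs = c("KR", "RR", "KK", "RK"),
                           allow_tribasic = TRUE,
                           monobasic_mode = FALSE) {
  structure(list(pairs = pairs, allow_tribasic = allow_tribasic,
                 monobasic_mode = monobasic_mode),
            class = "cleavage_rules")
}

#' Locate prohormone-convertase cleavage sites
#'
#' Scans the protein after the signal peptide for maximal runs of basic
#' residues (K/R). A run of two matching an accepted pair is a dibasic
#' site; a run of three is a single tribasic site (not nested dibasics);
#' runs of four or more are split deterministically (leftmost three as
#' tribasic, remainder re-examined under the same rules). A lone R is a
#' monobasic site only under `monobasic_mode`, and only when another basic
#' residue lies 2, 4 or 6 positions upstream.
#'
#' @param protein Amino-acid string.
#' @param signal_end 1-based index of the signal peptide's last residue
#'   (0 when no signal); sites never overlap the signal.
#' @param rules A [cleavage_rules()] list.
#' @return List of sites, each `list(start, end, kind, motif, confidence)`
#'   with 1-based inclusive coordinates, sorted by `start`.
#' @export
find_cleavage_sites <- function(protein, signal_end = 0,
                                rules = cleavage_rules()) {
  protein <- toupper(protein)
  n <- nchar(protein)
  stopifnot(signal_end < n)
  aa <- strsplit(protein, "")[[1]]
  basic <- aa %in% c("K", "R")
  sites <- list()
  add <- function(start, end) {
    motif <- paste0(aa[start:end], collapse = "")
    len <- end - start + 1
    if (len == 2 && !(motif %in% rules$pairs)) return()
    kind <- c("monobasic", "dibasic", "tribasic")[len]
    conf <- if ((len == 2 && motif == "KR") ||
                (len == 3 && substr(motif, 2, 3) == "KR")) "canonical" else "extended"
    sites[[length(sites) + 1]] <<- list(start = start, end = end, kind = kind,
                                        motif = motif, confidence = conf)
  }
  # maximal runs of K/R strictly after the signal
  i <- signal_end + 1
  while (i <= n) {
    if (!basic[i]) { i <- i + 1; next }
    j <- i
    while (j < n && basic[j + 1]) j <- j + 1
    run_start <- i
    run_end <- j
    # split the run deterministically
    s <- run_start
    while (s <= run_end) {
      rem <- run_end - s + 1
      if (rem >= 3 && rules$allow_tribasic) {
        add(s, s + 2); s <- s + 3
      } else if (rem >= 2) {
        add(s, s + 1); s <- s + 2
      } else {
        # lone basic residue
        if (rules$monobasic_mode && aa[s] == "R") {
          up <- s - c(2, 4, 6)
          up <- up[up > signal_end]
          if (length(up) && any(basic[up])) add(s, s)
        }
        s <- s + 1
      }
    }
    i <- run_end + 1
  }
  sites[order(vapply(sites, `[[`, 0, "start"))]
}

#' Excise the raw segments between cleavage sites
#'
#' Segments are the maximal stretches strictly between the signal peptide,
#' the cleavage-site motifs and the C-terminus; basic residues of the site
#' motifs belong to no segment. Concatenating signal, sites and segments in
#' order reconstructs the protein exactly.
#'
#' @param protein Amino-acid string.
#' @param signal_end 1-based index of the signal's last residue (0 if none).
#' @param sites Output of [find_cleavage_sites()] (sorted, non-overlapping).
#' @return List of segments `list(start, end, seq)` (1-based inclusive);
#'   zero-length stretches (adjacent sites) are omitted.
#' @export
segment_between_sites <- function(protein, signal_end, sites) {
  n <- nchar(protein)
  starts <- vapply(sites, `[[`, 0, "start")
  ends <- vapply(sites, `[[`, 0, "end")
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)])) {
    stop("Overlapping cleavage sites")
  }
  bounds_lo <- c(signal_end + 1, ends + 1)
  bounds_hi <- c(starts - 1, n)
  segs <- list()
  for (k in seq_along(bounds_lo)) {
    if (bounds_lo[k] > bounds_hi[k]) next
    segs[[length(segs) + 1]] <- list(
      start = bounds_lo[k], end = bounds_hi[k],
      seq = substr(protein, bounds_lo[k], bounds_hi[k]))
  }
  segs
}
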