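# Per-residue style assignment, precedence high -> low. The legend follows
# the conventional colouring of precursor annotations: signal peptide blue,
# mature peptides red, amidation glycines orange, basic cleavage sites
# green, neurophysin domain purple.
.style_order <- c("signal", "cleavage", "amide_gly", "peptide",
                  "neurophysin", "c_peptide", "plain")

.ansi_codes <- c(signal = "34", cleavage = "32", amide_gly = "33",
                 peptide = "31", neurophysin = "35", c_peptide = "36",
                 plain = "0")

.annotation_spans <- function(ann) {
  n <- nchar(ann$protein)
  style <- rep("plain", n)
  for (p in ann$peptides) {
    style[p$precursor_coords[1]:p$precursor_coords[2]] <- "peptide"
  }
  # domain features take the legend style over the generic peptide red
  for (f in ann$features) {
    st <- switch(f$kind, neurophysin_domain = "neurophysin",
                 C_peptide = "c_peptide", NULL)
    if (!is.null(st)) style[f$coords[1]:f$coords[2]] <- st
  }
  for (p in ann$peptides) {
    if (isTRUE(p$cterm_amide)) {
      style[p$precursor_coords[2]] <- "amide_gly"  # the segment's terminal G
    }
  }
  for (s in ann$sites) {
    style[s$start:s$end] <- "cleavage"
  }
  if (isTRUE(ann$signal$present)) style[1:ann$signal$cleave_after] <- "signal"
  r <- rle(style)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lapply(seq_along(r$values), function(k) {
    list(start = starts[k], end = ends[k], style = r$values[k],
         seq = substr(ann$protein, starts[k], ends[k]))
  })
}

#' Render a precursor annotation as styled text
#'
#' Every residue appears exactly once, styled according to the annotation
#' legend (signal peptide, mature peptides, amidation glycines, cleavage
#' sites, neurophysin domain, C-peptide). The `plain` format wraps spans in
#' bracket tags (`[style]...[/style]`) and can be parsed back to spans with
#' [parse_rendered()]; `html` uses `<span class="style">` elements; `ansi`
#' uses terminal colours.
#'
#' @param annotation A `precursor_annotation`.
#' @param format `"plain"`, `"ansi"` or `"html"`.
#' @return Single string.
#' @export
render_annotation <- function(annotation, format = c("plain", "ansi", "html")) {
  format <- match.arg(format)
  spans <- .annotation_spans(annotation)
  txt <- vapply(spans, function(sp) {
    switch(format,
      plain = if (sp$style == "plain") sp$seq else
        paste0("[", sp$style, "]", sp$seq, "[/", sp$style, "]"),
      ansi = paste0("\033[", .ansi_codes[[sp$style]], "m", sp$seq, "\033[0m"),
      html = paste0("<span class=\"", sp$style, "\">", sp$seq, "</span>"))
  }, "")
  paste0(txt, collapse = "")
}

#' Parse a plain-format render back to spans
#'
#' @param text Output of `render_annotation(..., format = "plain")`.
#' @return List of spans `list(start, end, style, seq)` tiling the protein.
#' @export
parse_rendered <- function(text) {
  spans <- list()
  pos <- 1
  rest <- text
  tag_re <- "^\\[([a-z_]+)\\]"
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(tag_re, rest))[[1]]
    if (length(m)) {
      st <- m[2]
      close <- paste0("[/", st, "]")
      body_start <- nchar(m[1]) + 1
      close_at <- regexpr(close, rest, fixed = TRUE)
      if (close_at < 0) stop("Unclosed tag [", st, "]")
      seq <- substr(rest, body_start, close_at - 1)
      rest <- substr(rest, close_at + nchar(close), nchar(rest))
    } else {
      nxt <- regexpr("[", rest, fixed = TRUE)
      seq <- if (nxt < 0) rest else substr(rest, 1, nxt - 1)
      rest <- if (nxt < 0) "" else substr(rest, nxt, nchar(rest))
      st <- "plain"
    }
    spans[[length(spans) + 1]] <- list(start = pos, end = pos + nchar(seq) - 1,
                                       style = st, seq = seq)
    pos <- pos + nchar(seq)
  }
  spans
}

#' Export annotations as machine-readable tables
#'
#' Writes (or returns) a precursor table, a peptide table and a peptide
#' FASTA. FASTA descriptions carry the conventional maturation suffixes:
#' `-NH2` for amidated peptides and a `pQ` note for N-terminal
#' pyroglutamate.
#'
#' @param annotations List of `precursor_annotation`s.
#' @param prefix Optional file prefix; when given, writes
#'   `<prefix>_precursors.tsv`, `<prefix>_peptides.tsv`,
#'   `<prefix>_peptides.fasta`.
#' @return Invisibly, a list with `precursors` and `peptides` data.frames
#'   and `fasta` (named character vector of peptide sequences).
#' @export
export_tables <- function(annotations, prefix = NULL) {
  prec <- data.frame(
    protein_id = vapply(annotations, `[[`, "", "protein_id"),
    length = vapply(annotations, function(a) nchar(a$protein), 0L),
    signal_present = vapply(annotations, function(a) isTRUE(a$signal$present), NA),
    signal_end = vapply(annotations, function(a) {
      if (isTRUE(a$signal$present)) a$signal$cleave_after else NA_integer_
    }, 0L),
    n_sites = vapply(annotations, function(a) length(a$sites), 0L),
    n_peptides = vapply(annotations, function(a) length(a$peptides), 0L),
    score = vapply(annotations, function(a) a$score %||% NA_real_, 0),
    stringsAsFactors = FALSE)
  pep_rows <- list()
  fasta <- character(0)
  for (a in annotations) {
    for (i in seq_along(a$peptides)) {
      p <- a$peptides[[i]]
      fams <- a$family_hits$family[a$family_hits$peptide == i]
      pep_rows[[length(pep_rows) + 1]] <- data.frame(
        protein_id = a$protein_id, index = i,
        start = p$precursor_coords[1], end = p$precursor_coords[2],
        seq = p$seq, cterm_amide = p$cterm_amide,
        nterm_pyroglu = p$nterm_pyroglu,
        n_cys = length(p$cys_positions), copy_id = p$copy_id,
        families = paste(fams, collapse = ";"), stringsAsFactors = FALSE)
      desc <- paste0(a$protein_id, ".pep", i,
                     if (p$cterm_amide) " -NH2" else "",
                     if (p$nterm_pyroglu) " pQ" else "")
      fasta[[desc]] <- p$seq
    }
  }
  peps <- if (length(pep_rows)) do.call(rbind, pep_rows) else
    data.frame(protein_id = character(0), index = integer(0),
               start = integer(0), end = integer(0), seq = character(0),
               cterm_amide = logical(0), nterm_pyroglu = logical(0),
               n_cys = integer(0), copy_id = integer(0),
               families = character(0), stringsAsFactors = FALSE)
  if (!is.null(prefix)) {
    write.table(prec, paste0(prefix, "_precursors.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(peps, paste0(prefix, "_peptides.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (length(fasta)) write_fasta(fasta, paste0(prefix, "_peptides.fasta"))
  }
  invisible(list(precursors = prec, peptides = peps, fasta = fasta))
}

#' Read back an exported peptide table
#'
#' @param path Path to a `*_peptides.tsv` written by [export_tables()].
#' @return Data.frame with the same columns and types.
#' @export
read_peptide_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(protein_id = "character", seq = "character",
                                  families = "character"))
  df$families[is.na(df$families)] <- ""
  df
}
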