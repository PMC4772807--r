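# Motif mini-language -> regex. Classes: x = any residue, h = hydrophobic
# {A,V,L,I,M,F,W,Y}; bracketed classes pass through; other letters literal.
.compile_motif <- function(pattern, anchor = c("cterm", "nterm")) {
  anchor <- match.arg(anchor)
  out <- character(0)
  i <- 1
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n))
      if (j < 0) stop("Malformed motif pattern (unclosed '['): ", pattern)
      out <- c(out, substr(pattern, i, i + j - 1))
      i <- i + j
    } else if (ch == "x") {
      out <- c(out, "."); i <- i + 1
    } else if (ch == "h") {
      out <- c(out, "[AVLIMFWY]"); i <- i + 1
    } else if (grepl("[A-WYZ.{}0-9,^$]", ch)) {
      out <- c(out, ch); i <- i + 1
    } else {
      stop("Malformed motif pattern (character '", ch, "'): ", pattern)
    }
  }
  body <- paste0(out, collapse = "")
  if (anchor == "cterm" && !endsWith(body, "$")) body <- paste0(body, "$")
  if (anchor == "nterm" && !startsWith(body, "^")) body <- paste0("^", body)
  # X (from ambiguous codons) never matches a motif class or literal
  body
}

.family_entry <- function(family, pattern, anchor, requires_amide = FALSE,
                          requires_pyroglu = FALSE, cys_positions = NULL,
                          cys_min_in_first = NULL, length_range = NULL,
                          confidence = "canonical", provenance = "") {
  list(family = family, pattern = pattern, anchor = anchor,
       regex = .compile_motif(pattern, anchor),
       requires_amide = requires_amide, requires_pyroglu = requires_pyroglu,
       cys_positions = cys_positions, cys_min_in_first = cys_min_in_first,
       length_range = length_range, confidence = confidence,
       provenance = provenance)
}

#' Built-in neuropeptide family motif registry
#'
#' Anchored sequence/structure signatures of neuropeptide families described
#' in echinoderms. Pattern language: `x` any residue, `h` hydrophobic
#' (A,V,L,I,M,F,W,Y), bracketed residue classes. C-terminally anchored
#' patterns refer to the mature (amidated) terminus. Families without a
#' sequence motif (PDF-, CRH-, orexin-, MCH-, somatostatin-type and others)
#' are assigned by homology screening, not by motif.
#'
#' @return A list of class `family_registry`.
#' @export
default_family_registry <- function() {
  reg <- list(
    .family_entry("SALMFamide-L", "[ST]xLx[FY]", "cterm", requires_amide = TRUE,
                  provenance = "L-type C-terminal S/TxLxF/Y-amide motif"),
    .family_entry("SALMFamide-F", "[FY]x[FY]", "cterm", requires_amide = TRUE,
                  provenance = "F-type C-terminal F/YxF/Y-amide motif"),
    .family_entry("kisspeptin", "NxxSxxLxF", "cterm", requires_amide = TRUE,
                  provenance = "C-terminal NxxSxxLxF-amide motif"),
    .family_entry("tachykinin", "GhF", "cterm", requires_amide = TRUE,
                  confidence = "extended",
                  provenance = "C-terminal GxF-amide, x hydrophobic (L/I observed)"),
    .family_entry("luqin", "KFMRW", "cterm", requires_amide = TRUE,
                  provenance = "C-terminal KFMRW-amide"),
    .family_entry("CCK-type", "[DQ]YGxGLF[WF]", "cterm", requires_amide = TRUE,
                  confidence = "extended",
                  provenance = "generalised from octapeptides DYGHGLFW / QYGFGLFF"),
    .family_entry("GnRH-type", "WxxG", "cterm", requires_amide = TRUE,
                  provenance = "C-terminal WxxG-amide motif"),
    .family_entry("TRH-type", "Q", "nterm", requires_amide = TRUE,
                  requires_pyroglu = TRUE, length_range = c(4, 4),
                  provenance = "tetrapeptide with N-terminal pyroglutamate and C-terminal amide"),
    .family_entry("VP/OT-type", "CxxxxC", "nterm", requires_amide = TRUE,
                  cys_positions = c(1, 6), length_range = c(9, 9),
                  provenance = "9-residue amidated peptide, disulfide between Cys1 and Cys6"),
    .family_entry("calcitonin-type", "x", "nterm", requires_amide = TRUE,
                  cys_min_in_first = c(2, 10), length_range = c(10, 50),
                  confidence = "extended",
                  provenance = "two cysteines in the N-terminal region, amidated terminus"),
    .family_entry("insulin-A-chain", "CCxxxCxxxxxxxxC", "cterm",
                  provenance = "A-chain cysteine motif CCxxxCxxxxxxxxC, C-terminal Cys (relaxin-type)"),
    .family_entry("insulin-B-chain", "^.{0,12}CxxxxxxxxxxxC", "nterm",
                  provenance = "B-chain cysteine motif CxxxxxxxxxxxC"),
    .family_entry("relaxin-RBM", "^.{0,20}RxxxRxx[IV]", "nterm",
                  confidence = "extended",
                  provenance = "relaxin receptor-binding motif RxxxRxxI/V"),
    .family_entry("AN-peptide", "AN", "nterm",
                  provenance = "N-terminal alanine/asparagine (AN) motif")
  )
  names(reg) <- vapply(reg, `[[`, "", "family")
  structure(reg, class = "family_registry")
}

#' Classify a mature peptide into neuropeptide families
#'
#' Returns every registry family whose anchored pattern, amide requirement,
#' pyroglutamate requirement, cysteine constraint and length range all hold.
#' Output is multi-label (a peptide may match several families) in registry
#' order; arbitration between overlapping families is left to the analyst.
#'
#' @param peptide A `mature_peptide` (from [mature()]) or an amino-acid
#'   string (treated as amidated only if `assume_amide`).
#' @param registry A `family_registry` (default [default_family_registry()]).
#' @param assume_amide When `peptide` is a bare string, its amidation state.
#' @return Character vector of family names (possibly empty).
#' @export
classify <- function(peptide, registry = default_family_registry(),
                     assume_amide = FALSE) {
  if (is.character(peptide)) {
    p <- mature(peptide, pyroglu = FALSE)
    p$cterm_amide <- assume_amide
    p$seq <- peptide
    p$cys_positions <- which(strsplit(peptide, "")[[1]] == "C")
    peptide <- p
  }
  if (!length(registry)) stop("Empty family registry")
  hits <- character(0)
  for (e in registry) {
    if (isTRUE(e$requires_amide) && !isTRUE(peptide$cterm_amide)) next
    if (isTRUE(e$requires_pyroglu) && !isTRUE(peptide$nterm_pyroglu)) next
    if (!is.null(e$length_range)) {
      n <- nchar(peptide$seq)
      if (n < e$length_range[1] || n > e$length_range[2]) next
    }
    if (!is.null(e$cys_positions)) {
      if (!identical(as.integer(peptide$cys_positions),
                     as.integer(e$cys_positions))) next
    }
    if (!is.null(e$cys_min_in_first)) {
      k <- e$cys_min_in_first[1]; w <- e$cys_min_in_first[2]
      if (sum(peptide$cys_positions <= w) < k) next
    }
    if (grepl("X", peptide$seq, fixed = TRUE)) {
      # X never matches a motif: skip pattern-bearing entries unless the
      # match avoids X -- conservative: require a match on the X-free string
      if (!grepl(e$regex, peptide$seq, perl = TRUE) ||
          grepl("X", regmatches(peptide$seq,
                                regexpr(e$regex, peptide$seq, perl = TRUE)))) next
    } else if (!grepl(e$regex, peptide$seq, perl = TRUE)) next
    hits <- c(hits, e$family)
  }
  hits
}

#' Load a family-motif registry from a YAML file
#'
#' Built-in defaults are merged with user entries; a user entry with the
#' same family name overrides the default. Each user entry is a mapping
#' with keys `family`, `pattern`, `anchor` (`cterm`/`nterm`) and optional
#' `requires_amide`, `requires_pyroglu`, `length_range`, `cys_positions`,
#' `confidence`, `provenance`.
#'
#' @param path YAML file path (may define zero entries).
#' @param defaults Base registry to merge into.
#' @return A `family_registry`.
#' @export
registry_load <- function(path, defaults = default_family_registry()) {
  doc <- yaml::read_yaml(path)
  entries <- doc$families
  if (is.null(entries)) entries <- list()
  fams <- vapply(entries, function(e) e$family %||% "", "")
  if (anyDuplicated(fams[nzchar(fams)])) {
    stop("Duplicate family names in registry file: ",
         fams[duplicated(fams)][1])
  }
  reg <- unclass(defaults)
  for (e in entries) {
    if (is.null(e$family) || is.null(e$pattern)) {
      stop("Registry entry must have 'family' and 'pattern'")
    }
    entry <- .family_entry(
      family = e$family, pattern = e$pattern,
      anchor = e$anchor %||% "cterm",
      requires_amide = isTRUE(e$requires_amide),
      requires_pyroglu = isTRUE(e$requires_pyroglu),
      cys_positions = e$cys_positions,
      length_range = e$length_range,
      confidence = e$confidence %||% "user",
      provenance = e$provenance %||% "user-supplied")
    reg[[e$family]] <- entry
  }
  structure(reg, class = "family_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
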