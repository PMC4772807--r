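# Internal: genetic code lookup (standard code, table 1).
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.translate_codons <- function(codons) {
  tab <- .codon_table()
  aa <- tab[codons]
  # any codon containing a character outside ACGT (i.e. N) translates to X
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read sequences from a FASTA file
#'
#' Reads nucleotide contigs or protein records from FASTA. Sequences are
#' uppercased; in nucleotide mode `U` is converted to `T`. Record order is
#' preserved. Duplicate record identifiers and characters outside the
#' permitted alphabet are rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param type `"nucleotide"` (alphabet A, C, G, T, N after U->T) or
#'   `"protein"` (the 20 amino acids plus X and `*`).
#' @return A named list of class `contig_set`: one element per record, each a
#'   list with `id` and `seq`. Empty file yields an empty list.
#' @export
read_fasta <- function(path, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur_seq <- character(0)
  allowed <- if (type == "nucleotide") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX*"
  ok_re <- paste0("^[", gsub("\\*", "\\\\*", allowed), "]*$")
  flush_record <- function() {
    if (!is.null(cur_id)) {
      ids <<- c(ids, cur_id)
      seqs <<- c(seqs, paste0(cur_seq, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      id <- sub("^>\\s*", "", ln)
      id <- sub("\\s.*$", "", id)
      if (!nzchar(id)) {
        stop("Malformed FASTA header at line ", i, ": empty identifier")
      }
      flush_record()
      cur_id <- id
      cur_seq <- character(0)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_id)) {
        stop("Malformed FASTA at line ", i, ": sequence before any header")
      }
      s <- toupper(trimws(ln))
      if (type == "nucleotide") s <- gsub("U", "T", s, fixed = TRUE)
      if (!grepl(ok_re, s)) {
        bad <- regmatches(s, regexpr(paste0("[^", gsub("\\*", "\\\\*", allowed), "]"), s))
        stop("Illegal character '", bad, "' at line ", i,
             " (allowed: ", allowed, ")")
      }
      cur_seq <- c(cur_seq, s)
    }
  }
  flush_record()
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("Duplicate record id in FASTA: '", dup, "'")
  }
  if (length(ids) && any(!nchar(seqs))) {
    stop("Record '", ids[!nchar(seqs)][1], "' has an empty sequence")
  }
  recs <- lapply(seq_along(ids), function(i) list(id = ids[[i]], seq = seqs[[i]]))
  names(recs) <- ids
  structure(recs, class = "contig_set", type = type)
}

#' Write sequence records to FASTA
#'
#' @param records Named list of `list(id=, seq=)` records (a `contig_set`), or
#'   a named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i) {
      list(id = names(records)[[i]], seq = unname(records[[i]]))
    })
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$seq
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Extract open reading frames by six-frame translation
#'
#' Translates a contig in all six frames, considers every maximal
#' stop-to-stop segment, and reports one ORF per segment following the
#' leftmost-longest convention: the ORF starts at the first methionine of
#' the segment, or at the segment start when `allow_partial = TRUE` and the
#' segment abuts the contig edge in its reading direction. Nucleotide
#' coordinates are 0-based half-open on the forward strand and cover exactly
#' the reported codons (stop codon excluded).
#'
#' @param contig A `list(id=, seq=)` contig record (as produced by
#'   [read_fasta()]).
#' @param min_len Minimum protein length, in residues (default 60: secreted
#'   precursor proteins are rarely shorter).
#' @param allow_partial Report ORFs truncated by the contig edge (missing
#'   start and/or stop).
#' @return A data.frame with columns `contig_id`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `protein`, `partial5`, `partial3`, sorted by
#'   (`nt_start`, `strand`, `frame`).
#' @export
six_frame_orfs <- function(contig, min_len = 60, allow_partial = FALSE) {
  stopifnot(min_len >= 1)
  seq <- toupper(contig$seq)
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    rseq <- if (strand == "+") seq else .revcomp(seq)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < 1) next
      starts <- frame + seq_len(n_codons) * 3 - 2   # 1-based codon starts in rseq
      codons <- substring(rseq, starts, starts + 2)
      aa <- .translate_codons(codons)
      is_stop <- aa == "*"
      # maximal stop-to-stop segments (runs of non-stop codons)
      r <- rle(is_stop)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1
      for (k in seq_along(r$values)) {
        if (r$values[[k]]) next
        seg_from <- starts_idx[[k]]  # codon index, 1-based
        seg_to <- ends_idx[[k]]
        abuts5 <- seg_from == 1                 # no upstream in-frame stop
        abuts3 <- seg_to == n_codons            # ran into contig edge, no stop
        seg_aa <- aa[seg_from:seg_to]
        first_m <- match("M", seg_aa)
        if (allow_partial && abuts5 && (is.na(first_m) || first_m > 1)) {
          orf_from <- seg_from
          partial5 <- TRUE
        } else if (!is.na(first_m)) {
          orf_from <- seg_from + first_m - 1
          partial5 <- FALSE
        } else {
          next
        }
        partial3 <- abuts3
        if (partial3 && !allow_partial) next
        protein <- paste0(aa[orf_from:seg_to], collapse = "")
        if (nchar(protein) < min_len) next
        # reading-frame coords (0-based half-open on rseq)
        r_start <- frame + (orf_from - 1) * 3
        r_end <- frame + seg_to * 3
        if (strand == "+") {
          nt_start <- r_start; nt_end <- r_end
        } else {
          nt_start <- L - r_end; nt_end <- L - r_start
        }
        out[[length(out) + 1]] <- data.frame(
          contig_id = contig$id, strand = strand, frame = frame,
          nt_start = nt_start, nt_end = nt_end, protein = protein,
          partial5 = partial5, partial3 = partial3,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), protein = character(0),
                      partial5 = logical(0), partial3 = logical(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$nt_start, df$strand, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Project a residue range of an ORF onto forward-strand nucleotides
#'
#' @param orf One ORF row (list or single-row data.frame) with `strand`,
#'   `nt_start`, `nt_end`.
#' @param res_start,res_end 1-based inclusive residue coordinates.
#' @return Integer vector `c(start, end)`, 1-based inclusive nucleotide
#'   coordinates on the forward strand (GFF3 convention).
#' @export
residues_to_nt <- function(orf, res_start, res_end) {
  stopifnot(res_start >= 1, res_end >= res_start)
  if (orf$strand == "+") {
    c(orf$nt_start + 3 * (res_start - 1) + 1, orf$nt_start + 3 * res_end)
  } else {
    c(orf$nt_end - 3 * res_end + 1, orf$nt_end - 3 * (res_start - 1))
  }
}

#' Export precursor annotations as GFF3
#'
#' Emits `signal_peptide`, `cleavage_site`, `mature_peptide` and `domain`
#' features in 1-based inclusive nucleotide coordinates on the forward
#' strand, projected phase-correctly from residue coordinates.
#'
#' @param annotations List of [precursor_annotation] objects.
#' @param orfs Data.frame of ORFs ([six_frame_orfs()] output, with a
#'   `protein_id` column or rownames matching annotation `protein_id`s), or a
#'   named list mapping `protein_id` to an ORF row.
#' @param path Optional output file; when `NULL` the GFF3 text is returned.
#' @return GFF3 text (character vector of lines), invisibly when written.
#' @export
write_gff3 <- function(annotations, orfs, path = NULL) {
  lines <- "##gff-version 3"
  orf_for <- function(id) {
    if (is.data.frame(orfs)) {
      i <- match(id, orfs$protein_id)
      if (is.na(i)) stop("Annotation references unknown ORF: ", id)
      as.list(orfs[i, ])
    } else {
      o <- orfs[[id]]
      if (is.null(o)) stop("Annotation references unknown ORF: ", id)
      o
    }
  }
  feat_line <- function(contig, type, nt, strand, attrs) {
    paste(contig, "npscan", type, nt[1], nt[2], ".", strand, ".", attrs,
          sep = "\t")
  }
  n <- 0
  for (ann in annotations) {
    orf <- orf_for(ann$protein_id)
    emit <- function(type, rs, re, attrs) {
      nt <- residues_to_nt(orf, rs, re)
      lines[[length(lines) + 1]] <<- feat_line(orf$contig_id, type, nt,
                                               orf$strand, attrs)
    }
    n <- n + 1
    if (isTRUE(ann$signal$present)) {
      emit("signal_peptide", 1, ann$signal$cleave_after,
           paste0("ID=", ann$protein_id, ".sig;Parent=", ann$protein_id))
    }
    for (s in ann$sites) {
      emit("cleavage_site", s$start, s$end,
           paste0("Parent=", ann$protein_id, ";kind=", s$kind,
                  ";motif=", s$motif))
    }
    for (i in seq_along(ann$peptides)) {
      p <- ann$peptides[[i]]
      emit("mature_peptide", p$precursor_coords[1], p$precursor_coords[2],
           paste0("ID=", ann$protein_id, ".pep", i, ";Parent=", ann$protein_id,
                  ";amide=", tolower(p$cterm_amide),
                  ";pyroglu=", tolower(p$nterm_pyroglu)))
    }
    for (f in ann$features) {
      emit("domain", f$coords[1], f$coords[2],
           paste0("Parent=", ann$protein_id, ";kind=", f$kind))
    }
  }
  lines <- unlist(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
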