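#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (from Biostrings), restricted to the 20
#' residues plus X.
#' @return Integer matrix with dimnames over the residue alphabet.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V", "X")
  m[keep, keep]
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic programming with Gotoh's affine-gap recurrences; a gap of
#' length k costs `gap_open + k * gap_extend`. Used as the desk-scale
#' surrogate for translated-BLAST homology screening: datasets here are
#' small enough that no heuristic seeding is needed. Tie-break among
#' co-optimal alignments is deterministic: smallest target start, then
#' smallest query start, then shortest alignment.
#'
#' @param query,target Amino-acid strings (non-empty).
#' @param matrix Substitution matrix covering all residues present
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (positive numbers; defaults 11
#'   and 1, the translated-BLAST defaults).
#' @return A list of class `alignment_hit`: `score` (0 for no positive-
#'   scoring alignment, with empty alignment), `q_start`, `q_end`,
#'   `t_start`, `t_end` (1-based inclusive; `NA` when empty), `q_aln`,
#'   `t_aln` (aligned strings with `-` gaps).
#' @export
smith_waterman <- function(query, target, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(target))
  q <- strsplit(toupper(query), "")[[1]]
  t <- strsplit(toupper(target), "")[[1]]
  unknown <- setdiff(unique(c(q, t)), rownames(matrix))
  if (length(unknown)) {
    stop("Residue '", unknown[1], "' not covered by the substitution matrix")
  }
  m <- length(q); n <- length(t)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)       # best ending at (i,j)
  E <- matrix(NEG, m + 1, n + 1)     # gap in query (consuming target)
  Fm <- matrix(NEG, m + 1, n + 1)    # gap in target (consuming query)
  sub <- matrix[q, t, drop = FALSE]
  for (i in 1:m) {
    for (j in 1:n) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             E[i + 1, j] - gap_extend)
      Fm[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                              Fm[i, j + 1] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + sub[i, j],
                             E[i + 1, j + 1], Fm[i + 1, j + 1])
    }
  }
  best <- max(H)
  empty <- structure(list(score = 0, q_start = NA_integer_,
                          q_end = NA_integer_, t_start = NA_integer_,
                          t_end = NA_integer_, q_aln = "", t_aln = ""),
                     class = "alignment_hit")
  if (best <= 0) return(empty)
  # candidate endpoints, traceback each, pick by tie-break
  ends <- which(H == best, arr.ind = TRUE)
  cands <- list()
  for (r in seq_len(nrow(ends))) {
    i <- ends[r, 1] - 1; j <- ends[r, 2] - 1
    qa <- character(0); ta <- character(0)
    state <- "H"
    ii <- i; jj <- j
    repeat {
      if (state == "H") {
        h <- H[ii + 1, jj + 1]
        if (h == 0) break
        if (ii > 0 && jj > 0 && h == H[ii, jj] + sub[ii, jj]) {
          qa <- c(q[ii], qa); ta <- c(t[jj], ta); ii <- ii - 1; jj <- jj - 1
        } else if (h == E[ii + 1, jj + 1]) {
          state <- "E"
        } else {
          state <- "F"
        }
      } else if (state == "E") {
        qa <- c("-", qa); ta <- c(t[jj], ta)
        from_open <- H[ii + 1, jj] - gap_open - gap_extend
        e_here <- E[ii + 1, jj + 1]
        jj <- jj - 1
        state <- if (e_here == from_open) "H" else "E"
      } else {
        qa <- c(q[ii], qa); ta <- c("-", ta)
        from_open <- H[ii, jj + 1] - gap_open - gap_extend
        f_here <- Fm[ii + 1, jj + 1]
        ii <- ii - 1
        state <- if (f_here == from_open) "H" else "F"
      }
    }
    cands[[length(cands) + 1]] <- list(
      q_start = as.integer(ii + 1), q_end = as.integer(i),
      t_start = as.integer(jj + 1), t_end = as.integer(j),
      q_aln = paste0(qa, collapse = ""),
      t_aln = paste0(ta, collapse = ""), len = length(qa))
  }
  ord <- order(vapply(cands, `[[`, 0L, "t_start"),
               vapply(cands, `[[`, 0L, "q_start"),
               vapply(cands, `[[`, 0L, "len"))
  ch <- cands[[ord[1]]]
  structure(list(score = best, q_start = ch$q_start, q_end = ch$q_end,
                 t_start = ch$t_start, t_end = ch$t_end,
                 q_aln = ch$q_aln, t_aln = ch$t_aln),
            class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  if (x$score <= 0) {
    cat("No local alignment with positive score\n")
  } else {
    cat(sprintf("Local alignment, score %d\n  query  %d-%d  %s\n  target %d-%d  %s\n",
                x$score, x$q_start, x$q_end, x$q_aln,
                x$t_start, x$t_end, x$t_aln))
  }
  invisible(x)
}

#' Re-score an alignment hit from its aligned strings
#'
#' @param hit An `alignment_hit`.
#' @param matrix,gap_open,gap_extend As in [smith_waterman()].
#' @return Numeric score.
#' @export
rescore_alignment <- function(hit, matrix = blosum62(), gap_open = 11,
                              gap_extend = 1) {
  qa <- strsplit(hit$q_aln, "")[[1]]
  ta <- strsplit(hit$t_aln, "")[[1]]
  if (!length(qa)) return(0)
  score <- 0
  in_gap <- FALSE
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || ta[k] == "-") {
      score <- score - gap_extend - (!in_gap) * gap_open
      in_gap <- TRUE
    } else {
      score <- score + matrix[qa[k], ta[k]]
      in_gap <- FALSE
    }
  }
  score
}

#' Screen query peptides/precursors against an ORF set
#'
#' Desk-scale homology screen: each query is locally aligned against every
#' ORF protein; hits at or above `min_score` are reported, at most `top_k`
#' per query, sorted by (score desc, contig id, target start).
#'
#' @param queries Named character vector (or `contig_set` of protein
#'   records) of query sequences.
#' @param orfs Data.frame from [six_frame_orfs()] (any rows), with columns
#'   `contig_id` and `protein`.
#' @param min_score Minimum alignment score (recall-oriented low default).
#' @param top_k Maximum hits per query.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return Data.frame with columns `query_id`, `contig_id`, `orf_index`,
#'   `score`, `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
screen <- function(queries, orfs, min_score = 20, top_k = 25,
                   matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  stopifnot(min_score >= 0, top_k >= 1)
  if (is.list(queries) && !is.null(queries[[1]]$seq)) {
    queries <- setNames(vapply(queries, `[[`, "", "seq"),
                        vapply(queries, `[[`, "", "id"))
  }
  rows <- list()
  if (nrow(orfs)) {
    ord_orfs <- order(orfs$contig_id, orfs$nt_start %||% seq_len(nrow(orfs)))
    orfs <- orfs[ord_orfs, , drop = FALSE]
  }
  for (qi in seq_along(queries)) {
    qid <- names(queries)[[qi]]
    hits <- list()
    for (oi in seq_len(nrow(orfs))) {
      h <- smith_waterman(queries[[qi]], orfs$protein[[oi]], matrix,
                          gap_open, gap_extend)
      if (h$score >= min_score && h$score > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          query_id = qid, contig_id = orfs$contig_id[[oi]], orf_index = oi,
          score = h$score, q_start = h$q_start, q_end = h$q_end,
          t_start = h$t_start, t_end = h$t_end, stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) {
      tab <- do.call(rbind, hits)
      tab <- tab[order(-tab$score, tab$contig_id, tab$t_start), , drop = FALSE]
      rows[[length(rows) + 1]] <- head(tab, top_k)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), contig_id = character(0),
                      orf_index = integer(0), score = numeric(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
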