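# Kyte-Doolittle hydropathy scale.
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

.charge <- c(K = 1, R = 1, D = -1, E = -1)

#' Parameters for the built-in signal-peptide heuristic
#'
#' @param min_pos,max_pos Candidate cleavage window: the signal peptide's
#'   last residue is scanned over `[min_pos, max_pos]` (residues; defaults
#'   15-45, spanning the 16-44-residue signal peptides typical of secreted
#'   precursors).
#' @param hydropathy_threshold Minimum mean Kyte-Doolittle hydropathy of the
#'   hydrophobic core window (default 1.5).
#' @param h_window Length of the hydrophobic core window (default 7
#'   consecutive residues).
#' @param small_set Residues accepted at the -3 and -1 positions relative to
#'   cleavage (von Heijne small/neutral set).
#' @return A list of class `signal_params`.
#' @export
signal_params <- function(min_pos = 15, max_pos = 45,
                          hydropathy_threshold = 1.5, h_window = 7,
                          small_set = c("A", "G", "S", "C", "T", "V")) {
  structure(list(min_pos = min_pos, max_pos = max_pos,
                 hydropathy_threshold = hydropathy_threshold,
                 h_window = h_window, small_set = small_set),
            class = "signal_params")
}

#' Predict an N-terminal signal peptide (heuristic)
#'
#' A deterministic, rule-based stand-in for dedicated signal-peptide
#' predictors, capturing the classical tripartite architecture: a
#' non-negatively charged n-region, a hydrophobic h-region core, and small
#' residues at the -3 and -1 positions relative to the cleavage site.
#' Candidate cleavage positions within the window are scored as the mean
#' hydropathy of the best h-region window plus 1 per satisfied small-residue
#' position; the highest-scoring position passing all three rules is
#' returned, ties broken by the smallest position. Externally produced
#' predictions can be imported with [import_signal_table()] and take
#' precedence downstream.
#'
#' @param protein Amino-acid string.
#' @param params A [signal_params()] list.
#' @return A list of class `signal_prediction`: `present`, `cleave_after`
#'   (1-based index of the signal's last residue, or `NA`), `score`,
#'   `source = "heuristic"`, and `warning` (`TRUE` when the protein was too
#'   short to scan).
#' @export
predict_signal <- function(protein, params = signal_params()) {
  protein <- toupper(protein)
  n <- nchar(protein)
  none <- function(warn = FALSE) {
    structure(list(present = FALSE, cleave_after = NA_integer_, score = 0,
                   source = "heuristic", warning = warn),
              class = "signal_prediction")
  }
  if (n < 25) return(none(warn = TRUE))
  aa <- strsplit(protein, "")[[1]]
  hyd <- unname(.kd[aa]); hyd[is.na(hyd)] <- 0
  chg <- unname(.charge[aa]); chg[is.na(chg)] <- 0
  w <- params$h_window
  max_pos <- min(params$max_pos, n - 5)
  if (n <= 50) max_pos <- min(max_pos, n - 5)
  if (max_pos < params$min_pos) return(none())
  best <- NULL
  for (p in params$min_pos:max_pos) {
    # rule 3: small residues at -3 and -1 (residues p-2 and p)
    if (p - 2 < 1) next
    if (!(aa[p] %in% params$small_set) || !(aa[p - 2] %in% params$small_set)) next
    # rule 2: best h-window of w consecutive residues within 2..(p-1)
    win_starts <- 2:(p - w)
    if (length(win_starts) < 1 || p - w < 2) next
    means <- vapply(win_starts, function(s) mean(hyd[s:(s + w - 1)]), 0)
    if (max(means) < params$hydropathy_threshold) next
    h_start <- win_starts[which.max(means)]
    # rule 1: net charge of the n-region (residues before the h-region core)
    if (h_start > 1 && sum(chg[1:(h_start - 1)]) < 0) next
    score <- max(means) + 2  # both small-residue positions satisfied
    if (is.null(best) || score > best$score) {
      best <- list(pos = p, score = score)
    }
  }
  if (is.null(best)) return(none())
  structure(list(present = TRUE, cleave_after = best$pos, score = best$score,
                 source = "heuristic", warning = FALSE),
            class = "signal_prediction")
}

#' @export
print.signal_prediction <- function(x, ...) {
  if (x$present) {
    cat(sprintf("Signal peptide: residues 1-%d (score %.2f, %s)\n",
                x$cleave_after, x$score, x$source))
  } else {
    cat("Signal peptide: absent", if (isTRUE(x$warning)) " (sequence too short to scan)", "\n", sep = "")
  }
  invisible(x)
}

#' Import externally produced signal-peptide predictions
#'
#' Reads a TSV with columns `id`, `present`, `cleave_after` (e.g. exported
#' from a dedicated predictor). Imported entries carry `source = "imported"`
#' and override heuristic predictions downstream.
#'
#' @param path TSV file path.
#' @param protein_lengths Optional named integer vector of protein lengths;
#'   when given, `cleave_after` outside `[1, length)` is an error.
#' @return Named list mapping protein id to `signal_prediction`.
#' @export
import_signal_table <- function(path, protein_lengths = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "present", "cleave_after")
  if (!all(need %in% names(df))) {
    stop("Signal table must have columns: ", paste(need, collapse = ", "),
         " (missing: ", paste(setdiff(need, names(df)), collapse = ", "), ")")
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    pres <- df$present[[i]]
    if (is.character(pres)) pres <- tolower(pres) %in% c("true", "t", "1", "yes")
    pres <- isTRUE(as.logical(pres))
    ca <- df$cleave_after[[i]]
    if (pres) {
      ca_num <- suppressWarnings(as.integer(ca))
      if (is.na(ca_num)) {
        stop("Row ", i, ": cleave_after '", ca, "' is not an integer")
      }
      id <- df$id[[i]]
      if (!is.null(protein_lengths) && id %in% names(protein_lengths)) {
        if (ca_num < 1 || ca_num >= protein_lengths[[id]]) {
          stop("Row ", i, ": cleave_after ", ca_num,
               " outside [1, protein length) for '", id, "'")
        }
      }
      ca <- ca_num
    } else {
      ca <- NA_integer_
    }
    out[[df$id[[i]]]] <- structure(
      list(present = pres, cleave_after = ca, score = NA_real_,
           source = "imported", warning = FALSE),
      class = "signal_prediction")
  }
  out
}
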