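# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, alphabet = AA20) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# --- independent six-frame ORF enumerator (brute force over frames) -------
# Translates with Biostrings and enumerates stop-delimited segments by
# string splitting; reports the first-M ORF per segment, complete ORFs only.
oracle_orfs <- function(seq, min_len) {
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") seq else revcomp_chr(seq)
    for (frame in 0:2) {
      nc <- (L - frame) %/% 3
      if (nc < 1) next
      aa <- vapply(seq_len(nc), function(k) {
        cod <- substr(rs, frame + 3 * k - 2, frame + 3 * k)
        if (grepl("[^ACGT]", cod)) "X" else unname(gc[[cod]])
      }, "")
      prot <- paste0(aa, collapse = "")
      # stop positions delimit segments; a complete ORF needs a trailing stop
      stops <- c(0, which(aa == "*"))
      for (si in seq_along(stops)[-length(stops)]) {
        lo <- stops[si] + 1; hi <- stops[si + 1] - 1
        if (hi < lo) next
        seg <- aa[lo:hi]
        mpos <- which(seg == "M")
        if (!length(mpos)) next
        p <- paste0(seg[mpos[1]:length(seg)], collapse = "")
        if (nchar(p) < min_len) next
        a <- lo + mpos[1] - 1   # codon index of the M
        r_start <- frame + (a - 1) * 3
        r_end <- frame + hi * 3
        coords <- if (strand == "+") c(r_start, r_end) else
          c(L - r_end, L - r_start)
        out[[length(out) + 1]] <- sprintf("%s|%d|%d|%d|%s", strand, frame,
                                          coords[1], coords[2], p)
      }
    }
  }
  sort(as.character(unlist(out)))
}

orf_keys <- function(df) {
  sort(sprintf("%s|%d|%d|%d|%s", df$strand, df$frame, df$nt_start,
               df$nt_end, df$protein))
}

# --- brute-force local aligner over matched-pair sets ----------------------
# Scores every monotone set of aligned residue pairs; between consecutive
# pairs the unaligned residues of each sequence form one affine gap run
# (splitting a run can only add gap-open cost, so this covers the optimum).
oracle_local_score <- function(q, t, mat, open = 11, ext = 1) {
  qs <- strsplit(q, "")[[1]]; ts <- strsplit(t, "")[[1]]
  m <- length(qs); n <- length(ts)
  gapc <- function(k) ifelse(k <= 0, 0, open + ext * k)
  f <- matrix(-Inf, m, n)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- mat[qs[i], ts[j]]
      b <- s
      if (i > 1 && j > 1) {
        prev <- f[1:(i - 1), 1:(j - 1), drop = FALSE]
        gq <- gapc((i - 1:(i - 1)) - 1)           # query gap runs
        gt <- gapc((j - 1:(j - 1)) - 1)           # target gap runs
        pen <- outer(gq, gt, `+`)
        b <- max(b, max(prev - pen) + s)
      }
      f[i, j] <- b
      if (b > best) best <- b
    }
  }
  best
}

# --- independent regexes for the built-in family registry -----------------
oracle_family_match <- function(p) {
  s <- p$seq
  amide <- isTRUE(p$cterm_amide)
  ncys_first10 <- sum(p$cys_positions <= 10)
  hits <- character(0)
  if (amide && grepl("[ST].L.[FY]$", s)) hits <- c(hits, "SALMFamide-L")
  if (amide && grepl("[FY].[FY]$", s)) hits <- c(hits, "SALMFamide-F")
  if (amide && grepl("N..S..L.F$", s)) hits <- c(hits, "kisspeptin")
  if (amide && grepl("G[AVLIMFWY]F$", s)) hits <- c(hits, "tachykinin")
  if (amide && grepl("KFMRW$", s)) hits <- c(hits, "luqin")
  if (amide && grepl("[DQ]YG.GLF[WF]$", s)) hits <- c(hits, "CCK-type")
  if (amide && grepl("W..G$", s)) hits <- c(hits, "GnRH-type")
  if (amide && isTRUE(p$nterm_pyroglu) && nchar(s) == 4 && grepl("^Q", s)) {
    hits <- c(hits, "TRH-type")
  }
  if (amide && nchar(s) == 9 && identical(as.integer(p$cys_positions),
                                          c(1L, 6L)) &&
      grepl("^C....C", s)) hits <- c(hits, "VP/OT-type")
  if (amide && nchar(s) >= 10 && nchar(s) <= 50 && ncys_first10 >= 2) {
    hits <- c(hits, "calcitonin-type")
  }
  if (grepl("CC.{3}C.{8}C$", s)) hits <- c(hits, "insulin-A-chain")
  if (grepl("^.{0,12}C.{11}C", s)) hits <- c(hits, "insulin-B-chain")
  if (grepl("^.{0,20}R.{3}R.{2}[IV]", s)) hits <- c(hits, "relaxin-RBM")
  if (grepl("^AN", s)) hits <- c(hits, "AN-peptide")
  hits
}

# random mature-peptide object with independent maturation state
random_mature_peptide <- function(len = sample(3:14, 1)) {
  s <- random_protein(len)
  structure(list(seq = s, precursor_coords = c(1, len),
                 cterm_amide = sample(c(TRUE, FALSE), 1),
                 nterm_pyroglu = substr(s, 1, 1) == "Q" &&
                   sample(c(TRUE, FALSE), 1),
                 cys_positions = which(strsplit(s, "")[[1]] == "C"),
                 max_disulfides = sum(strsplit(s, "")[[1]] == "C") %/% 2,
                 sulfation_candidates = integer(0), copy_id = 1L),
            class = "mature_peptide")
}

# cleavage-site oracle: K/R runs by regex, split by pure arithmetic
oracle_sites <- function(protein, signal_end, monobasic = FALSE,
                         pairs = c("KR", "RR", "KK", "RK")) {
  tail_seq <- substr(protein, signal_end + 1, nchar(protein))
  mm <- gregexpr("[KR]+", tail_seq)[[1]]
  keys <- character(0)
  aa <- strsplit(protein, "")[[1]]
  if (mm[1] != -1) {
    for (k in seq_along(mm)) {
      run_start <- signal_end + mm[k]
      run_len <- attr(mm, "match.length")[k]
      s <- run_start
      remaining <- run_len
      while (remaining > 0) {
        if (remaining >= 3) {
          keys <- c(keys, paste(s, s + 2, "tribasic", sep = ":"))
          s <- s + 3; remaining <- remaining - 3
        } else if (remaining == 2) {
          motif <- paste0(aa[s:(s + 1)], collapse = "")
          if (motif %in% pairs) {
            keys <- c(keys, paste(s, s + 1, "dibasic", sep = ":"))
          }
          s <- s + 2; remaining <- 0
        } else {
          if (monobasic && aa[s] == "R") {
            ups <- s - c(2, 4, 6)
            ups <- ups[ups > signal_end]
            if (length(ups) && any(aa[ups] %in% c("K", "R"))) {
              keys <- c(keys, paste(s, s, "monobasic", sep = ":"))
            }
          }
          remaining <- 0
        }
      }
    }
  }
  sort(keys)
}

site_keys_of <- function(sites) {
  sort(vapply(sites, function(s) paste(s$start, s$end, s$kind, sep = ":"), ""))
}
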