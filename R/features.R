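# Hydropathy-window heuristics and PROSITE motif matching. These replace the
# external signal-peptide / transmembrane predictors with fixed, documented
# approximations: an N-terminal hydrophobic window stands in for a signal
# peptide and a long hydrophobic window near the C terminus for a C-terminal
# transmembrane (CTM) stretch.

KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

kd_values <- function(seq) {
  res <- strsplit(toupper(seq), "")[[1]]
  v <- KD_SCALE[res]
  if (anyNA(v)) abort("sequence contains residues outside the amino-acid alphabet")
  unname(v)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean hydropathy; windows at the ends are truncated to the
#' part that fits inside the sequence.
#'
#' @param seq Protein string.
#' @param window Odd window width, at most the sequence length.
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(seq, window = 9L) {
  v <- kd_values(seq)
  n <- length(v)
  if (window %% 2L == 0L) abort("window must be odd")
  if (window > n) abort("window exceeds sequence length")
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

best_window <- function(v, width, starts) {
  cs <- c(0, cumsum(v))
  means <- (cs[starts + width] - cs[starts]) / width
  k <- which.max(means)
  list(start = starts[k], end = starts[k] + width - 1L, mean = means[k])
}

#' Predict an N-terminal signal peptide
#'
#' Present iff some 8-residue window fully inside residues 1-40 has mean
#' Kyte-Doolittle hydropathy >= `threshold`; the reported span is the
#' best-scoring such window.
#'
#' @param seq Protein string of length >= 25.
#' @param threshold Mean-hydropathy cutoff (default 1.5).
#' @return List with `present`, `start`, `end`, `score`.
#' @export
predict_signal_peptide <- function(seq, threshold = 1.5) {
  v <- kd_values(seq)
  if (length(v) < 25L) abort("sequence shorter than 25 residues")
  starts <- seq_len(min(40L, length(v)) - 7L)
  w <- best_window(v, 8L, starts)
  list(present = w$mean >= threshold, start = w$start, end = w$end,
       score = w$mean)
}

#' Predict a C-terminal transmembrane stretch
#'
#' Present iff some 19-residue window whose start lies within the final 80
#' residues has mean Kyte-Doolittle hydropathy >= `threshold`; the reported
#' span is the highest-scoring window.
#'
#' @param seq Protein string of length >= 60.
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @return List with `present`, `start`, `end`, `score`.
#' @export
predict_ctm <- function(seq, threshold = 1.6) {
  v <- kd_values(seq)
  n <- length(v)
  if (n < 60L) abort("sequence shorter than 60 residues")
  starts <- seq(max(1L, n - 79L), n - 18L)
  w <- best_window(v, 19L, starts)
  list(present = w$mean >= threshold, start = w$start, end = w$end,
       score = w$mean)
}

#' PROSITE pattern for the eukaryotic aspartyl protease active site (PS00141)
#' @export
PS00141 <- "[LIVMFGAC]-[LIVMTADN]-[LIVFSA]-D-[ST]-G-[STAV]-[STAPDENQ]-x-[LIVMFSTNC]-x-[LIVMFGTA]"

#' Convert a PROSITE-syntax pattern to a regular expression
#'
#' Supports residue classes `[..]`, exclusions `{..}`, wildcards `x`,
#' repetition `(n)`/`(n,m)` and the `<`/`>` anchors.
#'
#' @param pattern PROSITE pattern string.
#' @return A regular expression string.
#' @export
prosite_to_regex <- function(pattern) {
  pattern <- gsub("\\.$", "", trimws(pattern))
  elements <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(elements)) abort("empty PROSITE pattern")
  out <- vapply(elements, function(el) {
    anchor_l <- grepl("^<", el); anchor_r <- grepl(">$", el)
    el <- sub("^<", "", sub(">$", "", el))
    rep <- ""
    m <- regmatches(el, regexpr("\\((\\d+)(,\\d+)?\\)$", el))
    if (length(m) && nzchar(m)) {
      rep <- sub("\\((.*)\\)", "{\\1}", m)
      el <- sub("\\(.*\\)$", "", el)
    }
    core <- if (el == "x") "."
    else if (grepl("^\\[[A-Z]+\\]$", el)) el
    else if (grepl("^\\{[A-Z]+\\}$", el)) paste0("[^", substr(el, 2, nchar(el) - 1), "]")
    else if (grepl("^[A-Z]$", el)) el
    else abort(sprintf("malformed PROSITE element '%s'", el))
    paste0(if (anchor_l) "^", core, rep, if (anchor_r) "$")
  }, character(1))
  paste(out, collapse = "")
}

#' Find aspartyl-protease active-site motifs
#'
#' All non-overlapping, leftmost-first matches of a PROSITE pattern (default
#' PS00141); each hit reports the 1-based match start and the position of the
#' aspartate of the D-\[ST\]-G core.
#'
#' @param seq Protein string.
#' @param pattern PROSITE-syntax pattern.
#' @return Tibble with columns `start`, `end`, `match`, `asp_pos`.
#' @export
find_active_site_motifs <- function(seq, pattern = PS00141) {
  rx <- prosite_to_regex(pattern)
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(), end = integer(),
                  match = character(), asp_pos = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  hits <- substring(seq, starts, starts + lens - 1L)
  asp <- vapply(hits, function(h) {
    k <- regexpr("D[ST]G", h)[1]
    if (k == -1L) NA_integer_ else as.integer(k)
  }, integer(1))
  tibble(start = starts, end = starts + lens - 1L, match = unname(hits),
         asp_pos = starts + unname(asp) - 1L)
}
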