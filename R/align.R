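# Local alignment evidence: Smith-Waterman with affine gaps (BLOSUM62,
# BLASTP-like open/extend costs) via Biostrings, summarised into the
# identity/coverage/gap numbers the triage thresholds are calibrated on.
# E-values are deliberately not computed.

blosum62 <- function() {
  if (is.null(codon_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    codon_env$blosum62 <- e$BLOSUM62
  }
  codon_env$blosum62
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). Identity is computed over all alignment
#' columns, gap columns included in the denominator.
#'
#' @param a,b Protein strings (nonempty).
#' @param substitution_matrix Scoring matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap costs (defaults 11 and 1,
#'   BLASTP-like).
#' @return One-row tibble: `score`, `identity_pct`, `aligned_length`,
#'   `gap_pct`, `query_start`, `query_end`, `subject_start`, `subject_end`.
#' @export
local_align <- function(a, b, substitution_matrix = NULL,
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  sm <- if (is.null(substitution_matrix)) blosum62() else substitution_matrix
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(p)
  if (len == 0L) {
    return(tibble(score = 0, identity_pct = 0, aligned_length = 0L,
                  gap_pct = 0, query_start = NA_integer_,
                  query_end = NA_integer_, subject_start = NA_integer_,
                  subject_end = NA_integer_))
  }
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  gapcol <- pc == "-" | sc == "-"
  ident <- sum(pc == sc & !gapcol)
  tibble(score = Biostrings::score(aln),
         identity_pct = 100 * ident / len,
         aligned_length = len,
         gap_pct = 100 * sum(gapcol) / len,
         query_start = Biostrings::start(Biostrings::pattern(aln)),
         query_end = Biostrings::end(Biostrings::pattern(aln)),
         subject_start = Biostrings::start(Biostrings::subject(aln)),
         subject_end = Biostrings::end(Biostrings::subject(aln)))
}

# fraction of the shorter of the two sequences covered by the local alignment
alignment_coverage <- function(res, len_a, len_b) {
  if (is.na(res$query_start)) return(0)
  if (len_a <= len_b) (res$query_end - res$query_start + 1L) / len_a
  else (res$subject_end - res$subject_start + 1L) / len_b
}

#' Best hit of a query in a database, with reciprocal check
#'
#' The best forward hit is the database entry with the highest local-alignment
#' score (ties broken by identity, then lexicographic id). The reciprocal flag
#' is true iff aligning that hit against the query's home set returns the
#' query as top score.
#'
#' @param query Single named protein (length-1 named character vector, or
#'   unnamed with `query_id`).
#' @param db Named character vector of protein sequences.
#' @param home_db Named character vector containing the query (defaults to the
#'   query alone, which makes the reciprocal check trivially true).
#' @param query_id Id of the query within `home_db`.
#' @param ... Passed to [local_align()].
#' @return List: `best_id`, `score`, `identity_pct`, `reciprocal`.
#' @export
reciprocal_best_hit <- function(query, db, home_db = NULL, query_id = NULL,
                                ...) {
  db <- as_seq_vector(db)
  if (!length(db)) abort("empty database")
  qseq <- if (is.character(query) && length(query) == 1L) unname(query)
          else abort("query must be a single sequence string")
  if (is.null(query_id)) query_id <- names(query) %||% "query"
  hits <- best_hit(qseq, db, ...)
  if (is.null(home_db)) home_db <- setNames(qseq, query_id)
  home_db <- as_seq_vector(home_db)
  back <- best_hit(db[[hits$best_id]], home_db, ...)
  list(best_id = hits$best_id, score = hits$score,
       identity_pct = hits$identity_pct,
       reciprocal = identical(back$best_id, query_id))
}

best_hit <- function(qseq, db, ...) {
  res <- lapply(names(db), function(id) {
    r <- local_align(qseq, db[[id]], ...)
    tibble(id = id, score = r$score, identity_pct = r$identity_pct)
  })
  res <- bind_rows(res)
  res <- res[order(-res$score, -res$identity_pct, res$id), ]
  list(best_id = res$id[1], score = res$score[1],
       identity_pct = res$identity_pct[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
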