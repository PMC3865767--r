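# Conserved ungapped block extraction from a protein alignment, with
# per-column information content in bits (sequence-logo semantics).
# Deterministic column scoring stands in for Gibbs-sampling block finders:
# rows that are mostly gaps are dropped first (the "very divergent sequences
# are excluded" behaviour), then maximal runs of gap-free, high-information
# columns become blocks.

#' Information content of an alignment column
#'
#' `IC = log2(20) - H` with `H` the Shannon entropy of the observed residue
#' frequencies (gaps excluded). The optional small-sample correction subtracts
#' `19 / (2 ln 2 n)` and floors at zero.
#'
#' @param residues Character vector of residues in the column.
#' @param correction `"none"` or `"small-sample"`.
#' @return Information content in bits.
#' @export
column_information <- function(residues, correction = c("none", "small-sample")) {
  correction <- match.arg(correction)
  residues <- residues[residues != "-"]
  n <- length(residues)
  if (n == 0L) abort("empty column")
  f <- table(residues) / n
  h <- -sum(f * log2(f))
  ic <- log2(20) - h
  if (correction == "small-sample") ic <- ic - 19 / (2 * log(2) * n)
  max(ic, 0)
}

#' Extract conserved ungapped blocks from a protein alignment
#'
#' Rows with more than `max_gap_rows_frac` gaps are dropped; a column is
#' eligible iff it has no gap among the retained rows and information content
#' of at least `min_mean_ic` bits; maximal runs of eligible columns at least
#' `min_width` wide become blocks, reported N-terminal to C-terminal with the
#' spacing to the previous block.
#'
#' @param msa A protein [aligned_set()].
#' @param min_width Minimum block width (>= 3; default 6).
#' @param min_mean_ic Per-column information threshold in bits (default 2).
#' @param max_gap_rows_frac Maximum tolerated gap fraction per row (default
#'   0.5).
#' @param correction Passed to [column_information()].
#' @return Tibble with `block`, `start_col`, `end_col`, `width`, `mean_ic`,
#'   `spacing`; attributes `rows` (retained row ids) and `column_ic`.
#' @export
find_blocks <- function(msa, min_width = 6L, min_mean_ic = 2.0,
                        max_gap_rows_frac = 0.5, correction = "none") {
  if (min_width < 3L) abort("min_width must be >= 3")
  m <- aln_matrix(msa)
  gap_frac <- rowMeans(m == "-")
  retained <- rownames(m)[gap_frac <= max_gap_rows_frac]
  if (!length(retained)) abort("no rows retained after the gap filter")
  m <- m[retained, , drop = FALSE]
  ic <- apply(m, 2L, function(col) {
    if (all(col == "-")) 0 else column_information(col, correction)
  })
  eligible <- colSums(m == "-") == 0L & ic >= min_mean_ic
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width
  out <- tibble(start_col = starts[keep], end_col = ends[keep])
  out <- mutate(out,
                block = dplyr::row_number(),
                width = .data$end_col - .data$start_col + 1L,
                mean_ic = map_dbl(seq_len(nrow(out)), function(k) {
                  mean(ic[out$start_col[k]:out$end_col[k]])
                }),
                spacing = .data$start_col - dplyr::lag(.data$end_col) - 1L)
  out <- select(out, "block", "start_col", "end_col", "width", "mean_ic",
                "spacing")
  attr(out, "rows") <- retained
  attr(out, "column_ic") <- ic
  out
}

#' Per-position letter heights of a block (logo table)
#'
#' For each column of the block, every observed residue gets height
#' `f_a * IC`, so the column sums equal the column information content.
#'
#' @param msa The protein [aligned_set()] the blocks were extracted from.
#' @param start_col,end_col Block bounds (1-based alignment columns).
#' @param rows Row ids to use (defaults to all rows; pass `attr(blocks,
#'   "rows")` for consistency with [find_blocks()]).
#' @param correction Passed to [column_information()].
#' @return Tibble with `pos` (alignment column), `residue`, `freq`, `height`.
#' @export
logo_table <- function(msa, start_col, end_col, rows = NULL,
                       correction = "none") {
  m <- aln_matrix(msa)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (end_col > ncol(m) || start_col < 1L || start_col > end_col) {
    abort("invalid block bounds")
  }
  out <- lapply(start_col:end_col, function(cc) {
    col <- m[, cc]
    col <- col[col != "-"]
    ic <- column_information(col, correction)
    f <- table(col) / length(col)
    tibble(pos = cc, residue = names(f), freq = as.numeric(f),
           height = as.numeric(f) * ic)
  })
  bind_rows(out)
}

#' Plot block positions and column information along an alignment
#'
#' @param blocks Output of [find_blocks()].
#' @return A ggplot object.
#' @export
plot_blocks <- function(blocks) {
  ic <- attr(blocks, "column_ic")
  prof <- tibble(col = seq_along(ic), ic = ic)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$col, y = .data$ic)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_rect(
      data = blocks, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_col - 0.5, xmax = .data$end_col + 0.5,
                   ymin = 0, ymax = log2(20)),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::labs(x = "alignment column", y = "information (bits)") +
    ggplot2::theme_minimal()
}
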