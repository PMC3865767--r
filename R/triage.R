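# The homolog triage checklist: alignment evidence against BACE and cathepsin
# references, architecture features (signal peptide, CTM), active-site motif
# count and a reciprocal-best-hit check, combined into a three-way label.

#' Triage thresholds
#'
#' Defaults follow the published checklist: matches of ~35% identity or more
#' across the major part of the ORF without over-gapping, ~100 residues longer
#' than cathepsin homologs, signal peptide and CTM present, and a single
#' proximal PS00141 match for BACE1-like sequences versus two for
#' cathepsin-like ones. The exon-count criterion (>= 9) is metadata-only and
#' never computed from sequence.
#'
#' @param min_identity_pct Minimum identity to the BACE reference (default 35).
#' @param min_coverage_frac Minimum fraction of the shorter ORF covered by the
#'   alignment (default 0.7).
#' @param max_gap_pct Maximum percentage of gap columns (default 15).
#' @param min_length_delta Minimum length excess over the median cathepsin
#'   reference length (default 60 residues).
#' @param expected_motif_count_bace Expected number of full PS00141 matches
#'   for a BACE-like sequence (default 1, the proximal match).
#' @param expected_motif_count_cathepsin Expected count for cathepsin-like
#'   sequences (default 2); reported, not used in the label.
#' @param proximal_frac A motif is "proximal" when its start lies within this
#'   fraction of the sequence length (default 0.4).
#' @param min_exons Metadata-only exon-count criterion (default 9).
#' @return A `triage_criteria` list.
#' @export
triage_criteria <- function(min_identity_pct = 35, min_coverage_frac = 0.7,
                            max_gap_pct = 15, min_length_delta = 60,
                            expected_motif_count_bace = 1L,
                            expected_motif_count_cathepsin = 2L,
                            proximal_frac = 0.4, min_exons = 9L) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            min_coverage_frac >= 0, min_coverage_frac <= 1,
            max_gap_pct >= 0, max_gap_pct <= 100, min_length_delta >= 0)
  structure(list(min_identity_pct = min_identity_pct,
                 min_coverage_frac = min_coverage_frac,
                 max_gap_pct = max_gap_pct,
                 min_length_delta = min_length_delta,
                 expected_motif_count_bace = expected_motif_count_bace,
                 expected_motif_count_cathepsin = expected_motif_count_cathepsin,
                 proximal_frac = proximal_frac, min_exons = min_exons),
            class = "triage_criteria")
}

#' Classify candidate sequences as BACE-like, borderline or cathepsin-like
#'
#' Evaluates, per candidate: (1) reciprocal best hit into the BACE reference
#' set; (2) identity/coverage/gap thresholds against the best BACE reference;
#' (3) identity to cathepsins strictly lower than to BACE; (4) length excess
#' over the median cathepsin length; (5) signal peptide; (6) CTM; (7) full
#' PS00141 motif count matching the BACE expectation, with the proximal-match
#' requirement. Criteria 1, 2 and 6 are mandatory: all seven true gives
#' `bace-like`, mandatory true with any corroborative criterion unmet gives
#' `borderline`, a failed mandatory criterion gives `cathepsin-like`.
#' A feature that cannot be evaluated (sequence too short) counts as unmet.
#'
#' @param candidates Named character vector or tibble (`id`, `seq`) of
#'   candidate proteins.
#' @param bace_refs,cathepsin_refs Reference sequences (named vector/tibble).
#' @param criteria A [triage_criteria()] object.
#' @param metadata Optional tibble with `id` and `n_exons`; adds an
#'   `exons_ok` column (metadata-only, never part of the label).
#' @return Tibble, one row per candidate, with the label, all per-criterion
#'   booleans and the supporting numbers.
#' @export
triage_classify <- function(candidates, bace_refs, cathepsin_refs,
                            criteria = triage_criteria(), metadata = NULL) {
  candidates <- as_seq_vector(candidates)
  bace_refs <- as_seq_vector(bace_refs)
  cathepsin_refs <- as_seq_vector(cathepsin_refs)
  if (!length(bace_refs) || !length(cathepsin_refs)) {
    abort("reference sets must be nonempty")
  }
  cath_median_len <- median(nchar(cathepsin_refs))
  all_refs <- c(bace_refs, cathepsin_refs)

  rows <- lapply(names(candidates), function(id) {
    seq <- candidates[[id]]
    to_bace <- bind_rows(lapply(names(bace_refs), function(r) {
      res <- local_align(seq, bace_refs[[r]])
      mutate(res, ref = r,
             coverage = alignment_coverage(res, nchar(seq), nchar(bace_refs[[r]])))
    }))
    best <- to_bace[order(-to_bace$score), ][1, ]
    to_cath <- max(vapply(cathepsin_refs, function(s) {
      local_align(seq, s)$identity_pct
    }, numeric(1)))

    rbh <- reciprocal_best_hit(setNames(seq, id), all_refs,
                               home_db = c(setNames(seq, id), cathepsin_refs),
                               query_id = id)
    sp <- tryCatch(predict_signal_peptide(seq),
                   error = function(e) list(present = FALSE))
    ctm <- tryCatch(predict_ctm(seq), error = function(e) list(present = FALSE))
    hits <- find_active_site_motifs(seq)
    proximal <- nrow(hits) > 0L &&
      hits$start[1] <= criteria$proximal_frac * nchar(seq)
    length_delta <- nchar(seq) - cath_median_len

    crit <- c(
      rbh_bace = rbh$best_id %in% names(bace_refs) && rbh$reciprocal,
      identity_ok = best$identity_pct >= criteria$min_identity_pct &&
        best$coverage >= criteria$min_coverage_frac &&
        best$gap_pct <= criteria$max_gap_pct,
      closer_to_bace = best$identity_pct > to_cath,
      length_ok = length_delta >= criteria$min_length_delta,
      sp_ok = isTRUE(sp$present),
      ctm_ok = isTRUE(ctm$present),
      motif_ok = nrow(hits) == criteria$expected_motif_count_bace && proximal)
    mandatory <- crit[c("rbh_bace", "identity_ok", "ctm_ok")]
    label <- if (all(crit)) "bace-like"
             else if (all(mandatory)) "borderline"
             else "cathepsin-like"
    tibble(id = id, label = label, !!!as.list(crit),
           identity_pct = best$identity_pct, coverage = best$coverage,
           gap_pct = best$gap_pct, identity_to_cathepsin = to_cath,
           length = nchar(seq), length_delta = length_delta,
           motif_count = nrow(hits), rbh_hit = rbh$best_id)
  })
  out <- bind_rows(rows)
  if (!is.null(metadata)) {
    md <- as_tibble(metadata)[c("id", "n_exons")]
    out <- left_join(out, md, by = "id")
    out$exons_ok <- out$n_exons >= criteria$min_exons
  }
  out
}

#' Substrate presence/absence across proteomes
#'
#' A substrate is called present in a proteome iff its reciprocal-best-hit
#' local alignment meets both the identity and the coverage threshold
#' (coverage measured on the substrate).
#'
#' @param substrates Named character vector/tibble of substrate proteins.
#' @param proteomes Named list of proteomes (each a named character
#'   vector/tibble of proteins).
#' @param min_identity_pct Identity threshold (default 25).
#' @param min_coverage_frac Substrate-coverage threshold (default 0.5).
#' @return Tibble with one row per proteome x substrate: `present` plus the
#'   supporting numbers.
#' @export
presence_absence <- function(substrates, proteomes, min_identity_pct = 25,
                             min_coverage_frac = 0.5) {
  substrates <- as_seq_vector(substrates)
  if (!length(substrates) || !length(proteomes)) abort("empty input")
  rows <- list()
  for (pn in names(proteomes)) {
    prot <- as_seq_vector(proteomes[[pn]])
    for (sn in names(substrates)) {
      sseq <- substrates[[sn]]
      if (!length(prot)) {
        rows[[length(rows) + 1L]] <- tibble(
          proteome = pn, substrate = sn, present = FALSE,
          best_hit = NA_character_, identity_pct = 0, coverage = 0,
          reciprocal = FALSE)
        next
      }
      rbh <- reciprocal_best_hit(setNames(sseq, sn), prot,
                                 home_db = substrates, query_id = sn)
      res <- local_align(sseq, prot[[rbh$best_id]])
      cov <- if (is.na(res$query_start)) 0 else
        (res$query_end - res$query_start + 1L) / nchar(sseq)
      rows[[length(rows) + 1L]] <- tibble(
        proteome = pn, substrate = sn,
        present = rbh$reciprocal && res$identity_pct >= min_identity_pct &&
          cov >= min_coverage_frac,
        best_hit = rbh$best_id, identity_pct = res$identity_pct,
        coverage = cov, reciprocal = rbh$reciprocal)
    }
  }
  bind_rows(rows)
}
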