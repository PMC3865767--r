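# Paired-ortholog rate asymmetry between two paralog clades: for every pair
# of species present in both clades, the within-clade distance is compared
# between clade A and clade B. The headline statistic is the arithmetic mean
# of the per-pair d_B/d_A ratios (the ratio of the two mean distances is also
# reported), with direction counts and an exact two-sided sign test.

#' Species present in both paralog clades
#'
#' @param clades A [clade_table()] tibble (`id`, `clade`, `species`), clades
#'   labelled `"A"` and `"B"`.
#' @param exclude Ids to drop before matching (e.g. lineage-specific extra
#'   paralogs).
#' @return Sorted character vector of species with one sequence in each clade.
#' @export
match_species <- function(clades, exclude = character(0)) {
  clades <- clade_table(clades)
  clades <- clades[!clades$id %in% exclude, ]
  sp_a <- clades$species[clades$clade == "A"]
  sp_b <- clades$species[clades$clade == "B"]
  common <- sort(intersect(sp_a, sp_b))
  if (length(common) < 3L) abort("fewer than 3 species common to both clades")
  common
}

#' Per-species-pair distance comparison between clades
#'
#' For each unordered pair of matched species, looks up the within-clade
#' distances `d_A` and `d_B` in the distance matrix and records their ratio
#' and direction.
#'
#' @param dm Distance matrix with sequence ids as labels.
#' @param clades A [clade_table()] tibble.
#' @param exclude Ids to drop before matching.
#' @param tie_epsilon Distances within this of each other count as ties
#'   (default `1e-12`, exact ties only).
#' @return Tibble with `species_i`, `species_j`, `d_a`, `d_b`, `ratio`,
#'   `direction`.
#' @export
pair_table <- function(dm, clades, exclude = character(0),
                       tie_epsilon = 1e-12) {
  clades <- clade_table(clades)
  clades <- clades[!clades$id %in% exclude, ]
  common <- match_species(clades, exclude = character(0))
  id_of <- function(sp, cl) clades$id[clades$species == sp & clades$clade == cl]
  labs <- rownames(dm)
  need <- unlist(lapply(common, function(sp) c(id_of(sp, "A"), id_of(sp, "B"))))
  missing <- setdiff(need, labs)
  if (length(missing)) {
    abort(paste0("ids missing from distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  pairs <- utils::combn(common, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    si <- pairs[1, k]; sj <- pairs[2, k]
    d_a <- dm[id_of(si, "A"), id_of(sj, "A")]
    d_b <- dm[id_of(si, "B"), id_of(sj, "B")]
    tibble(species_i = si, species_j = sj, d_a = d_a, d_b = d_b,
           ratio = if (d_a > 0) d_b / d_a else NA_real_,
           direction = if (abs(d_b - d_a) <= tie_epsilon) "tie"
                       else if (d_b > d_a) "B>A" else "A>B")
  })
  bind_rows(rows)
}

#' Summarise paralog rate asymmetry
#'
#' @param pairs Tibble from [pair_table()].
#' @param tie_epsilon Tie tolerance used when `pairs` lacks a `direction`
#'   column.
#' @return An `asymmetry_summary` object: mean within-clade distances, the
#'   mean per-pair `d_B/d_A` ratio (and the ratio of means), direction counts
#'   and an exact two-sided sign test on the non-tie pairs. The sign test is
#'   an added inferential layer over the direction counts.
#' @export
asymmetry_summary <- function(pairs, tie_epsilon = 1e-12) {
  if (nrow(pairs) < 1L) abort("need at least one species pair")
  if (!"direction" %in% names(pairs)) {
    pairs$direction <- ifelse(abs(pairs$d_b - pairs$d_a) <= tie_epsilon, "tie",
                              ifelse(pairs$d_b > pairs$d_a, "B>A", "A>B"))
  }
  n_b <- sum(pairs$direction == "B>A")
  n_a <- sum(pairs$direction == "A>B")
  n_tie <- sum(pairs$direction == "tie")
  informative <- n_a + n_b
  p <- if (informative == 0L) 1 else {
    binom.test(n_b, informative, p = 0.5, alternative = "two.sided")$p.value
  }
  ratios <- pairs$ratio[pairs$d_a > 0]
  out <- list(
    n_pairs = nrow(pairs),
    mean_d_a = mean(pairs$d_a), mean_d_b = mean(pairs$d_b),
    mean_ratio = if (length(ratios)) mean(ratios) else NA_real_,
    ratio_of_means = if (mean(pairs$d_a) > 0) {
      mean(pairs$d_b) / mean(pairs$d_a)
    } else NA_real_,
    n_ratio_defined = length(ratios),
    n_b_greater = n_b, n_a_greater = n_a, n_ties = n_tie,
    sign_test_p = p, n_informative = informative,
    pairs = pairs)
  structure(out, class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Paralog rate asymmetry over %d species pairs\n",
           "  mean d(A) = %.4g, mean d(B) = %.4g\n",
           "  mean per-pair B/A ratio = %.4g (ratio of means %.4g)\n",
           "  direction: B>A %d, A>B %d, ties %d; sign test p = %.3g\n"),
    x$n_pairs, x$mean_d_a, x$mean_d_b, x$mean_ratio, x$ratio_of_means,
    x$n_b_greater, x$n_a_greater, x$n_ties, x$sign_test_p))
  invisible(x)
}

#' @method tidy asymmetry_summary
#' @export
tidy.asymmetry_summary <- function(x, ...) as_tibble(x$pairs)

#' @method glance asymmetry_summary
#' @export
glance.asymmetry_summary <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, mean_d_a = x$mean_d_a, mean_d_b = x$mean_d_b,
         mean_ratio = x$mean_ratio, ratio_of_means = x$ratio_of_means,
         n_b_greater = x$n_b_greater, n_a_greater = x$n_a_greater,
         n_ties = x$n_ties, sign_test_p = x$sign_test_p)
}

#' @method autoplot asymmetry_summary
#' @export
autoplot.asymmetry_summary <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$d_a, y = .data$d_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "clade A distance", y = "clade B distance",
                  title = sprintf("mean B/A ratio %.2f, sign test p = %.2g",
                                  object$mean_ratio, object$sign_test_p)) +
    ggplot2::theme_minimal()
}
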