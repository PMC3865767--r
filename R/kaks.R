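# Counting-based Ka/Ks: Nei-Gojobori (1986) mean-pairwise counting and a
# SLAC-style variant that counts substitutions on the branches of a tree after
# Fitch parsimony ancestral reconstruction. Both run over whole alignments or
# domain/exon partitions mapped through a reference row.

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column of the protein alignment expands to its source codon
#' (`-` expands to `---`). Every protein row must have a CDS whose translation
#' matches its ungapped residues exactly.
#'
#' @param protein_msa A protein [aligned_set()].
#' @param cds_by_id Named character vector (or tibble `id`/`seq`) of coding
#'   sequences.
#' @return A codon [aligned_set()].
#' @export
back_translate <- function(protein_msa, cds_by_id) {
  cds_by_id <- as_seq_vector(cds_by_id)
  rows <- vapply(names(protein_msa), function(id) {
    if (!id %in% names(cds_by_id)) abort(paste0("missing CDS for '", id, "'"))
    nt <- check_cds(cds_by_id[[id]], id)
    codons <- codon_split(nt)
    res <- strsplit(protein_msa[[id]], "")[[1]]
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(codons)) {
      abort(sprintf("CDS of '%s' has %d codons but the protein row has %d residues",
                    id, length(codons), length(ungapped)))
    }
    trans <- Biostrings::GENETIC_CODE[codons]
    bad <- which(trans != ungapped)
    if (length(bad)) {
      abort(sprintf("translation mismatch for '%s' at residue %d ('%s' vs '%s')",
                    id, bad[1], trans[bad[1]], ungapped[bad[1]]))
    }
    out <- character(length(res)); k <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }, character(1))
  aligned_set(rows, alphabet = "codon")
}

# sum of NG86 site counts of the sense codons in `codons` (gap codons skipped)
row_site_counts <- function(codons) {
  tab <- codon_tables()
  keep <- codons %in% tab$sense
  c(s = sum(tab$s_sites[codons[keep]]), n = sum(tab$n_sites[codons[keep]]))
}

#' Pairwise NG86 Ka/Ks between two codon rows
#'
#' Site counts are the mean of the two rows' summed NG86 site counts over the
#' mutually ungapped codon columns. Differences at multi-hit codons are
#' averaged over all orderings of the single-nucleotide steps with paths
#' through stop codons excluded; codons where every path is blocked are
#' skipped and counted in `n_blocked`. Proportions are Jukes-Cantor corrected
#' (`k = -3/4 ln(1 - 4p/3)`); `p >= 0.75` flags saturation.
#'
#' @param row_a,row_b Codon strings of equal length (gaps as `---`).
#' @param partition Label for the output row.
#' @return One-row tibble: site counts, differences, `p_s`, `p_n`, `ks`,
#'   `ka`, `ka_ks`, `n_codons`, `n_blocked`, `flag`.
#' @export
ng86_pair <- function(row_a, row_b, partition = "All") {
  a <- codon_split(toupper(row_a)); b <- codon_split(toupper(row_b))
  if (length(a) != length(b)) abort("codon rows differ in length")
  tab <- codon_tables()
  keep <- a %in% tab$sense & b %in% tab$sense
  if (!any(keep)) abort("no mutually ungapped codon columns")
  a <- a[keep]; b <- b[keep]
  sa <- row_site_counts(a); sb <- row_site_counts(b)
  s_sites <- (sa["s"] + sb["s"]) / 2
  n_sites <- (sa["n"] + sb["n"]) / 2
  sd <- nd <- 0; blocked <- 0L
  for (k in which(a != b)) {
    dd <- codon_path_diff(a[k], b[k])
    if (anyNA(dd)) blocked <- blocked + 1L
    else { sd <- sd + dd["sd"]; nd <- nd + dd["nd"] }
  }
  finish_kaks(s_sites, n_sites, sd, nd, length(a), blocked, partition,
              method = "ng86-pair")
}

finish_kaks <- function(s_sites, n_sites, sd, nd, n_codons, blocked,
                        partition, method) {
  p_s <- if (s_sites > 0) sd / s_sites else NA_real_
  p_n <- if (n_sites > 0) nd / n_sites else NA_real_
  ks <- if (is.na(p_s)) NA_real_ else jc_correct(p_s)
  ka <- if (is.na(p_n)) NA_real_ else jc_correct(p_n)
  flag <- if ((sd + nd) == 0) "no-differences"
          else if (is.na(ks) || is.na(ka)) "saturated"
          else if (ks == 0) "ks-zero"
          else "ok"
  tibble(partition = partition, method = method,
         s_sites = unname(s_sites), n_sites = unname(n_sites),
         sd = unname(sd), nd = unname(nd), p_s = unname(p_s),
         p_n = unname(p_n), ks = unname(ks), ka = unname(ka),
         ka_ks = if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_,
         n_codons = n_codons, n_blocked = blocked, flag = flag)
}

#' Dataset Ka/Ks by mean-pairwise NG86 counting
#'
#' Runs [ng86_pair()] over all unordered row pairs; the dataset `ka` and `ks`
#' are the means of the per-pair corrected rates and the reported ratio is
#' `mean(ka) / mean(ks)`.
#'
#' @param codon_msa A codon [aligned_set()].
#' @param partition Label for the summary row.
#' @return A `kaks_result` object (`summary` row, `pairs` table); [tidy()]
#'   returns the per-pair table, [glance()] the summary.
#' @export
kaks_ng86 <- function(codon_msa, partition = "All") {
  ids <- names(codon_msa)
  if (length(ids) < 2L) abort("need at least 2 rows")
  prs <- utils::combn(ids, 2L)
  pairs <- bind_rows(lapply(seq_len(ncol(prs)), function(k) {
    mutate(ng86_pair(codon_msa[[prs[1, k]]], codon_msa[[prs[2, k]]],
                     partition = partition),
           id_a = prs[1, k], id_b = prs[2, k])
  }))
  ka <- mean(pairs$ka, na.rm = TRUE)
  ks <- mean(pairs$ks, na.rm = TRUE)
  summary <- tibble(
    partition = partition, method = "ng86-mean-pairwise",
    s_sites = mean(pairs$s_sites), n_sites = mean(pairs$n_sites),
    sd = mean(pairs$sd), nd = mean(pairs$nd),
    ks = ks, ka = ka,
    ka_ks = if (!is.na(ks) && ks > 0) ka / ks else NA_real_,
    n_codons = pairs$n_codons[1],
    flag = if (all(pairs$sd + pairs$nd == 0)) "no-differences"
           else if (is.na(ks) || ks == 0) "ks-zero" else "ok")
  structure(list(summary = summary, pairs = pairs,
                 method = "ng86-mean-pairwise"),
            class = "kaks_result")
}

#' Fitch parsimony ancestral codons on a tree
#'
#' Per nucleotide column, Fitch parsimony (bottom-up set operations, top-down
#' resolution); gaps at leaves are treated as missing data. Where the
#' top-down pass leaves a choice, the codon minimising the nonsynonymous
#' change count on the branch to the parent is taken, ties broken
#' lexicographically; at the root the lexicographically smallest codon in the
#' product of the per-position state sets is used (stop codons avoided
#' whenever a sense codon is admissible).
#'
#' @param tree [ape::phylo]; leaves must be a subset of the alignment rows.
#'   Multifurcations are resolved with zero-length branches first.
#' @param codon_msa A codon [aligned_set()].
#' @return List: `states` (node x codon matrix of codon strings, tips first in
#'   `tree$tip.label` order), `score` (total nucleotide parsimony score),
#'   `tree` (the binary tree used).
#' @export
fitch_ancestral <- function(tree, codon_msa) {
  if (!all(tree$tip.label %in% names(codon_msa))) {
    abort("tree has leaves missing from the alignment")
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  m <- codon_matrix(codon_msa[tr$tip.label])
  n_cod <- ncol(m)

  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  nt_of_bit <- setNames(names(bit), bit)
  # leaf nucleotide state sets: 4 bits; gap codon -> full set (missing)
  sets <- array(0L, dim = c(n_node, n_cod, 3L))
  for (i in seq_len(n_tip)) {
    for (k in seq_len(n_cod)) {
      cod <- m[i, k]
      if (cod == "---") { sets[i, k, ] <- 15L } else {
        sets[i, k, ] <- bit[strsplit(cod, "")[[1]]]
      }
    }
  }
  score <- 0L
  parents <- unique(tr$edge[, 1])          # postorder: children before parents
  children_of <- split(tr$edge[, 2], tr$edge[, 1])
  for (nd in parents) {
    kids <- children_of[[as.character(nd)]]
    s <- sets[kids[1], , , drop = FALSE][1, , ]
    for (kid in kids[-1]) {
      s2 <- sets[kid, , , drop = FALSE][1, , ]
      inter <- bitwAnd(s, s2)
      un <- bitwOr(s, s2)
      score <- score + sum(inter == 0L)
      s <- ifelse(inter == 0L, un, inter)
    }
    sets[nd, , ] <- s
  }

  states <- matrix(NA_character_, n_node, n_cod)
  root <- n_tip + 1L
  pick_codon <- function(allowed, parent_codon = NULL) {
    # allowed: list of 3 integer bitmasks
    opts <- lapply(allowed, function(bm) nt_of_bit[as.character(
      Filter(function(x) bitwAnd(bm, x) > 0L, c(1L, 2L, 4L, 8L)))])
    grid <- expand.grid(opts[[1]], opts[[2]], opts[[3]],
                        stringsAsFactors = FALSE)
    cand <- sort(apply(grid, 1L, paste, collapse = ""))
    sense <- cand[!cand %in% STOP_CODONS]
    if (length(sense)) cand <- sense
    if (is.null(parent_codon) || length(cand) == 1L) return(cand[1])
    nd_of <- vapply(cand, function(cc) {
      d <- codon_path_diff(parent_codon, cc)["nd"]
      if (is.na(d)) 99 else d
    }, numeric(1))
    cand[which.min(nd_of)]                  # ties: first of sorted = lexicographic
  }
  # top-down (preorder): parent state kept where admissible
  pre <- ape::reorder.phylo(tr, "cladewise")
  for (k in seq_len(n_cod)) {
    states[root, k] <- pick_codon(as.list(sets[root, k, ]))
  }
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1L]; child <- pre$edge[e, 2L]
    if (child <= n_tip) { states[child, ] <- m[child, ]; next }
    pc <- states[par, ]
    for (k in seq_len(n_cod)) {
      pbits <- bit[strsplit(pc[k], "")[[1]]]
      allowed <- lapply(1:3, function(p) {
        if (bitwAnd(sets[child, k, p], pbits[p]) > 0L) pbits[p]
        else sets[child, k, p]
      })
      states[child, k] <- pick_codon(allowed, parent_codon = pc[k])
    }
  }
  rownames(states) <- c(tr$tip.label, paste0("node", (n_tip + 1L):n_node))
  list(states = states, score = score, tree = tr)
}

#' Dataset Ka/Ks by SLAC-style counting on a tree
#'
#' Reconstructs ancestral codons by Fitch parsimony, counts synonymous and
#' nonsynonymous differences on every branch (multi-hit codons path-averaged
#' as in [ng86_pair()]; leaf gap codons skipped), and takes expected site
#' counts as the mean of the per-node summed NG86 site counts over all nodes,
#' ancestors included. The ratio is `(sum Nd / N) / (sum Sd / S)`.
#'
#' @param tree [ape::phylo] with the alignment rows as leaves.
#' @param codon_msa A codon [aligned_set()].
#' @param partition Label for the summary row.
#' @return A `kaks_result` object (`summary`, per-`branches` table).
#' @export
kaks_slac <- function(tree, codon_msa, partition = "All") {
  anc <- fitch_ancestral(tree, codon_msa)
  tr <- anc$tree
  st <- anc$states
  tab <- codon_tables()
  sd_tot <- nd_tot <- 0; blocked <- 0L
  branch_rows <- list()
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    a <- st[par, ]; b <- st[child, ]
    keep <- a %in% tab$sense & b %in% tab$sense
    sd <- nd <- 0
    for (k in which(keep & a != b)) {
      dd <- codon_path_diff(a[k], b[k])
      if (anyNA(dd)) blocked <- blocked + 1L
      else { sd <- sd + dd["sd"]; nd <- nd + dd["nd"] }
    }
    sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
    branch_rows[[e]] <- tibble(parent = par, child = child,
                               length = tr$edge.length[e] %||% NA_real_,
                               sd = unname(sd), nd = unname(nd))
  }
  sd_tot <- unname(sd_tot); nd_tot <- unname(nd_tot)
  node_sites <- t(apply(st, 1L, row_site_counts))
  s_sites <- mean(node_sites[, "s"])
  n_sites <- mean(node_sites[, "n"])
  # tree-wide aggregate proportions; the ratio is taken directly on them
  # (no multiple-hit correction: per-branch changes are already near-single-hit
  # once ancestors are reconstructed), with per-unit-tree-length rates emitted
  tree_length <- sum(tr$edge.length %||% NA_real_)
  p_s <- if (s_sites > 0) sd_tot / s_sites else NA_real_
  p_n <- if (n_sites > 0) nd_tot / n_sites else NA_real_
  out <- tibble(
    partition = partition, method = "slac-like",
    s_sites = s_sites, n_sites = n_sites, sd = sd_tot, nd = nd_tot,
    p_s = p_s, p_n = p_n,
    ks = if (!is.na(p_s) && !is.na(tree_length) && tree_length > 0) {
      p_s / tree_length
    } else NA_real_,
    ka = if (!is.na(p_n) && !is.na(tree_length) && tree_length > 0) {
      p_n / tree_length
    } else NA_real_,
    ka_ks = if (!is.na(p_s) && !is.na(p_n) && p_s > 0) p_n / p_s else NA_real_,
    n_codons = ncol(st), n_blocked = blocked,
    flag = if ((sd_tot + nd_tot) == 0) "no-differences"
           else if (is.na(p_s) || p_s == 0) "ks-zero" else "ok",
    tree_length = tree_length)
  structure(list(summary = out, branches = bind_rows(branch_rows),
                 parsimony_score = anc$score, method = "slac-like"),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Ka/Ks (%s) partition '%s': Ka = %.4g, Ks = %.4g, Ka/Ks = %.4g [%s]\n",
              x$method, s$partition, s$ka, s$ks, s$ka_ks, s$flag))
  invisible(x)
}

#' @method tidy kaks_result
#' @export
tidy.kaks_result <- function(x, ...) {
  if (!is.null(x$pairs)) as_tibble(x$pairs) else as_tibble(x$branches)
}

#' @method glance kaks_result
#' @export
glance.kaks_result <- function(x, ...) as_tibble(x$summary)

# map residue coordinates on the (ungapped) reference row to alignment columns
ref_columns <- function(msa, reference_id, start_aa, end_aa) {
  unit <- if (attr(msa, "alphabet") == "codon") 3L else 1L
  row <- msa[[reference_id]]
  n_col <- nchar(row) %/% unit
  cods <- if (unit == 3L) codon_split(row) else strsplit(row, "")[[1]]
  gap <- if (unit == 3L) "---" else "-"
  residue_of_col <- cumsum(cods != gap)
  n_res <- residue_of_col[n_col]
  if (end_aa > n_res) abort("partition extends beyond the reference sequence")
  which(cods != gap & residue_of_col >= start_aa & residue_of_col <= end_aa)
}

subset_columns <- function(msa, cols) {
  unit <- if (attr(msa, "alphabet") == "codon") 3L else 1L
  rows <- vapply(unclass(msa), function(s) {
    parts <- if (unit == 3L) codon_split(s) else strsplit(s, "")[[1]]
    paste(parts[cols], collapse = "")
  }, character(1))
  aligned_set(rows, alphabet = attr(msa, "alphabet"))
}

#' Partitioned Ka/Ks over domains or exons
#'
#' Maps each partition's residue span through the gaps of the reference row to
#' alignment columns and applies the chosen counting method per partition; a
#' whole-alignment row labelled `"All"` is prepended.
#'
#' @param codon_msa A codon [aligned_set()].
#' @param partitions A [partition_table()] tibble (`name`, `start_aa`,
#'   `end_aa`, residue coordinates on the reference protein).
#' @param reference_id Row id whose ungapped residues carry the coordinates.
#' @param method `"ng86"`, `"slac"` or `"both"`.
#' @param tree Tree for the SLAC-style method (required when used).
#' @return Tibble of summary rows, one per partition x method, with
#'   coordinates.
#' @export
kaks_partition <- function(codon_msa, partitions, reference_id,
                           method = c("ng86", "slac", "both"), tree = NULL) {
  method <- match.arg(method)
  if (!reference_id %in% names(codon_msa)) {
    abort(paste0("reference id '", reference_id, "' not in alignment"))
  }
  partitions <- partition_table(partitions)
  methods <- if (method == "both") c("ng86", "slac") else method
  if ("slac" %in% methods && is.null(tree)) {
    abort("the SLAC-style method needs a tree")
  }
  n_ref <- sum(codon_split(codon_msa[[reference_id]]) != "---")
  spans <- bind_rows(tibble(name = "All", start_aa = 1L, end_aa = n_ref),
                     partitions)
  rows <- list()
  for (k in seq_len(nrow(spans))) {
    cols <- ref_columns(codon_msa, reference_id,
                        spans$start_aa[k], spans$end_aa[k])
    sub <- subset_columns(codon_msa, cols)
    for (mth in methods) {
      res <- if (mth == "ng86") kaks_ng86(sub, partition = spans$name[k])
             else kaks_slac(tree, sub, partition = spans$name[k])
      row <- res$summary
      row$start_aa <- spans$start_aa[k]; row$end_aa <- spans$end_aa[k]
      rows[[length(rows) + 1L]] <- row
    }
  }
  bind_rows(rows)
}

#' Bar plot of partitioned Ka/Ks
#'
#' @param partition_table Output of [kaks_partition()].
#' @return A ggplot object.
#' @export
plot_kaks_partitions <- function(partition_table) {
  ggplot2::ggplot(partition_table,
                  ggplot2::aes(x = stats::reorder(.data$partition, .data$start_aa),
                               y = .data$ka_ks, fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Ka/Ks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
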