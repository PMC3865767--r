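# Protein distance estimation and BIONJ tree construction. The BIONJ
# agglomeration (Gascuel 1997) is implemented here in full: standard NJ
# Q-criterion pair selection, NJ branch-length estimates, and the
# variance-weighted reduction step with pair-variance bookkeeping.

#' Pairwise p-distance between two alignment rows
#'
#' Pairwise deletion: columns where either row carries a gap or an `X` are
#' skipped; the distance is mismatches over compared columns.
#'
#' @param msa An [aligned_set()].
#' @param i,j Row ids or indices.
#' @return Proportion of differing compared columns.
#' @export
p_distance <- function(msa, i, j) {
  a <- strsplit(msa[[i]], "")[[1]]
  b <- strsplit(msa[[j]], "")[[1]]
  keep <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  if (!any(keep)) abort("no comparable columns between the two rows")
  sum(a[keep] != b[keep]) / sum(keep)
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, the expected number of substitutions per site under a
#' Poisson model of multiple hits.
#'
#' @param p Proportion of observed differences, `0 <= p < 1`.
#' @return Corrected distance.
#' @export
poisson_correct <- function(p) {
  if (any(p >= 1) || any(p < 0)) abort("p must satisfy 0 <= p < 1")
  -log(1 - p)
}

#' All-pairs distance matrix of an alignment
#'
#' @param msa An [aligned_set()].
#' @param model `"poisson"` (Poisson-corrected p-distance, default) or
#'   `"observed"` (raw p-distance).
#' @return Symmetric numeric matrix with row/column names and a `model`
#'   attribute.
#' @export
distance_matrix <- function(msa, model = c("poisson", "observed")) {
  model <- match.arg(model)
  n <- length(msa)
  if (n < 2L) abort("need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- p_distance(msa, i, j)
    d[i, j] <- d[j, i] <- if (model == "poisson") poisson_correct(p) else p
  }
  attr(d, "model") <- model
  d
}

#' Build a BIONJ tree from a distance matrix
#'
#' BIONJ agglomeration: at each step the pair minimising the NJ Q criterion is
#' joined (ties broken by the smallest row/column index pair), branch lengths
#' are the NJ estimates with negative lengths clamped to zero and the deficit
#' transferred to the sister branch, and the reduced distances use the
#' variance-weighted lambda of BIONJ with pair-variance bookkeeping. The final
#' three clusters are resolved exactly, leaving the conventional trifurcating
#' root of an unrooted tree.
#'
#' @param dm Symmetric distance matrix with labels (from
#'   [distance_matrix()] or read from file).
#' @return An [ape::phylo] tree.
#' @export
build_bionj <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 3L) abort("BIONJ needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  v <- d                               # pair variances, initialised to d
  sub <- rownames(d)                   # newick fragment per active cluster

  while (n > 3L) {
    rs <- rowSums(d)
    # Q-criterion pair selection, smallest (i, j) on ties
    best <- c(NA_integer_, NA_integer_); qbest <- Inf
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      q <- (n - 2) * d[i, j] - rs[i] - rs[j]
      if (q < qbest - 1e-12) { qbest <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    lambda <- if (v[i, j] > 0) {
      0.5 + sum(v[j, -c(i, j)] - v[i, -c(i, j)]) / (2 * (n - 2) * v[i, j])
    } else 0.5
    lambda <- min(1, max(0, lambda))
    others <- setdiff(seq_len(n), c(i, j))
    du <- lambda * (d[i, others] - bi) + (1 - lambda) * (d[j, others] - bj)
    vu <- lambda * v[i, others] + (1 - lambda) * v[j, others] -
      lambda * (1 - lambda) * v[i, j]
    newsub <- sprintf("(%s:%.15g,%s:%.15g)", sub[i], bi, sub[j], bj)

    keep <- others
    d <- d[keep, keep, drop = FALSE]; v <- v[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    v <- rbind(cbind(v, vu), c(vu, 0))
    sub <- c(sub[keep], newsub)
    n <- n - 1L
  }
  # exact 3-taxon resolution
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(a, b, c3), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 sub[1], lens[1], sub[2], lens[2], sub[3], lens[3])
  ape::read.tree(text = nwk)
}

# canonical leaf bipartitions induced by the internal edges of a tree:
# each split is the tip set on the child side of an internal edge, flipped to
# the side not containing the reference tip, and serialised sorted.
tree_splits <- function(tree, include_nodes = FALSE) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n_tip))
  splits <- character(0); nodes <- integer(0)
  for (nd in internal) {
    clade <- tree$tip.label[unlist(phangorn_free_descendants(tree, nd))]
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, nd)
  }
  if (include_nodes) list(splits = splits, nodes = nodes) else splits
}

# tip indices below a node (self-contained postorder walk; no phangorn dep)
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_free_descendants, tree = tree))
}

#' Bootstrap support for a BIONJ tree
#'
#' Resamples alignment columns with replacement (codon alignments are
#' resampled codon-wise), rebuilds the BIONJ tree per replicate and reports,
#' for each internal edge of the point-estimate tree, the percentage of
#' replicates containing the same leaf bipartition. Supports are attached as
#' internal node labels. Deterministic given `seed`.
#'
#' @param msa An [aligned_set()].
#' @param model Distance model, see [distance_matrix()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The point-estimate [ape::phylo] tree with `node.label` supports.
#' @export
bootstrap_support <- function(msa, model = "poisson", n_reps = 100L,
                              seed = 1L) {
  if (n_reps < 1L) abort("n_reps must be >= 1")
  point <- build_bionj(distance_matrix(msa, model))
  m <- aln_matrix(msa)
  unit <- if (attr(msa, "alphabet") == "codon") 3L else 1L
  n_units <- ncol(m) %/% unit
  ps <- tree_splits(point, include_nodes = TRUE)
  counts <- setNames(rep(0L, length(ps$splits)), ps$splits)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    take <- sample.int(n_units, n_units, replace = TRUE)
    cols <- as.vector(vapply(take, function(u) {
      ((u - 1L) * unit + 1L):(u * unit)
    }, integer(unit)))
    rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    bmsa <- aligned_set(rows, alphabet = attr(msa, "alphabet"))
    btree <- tryCatch(build_bionj(distance_matrix(bmsa, model)),
                      error = function(e) NULL)
    if (is.null(btree)) next
    hit <- ps$splits %in% tree_splits(btree)
    counts[hit] <- counts[hit] + 1L
  }
  support <- 100 * counts / n_reps
  n_tip <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  labs[ps$nodes - n_tip] <- format(support, trim = TRUE)
  point$node.label <- labs
  point
}
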