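# Seeded simulator of duplicated gene families: Yule species tree, one
# duplication producing two paralog clades with a clade-specific rate
# multiplier, and codon evolution with per-partition omega. The generated
# truth (tree, clade labels, alignment) drives every downstream stage's
# parameter-recovery tests.

#' Simulation parameters for a duplicated gene family
#'
#' @param n_species Number of species (>= 3).
#' @param total_height Expected root-to-tip path length of the species tree,
#'   in expected nucleotide substitutions per site. Default 0.25, the scale of
#'   the observed within-clade divergence of a vertebrate paralog family.
#' @param r Rate multiplier applied to every branch of paralog clade B
#'   (BACE2-like acceleration; default 2).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param omega Tibble with columns `name`, `start`, `end` (1-based inclusive
#'   codon coordinates) and `omega`. The default profile relaxes the termini
#'   (omega 0.3) around a strongly purifying core (omega 0.05), mirroring the
#'   5'-exon vs catalytic-core contrast seen in real duplicated protease
#'   genes.
#' @param omega_background Omega for codons not covered by `omega`.
#' @param codon_length Number of codons.
#' @param codon_freqs `"uniform"` or a named numeric vector of root codon
#'   frequencies over the 61 sense codons.
#' @param dup_stem Length of the stem edge from the duplication node to each
#'   clade root (clade B's stem is also multiplied by `r`). Defaults to
#'   `total_height`.
#' @param tree Optional fixed species tree ([ape::phylo] with branch lengths);
#'   overrides `n_species`/`total_height`.
#' @param seed Integer seed; every random draw of the run is derived from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_species = 10L, total_height = 0.25, r = 2,
                       kappa = 2, omega = NULL, omega_background = 0.05,
                       codon_length = 500L, codon_freqs = "uniform",
                       dup_stem = NULL, tree = NULL, seed = 1L) {
  if (is.null(tree) && n_species < 3L) abort("n_species must be >= 3")
  if (r <= 0) abort("rate multiplier r must be > 0")
  if (kappa < 0) abort("kappa must be >= 0")
  if (is.null(omega)) {
    nt <- max(3L, round(0.12 * codon_length))
    ct <- max(3L, round(0.08 * codon_length))
    omega <- tibble(
      name = c("nterm", "core", "cterm"),
      start = c(1L, nt + 1L, codon_length - ct + 1L),
      end = c(nt, codon_length - ct, codon_length),
      omega = c(0.3, 0.05, 0.3))
  }
  omega <- as_tibble(omega)
  if (any(omega$omega < 0)) abort("omega must be >= 0")
  if (max(omega$end) > codon_length) {
    abort("omega partition exceeds codon_length")
  }
  structure(list(n_species = as.integer(n_species),
                 total_height = total_height, r = r, kappa = kappa,
                 omega = omega, omega_background = omega_background,
                 codon_length = as.integer(codon_length),
                 codon_freqs = codon_freqs,
                 dup_stem = if (is.null(dup_stem)) total_height else dup_stem,
                 tree = tree, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a Yule species tree
#'
#' Pure-birth topology with exponential waiting times, rescaled so the mean
#' root-to-tip path equals `total_height`. Deterministic given `seed`.
#'
#' @inheritParams sim_params
#' @return An [ape::phylo] tree with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_species, total_height = 0.25, seed = 1L) {
  if (n_species < 3L) abort("n_species must be >= 3")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_species)]
  tr$edge.length <- tr$edge.length * (total_height / mean(depths))
  tr
}

#' Graft a duplication onto a species tree
#'
#' Returns a gene tree whose root is the duplication: two children, each an
#' independent copy of the species tree, with every branch of copy B (stem
#' included) multiplied by `r`. Leaf labels are suffixed `"_A"` / `"_B"`.
#'
#' @param species_tree [ape::phylo] with branch lengths.
#' @param r Positive clade-B rate multiplier.
#' @param stem Stem edge length from the duplication to each clade root.
#' @return An [ape::phylo] gene tree with `2 * n` tips.
#' @export
graft_duplication <- function(species_tree, r, stem = 0.25) {
  if (r <= 0) abort("rate multiplier r must be > 0")
  a <- species_tree
  a$tip.label <- paste0(a$tip.label, "_A")
  b <- species_tree
  b$tip.label <- paste0(b$tip.label, "_B")
  b$edge.length <- b$edge.length * r
  na <- sub(";\\s*$", "", ape::write.tree(a, digits = 15))
  nb <- sub(";\\s*$", "", ape::write.tree(b, digits = 15))
  ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);", na, stem, nb, stem * r))
}

# Per-omega substitution machinery: for each sense codon, the non-stop
# single-nucleotide targets with relative rates kappa^(is transition) *
# (omega if nonsynonymous). `scale` calibrates one branch-length unit to one
# expected nucleotide substitution per nucleotide site at the root codon
# distribution (3 codon events per codon per unit time).
codon_rates <- function(omega, kappa, pi) {
  tab <- codon_tables()
  targets <- vector("list", length(tab$sense))
  rates <- vector("list", length(tab$sense))
  total <- numeric(length(tab$sense))
  for (i in seq_along(tab$sense)) {
    nbi <- tab$nb[[i]]
    keep <- !nbi$stop
    w <- ifelse(nbi$transition[keep], kappa, 1) *
      ifelse(nbi$syn[keep], 1, omega)
    targets[[i]] <- unname(tab$idx[nbi$target[keep]])
    rates[[i]] <- w
    total[i] <- sum(w)
  }
  list(targets = targets, rates = rates, total = total,
       scale = 3 / sum(pi * total))
}

evolve_codon <- function(state, t, rt) {
  t_rem <- t
  repeat {
    lambda <- rt$scale * rt$total[state]
    if (lambda <= 0) break
    dt <- rexp(1L, lambda)
    if (dt > t_rem) break
    t_rem <- t_rem - dt
    k <- sample.int(length(rt$targets[[state]]), 1L,
                    prob = rt$rates[[state]])
    state <- rt$targets[[state]][k]
  }
  state
}

#' Simulate a codon alignment along a gene tree
#'
#' Root codons are drawn from the root frequencies (stop codons excluded) and
#' evolved along each branch under a codon process in which a proposed
#' single-nucleotide change is accepted at relative rate 1 (synonymous) or the
#' partition's omega (nonsynonymous), transitions weighted by kappa, and
#' changes creating stop codons rejected. Branch lengths are calibrated so one
#' unit equals one expected nucleotide substitution per nucleotide site at the
#' root composition. No indels, so the simulated columns are the true
#' alignment. Deterministic given `params$seed`.
#'
#' @param gene_tree [ape::phylo] with branch lengths (e.g. from
#'   [graft_duplication()]).
#' @param params A [sim_params()] object.
#' @return List with `alignment` (a codon [aligned_set()]) and `truth`
#'   (gene tree, per-site omega, params echo).
#' @export
simulate_codon_msa <- function(gene_tree, params) {
  stopifnot(inherits(params, "sim_params"))
  tab <- codon_tables()
  L <- params$codon_length
  if (max(params$omega$end) > L) abort("omega partition exceeds codon_length")
  pi <- if (identical(params$codon_freqs, "uniform")) {
    setNames(rep(1 / length(tab$sense), length(tab$sense)), tab$sense)
  } else {
    p <- params$codon_freqs[tab$sense]
    if (anyNA(p)) abort("codon_freqs must cover all 61 sense codons")
    p / sum(p)
  }
  omega_site <- rep(params$omega_background, L)
  for (k in seq_len(nrow(params$omega))) {
    omega_site[params$omega$start[k]:params$omega$end[k]] <- params$omega$omega[k]
  }
  rt_by_omega <- lapply(
    setNames(nm = as.character(unique(omega_site))),
    function(o) codon_rates(as.numeric(o), params$kappa, pi))

  set.seed(params$seed)
  tr <- ape::reorder.phylo(gene_tree, "cladewise")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  states <- matrix(NA_integer_, nrow = n_node, ncol = L)
  root <- n_tip + 1L
  states[root, ] <- sample.int(length(tab$sense), L, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    t <- tr$edge.length[e]
    for (s in seq_len(L)) {
      states[child, s] <- evolve_codon(states[par, s], t,
                                       rt_by_omega[[as.character(omega_site[s])]])
    }
  }
  rows <- vapply(seq_len(n_tip), function(i) {
    paste(tab$sense[states[i, ]], collapse = "")
  }, character(1))
  names(rows) <- tr$tip.label
  aln <- aligned_set(rows, alphabet = "codon")
  list(alignment = aln,
       truth = list(gene_tree = gene_tree, omega_site = omega_site,
                    root_codons = tab$sense[states[root, ]], params = params))
}

#' Translate a codon alignment to a protein alignment
#'
#' `---` codon gaps become `-` residues.
#'
#' @param codon_msa A codon [aligned_set()].
#' @return A protein [aligned_set()].
#' @export
translate_alignment <- function(codon_msa) {
  code <- Biostrings::GENETIC_CODE
  m <- codon_matrix(codon_msa)
  rows <- apply(m, 1L, function(cod) {
    aa <- ifelse(cod == "---", "-", unname(code[cod]))
    if (anyNA(aa) || any(aa == "*")) abort("stop or invalid codon in alignment")
    paste(aa, collapse = "")
  })
  aligned_set(rows, alphabet = "protein")
}

#' Simulate a complete duplicated gene family
#'
#' Convenience wrapper: species tree, duplication graft, codon alignment,
#' protein translation and a clade/species label table.
#'
#' @param params A [sim_params()] object.
#' @return List with `gene_tree`, `species_tree`, `codon_msa`, `protein_msa`,
#'   `labels` (tibble id/species/clade) and `truth`.
#' @export
simulate_gene_family <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sp <- if (!is.null(params$tree)) params$tree else {
    simulate_species_tree(params$n_species, params$total_height, params$seed)
  }
  gt <- graft_duplication(sp, params$r, stem = params$dup_stem)
  sim <- simulate_codon_msa(gt, params)
  labels <- tibble(id = gt$tip.label,
                   species = sub("_[AB]$", "", gt$tip.label),
                   clade = sub("^.*_", "", gt$tip.label))
  list(gene_tree = gt, species_tree = sp, codon_msa = sim$alignment,
       protein_msa = translate_alignment(sim$alignment),
       labels = labels, truth = sim$truth)
}

# ---- synthetic protein architectures ---------------------------------------

HYDROPHOBIC_AA <- c("L", "V", "I", "F", "A", "M")
POLAR_AA <- c("D", "E", "K", "N", "Q", "R", "S", "T", "G", "H")
AA20 <- setdiff(AA_ALPHABET, "X")

# Proximal active-site island in full PS00141 context (matches the pattern);
# distal island carries the D-[ST]-G core but a context that PS00141 rejects,
# the hallmark that separates BACE1-like (one full match) from
# cathepsin/BACE2-like (two full matches) sequences.
MOTIF_FULL <- "LLVDTGSSNLWV"
MOTIF_CORE_ONLY <- "EEPDSGTSELWV"
MOTIF_FULL2 <- "ILIDSGTTNLRL"

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

splice_in <- function(res, at, island) {
  res[at:(at + length(island) - 1L)] <- island
  res
}

architecture_template <- function(kind) {
  if (is.null(codon_env$templates)) codon_env$templates <- list()
  if (!is.null(codon_env$templates[[kind]])) return(codon_env$templates[[kind]])
  bace <- with_local_seed(104729L, {
    res <- sample(AA20, 480L, replace = TRUE)
    res[1L] <- "M"
    res <- splice_in(res, 4L, sample(HYDROPHOBIC_AA, 15L, replace = TRUE))
    res <- splice_in(res, 90L, strsplit(MOTIF_FULL, "")[[1]])
    res <- splice_in(res, 290L, strsplit(MOTIF_CORE_ONLY, "")[[1]])
    res <- splice_in(res, 436L, sample(c("L", "V", "I", "F"), 26L, replace = TRUE))
    res
  })
  cath <- with_local_seed(224737L, {
    res <- vapply(seq_len(380L), function(p) {
      if (p <= length(bace) && runif(1) < 0.45) bace[p] else sample(AA20, 1L)
    }, character(1))
    res[1L] <- "M"
    res <- splice_in(res, 4L, sample(HYDROPHOBIC_AA, 15L, replace = TRUE))
    res <- splice_in(res, 80L, strsplit(MOTIF_FULL, "")[[1]])
    res <- splice_in(res, 270L, strsplit(MOTIF_FULL2, "")[[1]])
    # polar C-terminal region: no transmembrane stretch can form here
    res[291:380] <- sample(POLAR_AA, 90L, replace = TRUE)
    res
  })
  islands <- list(
    `bace-like` = list(template = bace,
                       frozen = c(1:18, 90:101, 290:301, 436:480),
                       insert_at = 400L, insert_max = 60L,
                       expected_motifs = 1L, motif_islands = c(90L)),
    `cathepsin-like` = list(template = cath,
                            frozen = c(1:18, 80:91, 270:281, 291:380),
                            insert_at = 200L, insert_max = 40L,
                            expected_motifs = 2L,
                            motif_islands = c(80L, 270L)))
  codon_env$templates <- islands
  islands[[kind]]
}

#' Generate a synthetic protein with a BACE-like or cathepsin-like architecture
#'
#' Produces a decoy protein for classifier validation. `"bace-like"` decoys
#' (~480-540 residues) carry an N-terminal hydrophobic signal-peptide window,
#' two D-\[ST\]-G active-site cores of which only the proximal one sits in a
#' full PS00141 context (as in real BACE1), and a >=19-residue hydrophobic
#' stretch near the C terminus. `"cathepsin-like"` decoys (~380-420 residues)
#' keep the signal peptide and carry two full PS00141 matches but have a polar
#' C terminus (no transmembrane stretch). Residue noise is applied outside the
#' functional islands at rate `divergence` relative to a fixed internal
#' template, plus a random-length neutral insert, so decoys of a kind are
#' homologous to each other and only distantly similar across kinds. These are
#' synthetic stand-ins, not database sequences.
#'
#' @param kind `"bace-like"` or `"cathepsin-like"`.
#' @param seed Integer seed.
#' @param divergence Per-residue substitution probability outside the frozen
#'   islands (default 0.25).
#' @return A single protein string.
#' @export
decorate_architecture <- function(kind = c("bace-like", "cathepsin-like"),
                                  seed = 1L, divergence = 0.25) {
  kind <- match.arg(kind)
  arch <- architecture_template(kind)
  with_local_seed(seed, {
    res <- arch$template
    mut <- setdiff(seq_along(res), arch$frozen)
    flip <- mut[runif(length(mut)) < divergence]
    res[flip] <- vapply(res[flip], function(a) sample(setdiff(AA20, a), 1L),
                        character(1))
    ins_len <- sample.int(arch$insert_max + 1L, 1L) - 1L
    if (ins_len > 0L) {
      res <- append(res, sample(AA20, ins_len, replace = TRUE),
                    after = arch$insert_at)
    }
    seq <- paste(res, collapse = "")
    # strip any accidental PS00141 match created by the noise: keep only the
    # designed islands as full-pattern matches
    repeat {
      hits <- find_active_site_motifs(seq)
      extra <- nrow(hits) - arch$expected_motifs
      if (extra <= 0L) break
      designed <- vapply(hits$start, function(s) {
        any(abs(s - (arch$motif_islands +
                       ifelse(arch$motif_islands > arch$insert_at, ins_len, 0L))) <= 2L)
      }, logical(1))
      bad <- hits$start[!designed][1]
      substr(seq, bad + 3L, bad + 3L) <- "E"  # break the core's Asp
    }
    seq
  })
}
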