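# Independent oracles and small fixture builders shared across tests.

aa20 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL)

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# Brute-force affine-gap local alignment score (three-state dynamic program
# written from the recurrences; independent of the Biostrings C code behind
# local_align). A gap of length L costs open + L * ext.
sw_oracle_score <- function(a, b, sm, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                     sm[A[i - 1], B[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

# Exhaustive-minimum parsimony score: enumerate all internal nucleotide
# labelings per column and take the minimum number of changes over the edges.
fitch_oracle_score <- function(tree, codon_rows) {
  nts <- c("A", "C", "G", "T")
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  internal <- (n_tip + 1):(n_tip + tr$Nnode)
  m <- do.call(rbind, strsplit(gsub("(.)", "\\1 ", codon_rows[tr$tip.label]), " "))
  total <- 0L
  combos <- as.matrix(expand.grid(rep(list(nts), length(internal)),
                                  stringsAsFactors = FALSE))
  for (col in seq_len(ncol(m))) {
    leaf_states <- m[, col]
    missing <- leaf_states == "-"
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      lab <- character(n_tip + tr$Nnode)
      lab[seq_len(n_tip)] <- leaf_states
      lab[internal] <- combos[r, ]
      changes <- 0L
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        if (ch <= n_tip && missing[ch]) next
        if (lab[p] != lab[ch]) changes <- changes + 1L
      }
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# hand NG86 neighbour enumeration for one codon, written directly against the
# genetic code (independent of the package's cached tables)
ng86_sites_oracle <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  res <- strsplit(codon, "")[[1]]
  syn <- non <- 0L
  for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), res[p])) {
    r2 <- res; r2[p] <- nt
    target <- paste(r2, collapse = "")
    if (code[target] == "*") next
    if (code[target] == code[codon]) syn <- syn + 1L else non <- non + 1L
  }
  c(s = syn / 3, n = non / 3)
}

make_family <- function(n_species = 6, r = 2, codons = 200, seed = 1,
                        omega = 0.1, height = 0.25) {
  params <- sim_params(
    n_species = n_species, r = r, codon_length = codons, seed = seed,
    total_height = height,
    omega = tibble::tibble(name = "all", start = 1, end = codons,
                           omega = omega))
  simulate_gene_family(params)
}
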