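# Codon bookkeeping shared by the simulator and the Ka/Ks counting methods.
# All tables are built once at load time from the standard genetic code.

NT4 <- c("A", "C", "G", "T")

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  code <- Biostrings::GENETIC_CODE
  all_codons <- names(code)
  sense <- all_codons[code != "*"]
  aa <- code[sense]
  idx <- setNames(seq_along(sense), sense)

  # nb[[c]]: tibble-free list of single-nucleotide neighbours of sense codon c
  # with classification (synonymous / transition / target codon, stops kept
  # but flagged so callers can apply their own stop conventions).
  nb <- vector("list", length(sense))
  for (i in seq_along(sense)) {
    c0 <- sense[i]
    res <- strsplit(c0, "")[[1]]
    tgt <- character(0); pos <- integer(0)
    for (p in 1:3) for (n in NT4[NT4 != res[p]]) {
      r2 <- res; r2[p] <- n
      tgt <- c(tgt, paste(r2, collapse = "")); pos <- c(pos, p)
    }
    stop_flag <- tgt %in% STOP_CODONS
    syn <- !stop_flag & code[tgt] == aa[i]
    ts <- vapply(seq_along(tgt), function(k) {
      is_transition(substr(c0, pos[k], pos[k]), substr(tgt[k], pos[k], pos[k]))
    }, logical(1))
    nb[[i]] <- list(target = tgt, pos = pos, stop = stop_flag,
                    syn = unname(syn), transition = ts)
  }
  names(nb) <- sense

  # NG86 expected site counts per sense codon: each of the 9 single-nucleotide
  # changes is classified against the code; changes creating a stop codon are
  # dropped without renormalisation, so s + n <= 3.
  s_sites <- vapply(nb, function(x) sum(x$syn & !x$stop) / 3, numeric(1))
  n_sites <- vapply(nb, function(x) sum(!x$syn & !x$stop) / 3, numeric(1))

  codon_env$tab <- list(sense = sense, aa = aa, idx = idx, nb = nb,
                        s_sites = s_sites, n_sites = n_sites)
  codon_env$tab
}

#' Expected synonymous/nonsynonymous site counts of a codon
#'
#' Nei–Gojobori (1986) site decomposition: each of the nine single-nucleotide
#' neighbours of a sense codon is classified as synonymous or nonsynonymous
#' against the standard genetic code; neighbours that are stop codons are
#' dropped without renormalisation, so the two counts sum to at most 3 (and to
#' exactly 3 iff no neighbour is a stop).
#'
#' @param codon A sense codon string, e.g. `"TTT"`.
#' @return Named numeric vector `c(s_sites, n_sites)`.
#' @export
ng86_sites <- function(codon) {
  tab <- codon_tables()
  codon <- toupper(codon)
  if (!codon %in% tab$sense) {
    abort(sprintf("'%s' is not a sense codon", codon))
  }
  c(s_sites = unname(tab$s_sites[codon]), n_sites = unname(tab$n_sites[codon]))
}

# Classify the substitution path(s) between two sense codons.
# Returns c(sd, nd): expected synonymous / nonsynonymous differences,
# averaged over all orderings of the single-nucleotide steps with paths that
# traverse a stop codon excluded. NA if every path is blocked by stops.
codon_path_diff <- function(a, b) {
  tab <- codon_tables()
  if (a == b) return(c(sd = 0, nd = 0))
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- permutations_of(diff_pos)
  sd <- nd <- 0; nok <- 0L
  bchars <- strsplit(b, "")[[1]]
  for (ord in paths) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (p in ord) {
      nxt_chars <- strsplit(cur, "")[[1]]
      nxt_chars[p] <- bchars[p]
      nxt <- paste(nxt_chars, collapse = "")
      if (nxt %in% STOP_CODONS) { ok <- FALSE; break }
      if (tab$aa[cur] == tab$aa[nxt]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { sd <- sd + s; nd <- nd + n; nok <- nok + 1L }
  }
  if (nok == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd / nok, nd = nd / nok)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# split every row of a codon alignment into a codon matrix (rows x codon cols)
codon_matrix <- function(msa) {
  if (attr(msa, "alphabet") != "codon") abort("codon alignment required")
  ncod <- nchar(msa[[1]]) %/% 3L
  m <- matrix("", nrow = length(msa), ncol = ncod,
              dimnames = list(names(msa), NULL))
  for (i in seq_along(msa)) m[i, ] <- codon_split(msa[[i]])
  bad <- m[grepl("-", m) & m != "---"]
  if (length(bad)) abort("gap run not aligned to codon boundaries")
  m
}
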