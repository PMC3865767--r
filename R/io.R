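# Sequence, alignment, tree and table IO shared by all analysis stages.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
NT_ALPHABET <- c("A", "C", "G", "T")
GAP <- "-"

#' Read sequences from a FASTA file
#'
#' Reads protein or coding (CDS) sequences into a tibble. Ids are the first
#' whitespace-delimited token of each header; residues are uppercased and a
#' `'.'` gap character is normalised to `'-'`. For CDS input a terminal `'*'`
#' translation artefact is never expected, but a terminal stop codon is kept
#' (see [check_cds()]); ambiguous nucleotides are rejected because the
#' downstream Ka/Ks counting is undefined on ambiguity codes.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param aligned If `TRUE`, gap characters are allowed and all sequences must
#'   have equal length.
#' @return A tibble with columns `id`, `seq`, `desc`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- if (alphabet == "protein") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyNA(ids) || any(!nzchar(ids))) abort("empty sequence id in FASTA header")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id in FASTA: ",
                 ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  ok <- c(if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET,
          if (aligned) GAP, if (alphabet == "dna") "*")
  for (k in seq_along(seqs)) {
    res <- strsplit(seqs[k], "")[[1]]
    bad <- which(!res %in% ok)
    if (length(bad)) {
      abort(sprintf("illegal character '%s' at position %d in sequence '%s'",
                    res[bad[1]], bad[1], ids[k]))
    }
  }
  tibble(id = unname(ids), seq = unname(seqs), desc = unname(desc))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with `id` and `seq` columns (or a named character
#'   vector).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  v <- as_seq_vector(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(v)) {
    writeLines(paste0(">", names(v)[i]), con)
    s <- v[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Accept either a tibble(id, seq) or a named character vector.
as_seq_vector <- function(x) {
  if (is.character(x)) {
    if (length(x) == 0L) return(x)
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("sequences must be named")
    }
    return(x)
  }
  if (is.data.frame(x)) return(setNames(x$seq, x$id))
  abort("expected a named character vector or a tibble with id/seq columns")
}

#' Validate a coding sequence
#'
#' Checks that a CDS is over A/C/G/T, has length divisible by three after
#' trimming an optional terminal stop codon, and contains no internal stop
#' codon (a premature stop is treated as pseudogene evidence, not silently
#' trimmed).
#'
#' @param nt Nucleotide string.
#' @param id Id used in error messages.
#' @return The CDS with any terminal stop codon removed.
#' @export
check_cds <- function(nt, id = "<cds>") {
  nt <- toupper(nt)
  res <- strsplit(nt, "")[[1]]
  bad <- which(!res %in% NT_ALPHABET)
  if (length(bad)) {
    abort(sprintf("ambiguous/illegal nucleotide '%s' at position %d in '%s'",
                  res[bad[1]], bad[1], id))
  }
  if (nchar(nt) %% 3 != 0) {
    abort(sprintf("CDS length %d of '%s' is not divisible by 3", nchar(nt), id))
  }
  codons <- codon_split(nt)
  stops <- which(codons %in% STOP_CODONS)
  n <- length(codons)
  if (length(stops) && any(stops < n)) {
    abort(sprintf("internal stop codon at codon %d in '%s'", stops[1], id))
  }
  if (length(stops) && stops[length(stops)] == n) {
    nt <- substr(nt, 1L, 3L * (n - 1L))
  }
  nt
}

codon_split <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop codon is dropped and an internal
#' stop is a hard error.
#'
#' @param nt Nucleotide string, length divisible by 3.
#' @param id Id used in error messages.
#' @return Amino-acid string.
#' @export
translate_cds <- function(nt, id = "<cds>") {
  nt <- check_cds(nt, id)
  if (nchar(nt) == 0L) return("")
  code <- Biostrings::GENETIC_CODE
  aa <- code[codon_split(nt)]
  if (anyNA(aa)) abort(sprintf("untranslatable codon in '%s'", id))
  paste(aa, collapse = "")
}

#' Construct a validated alignment
#'
#' An aligned set is a named character vector of equal-length gapped rows with
#' an `alphabet` attribute (`"protein"` or `"codon"`), the container consumed
#' by the distance, Ka/Ks and block stages.
#'
#' @param rows Named character vector (or tibble with `id`/`seq`) of gapped
#'   rows.
#' @param alphabet `"protein"` or `"codon"`.
#' @return An `aligned_set` object.
#' @export
aligned_set <- function(rows, alphabet = c("protein", "codon")) {
  alphabet <- match.arg(alphabet)
  v <- as_seq_vector(rows)
  if (length(v) < 2L) abort("an alignment needs at least 2 rows")
  if (anyDuplicated(names(v))) abort("duplicate row ids in alignment")
  if (length(unique(nchar(v))) != 1L) abort("alignment rows differ in length")
  v <- toupper(gsub(".", "-", v, fixed = TRUE))
  ok <- c(if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET, GAP)
  for (k in seq_along(v)) {
    res <- strsplit(v[[k]], "")[[1]]
    bad <- which(!res %in% ok)
    if (length(bad)) {
      abort(sprintf("illegal character '%s' at column %d in row '%s'",
                    res[bad[1]], bad[1], names(v)[k]))
    }
  }
  if (alphabet == "codon" && nchar(v[[1]]) %% 3L != 0L) {
    abort("codon alignment length is not divisible by 3")
  }
  structure(v, alphabet = alphabet, class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d rows x %d columns (%s)\n",
              length(x), nchar(x[[1]]), attr(x, "alphabet")))
  invisible(x)
}

#' @export
`[.aligned_set` <- function(x, i) {
  aligned_set(unclass(x)[i], alphabet = attr(x, "alphabet"))
}

# alignment as a character matrix (rows x columns)
aln_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(unname(msa)), ""))
  rownames(m) <- names(msa)
  m
}

#' Read a tree from a Newick file or string
#'
#' Thin wrapper over [ape::read.tree()] with duplicate-label validation;
#' internal node labels are interpreted as bootstrap supports downstream.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) abort("could not parse Newick input")
  if (anyDuplicated(tr$tip.label)) abort("duplicate leaf labels in tree")
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read a domain/exon partition table
#'
#' Expects a TSV with a header row and columns `name`, `start_aa`, `end_aa`
#' (1-based inclusive residue coordinates on a named reference protein).
#'
#' @param path TSV path.
#' @param reference_length Optional reference protein length used to validate
#'   the coordinates.
#' @param exon_set If `TRUE` the partitions must be non-overlapping.
#' @return A tibble with columns `name`, `start_aa`, `end_aa`.
#' @export
read_partition_table <- function(path, reference_length = NULL,
                                 exon_set = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(raw) < 3L) abort("partition table needs >= 3 columns (name, start, end)")
  tab <- tibble(name = as.character(raw[[1]]),
                start_aa = raw[[2]], end_aa = raw[[3]])
  partition_table(tab, reference_length = reference_length,
                  exon_set = exon_set)
}

#' Validate a partition table
#'
#' @param tab Tibble/data frame with `name`, `start_aa`, `end_aa`.
#' @inheritParams read_partition_table
#' @return The validated tibble.
#' @export
partition_table <- function(tab, reference_length = NULL, exon_set = FALSE) {
  tab <- as_tibble(tab)
  for (col in c("start_aa", "end_aa")) {
    v <- tab[[col]]
    if (any(is.na(suppressWarnings(as.numeric(v)))) ||
        any(as.numeric(v) != round(as.numeric(v)))) {
      abort(sprintf("non-integer coordinate in partition column '%s'", col))
    }
    tab[[col]] <- as.integer(v)
  }
  if (any(tab$start_aa < 1L)) abort("partition start must be >= 1")
  bad <- which(tab$start_aa > tab$end_aa)
  if (length(bad)) {
    abort(sprintf("partition '%s' has start > end", tab$name[bad[1]]))
  }
  if (!is.null(reference_length) && any(tab$end_aa > reference_length)) {
    abort("partition extends beyond the reference length")
  }
  if (exon_set && nrow(tab) > 1L) {
    o <- order(tab$start_aa)
    if (any(tab$start_aa[o][-1] <= tab$end_aa[o][-nrow(tab)])) {
      abort("exon partitions overlap")
    }
  }
  tab
}

#' Read a clade membership table
#'
#' TSV with header and columns `id`, `clade`, `species`; used by the
#' rate-asymmetry stage to pair orthologs across the two paralog clades.
#'
#' @param path TSV path.
#' @return Tibble with columns `id`, `clade`, `species`.
#' @export
read_clade_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(raw) < 3L) abort("clade table needs columns id, clade, species")
  clade_table(tibble(id = as.character(raw[[1]]),
                     clade = as.character(raw[[2]]),
                     species = as.character(raw[[3]])))
}

#' Validate a clade membership table
#'
#' @param tab Tibble with `id`, `clade`, `species`.
#' @return The validated tibble.
#' @export
clade_table <- function(tab) {
  tab <- as_tibble(tab)[c("id", "clade", "species")]
  if (anyDuplicated(tab$id)) abort("duplicate ids in clade table")
  dup <- duplicated(tab[c("clade", "species")])
  if (any(dup)) {
    abort(sprintf("species '%s' appears twice in clade %s",
                  tab$species[dup][1], tab$clade[dup][1]))
  }
  tab
}
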