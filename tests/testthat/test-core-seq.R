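test_that("FASTA reading takes the first header token, validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first sequence", "mkl", ">b", "MKV"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs$id, c("a", "b"))
  expect_equal(seqs$seq, c("MKL", "MKV"))
  expect_equal(seqs$desc[1], "first sequence")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, out)
  expect_equal(read_fasta(out)$seq, seqs$seq)

  writeLines(c(">a", "MK", ">a", "ML"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">a", "MK1L"), path)
  expect_error(read_fasta(path), "position 3")
})

test_that("CDS validation trims terminal stops and rejects bad input", {
  expect_equal(check_cds("ATGTAA"), "ATG")
  expect_equal(check_cds("ATGAAA"), "ATGAAA")
  expect_error(check_cds("ATGTAAAAA"), "internal stop")
  expect_error(check_cds("ATGAA"), "divisible by 3")
  expect_error(check_cds("ATGNNN"), "ambiguous")
})

test_that("translation follows the standard code and drops the terminal stop", {
  expect_equal(translate_cds("ATG"), "M")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_error(translate_cds("ATGTAGAAA"), "internal stop")
  # a 1506-nt CDS (501 codons + terminal stop) yields a 501-residue protein,
  # the length of a full-length human BACE1-type chain
  set.seed(11)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  cds <- paste(c(sample(sense, 501, replace = TRUE), "TAA"), collapse = "")
  expect_equal(nchar(cds), 1506)
  expect_equal(nchar(translate_cds(cds)), 501)
})

test_that("Newick IO round-trips topology, lengths and supports", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  tr <- read_newick("((A:1,B:1)90:2,(C:1,D:1)75:2);")
  expect_true("90" %in% tr$node.label)

  set.seed(4)
  rt <- ape::rtree(10)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(rt, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(rt$tip.label))
  expect_equal(max(abs(sort(back$edge.length) - sort(rt$edge.length))), 0,
               tolerance = 1e-9)
  expect_error(read_newick("((A,B);"), regexp = ".")
})

test_that("partition tables validate coordinates", {
  tab <- partition_table(tibble::tibble(name = "Exon 2", start_aa = 88,
                                        end_aa = 117))
  expect_equal(tab$end_aa - tab$start_aa + 1L, 30L)
  expect_silent(partition_table(tibble::tibble(name = "X", start_aa = 5,
                                               end_aa = 5)))
  expect_error(partition_table(tibble::tibble(name = "Y", start_aa = 10,
                                              end_aa = 9)), "start > end")
  expect_error(partition_table(tibble::tibble(name = "Z", start_aa = 1.5,
                                              end_aa = 3)), "non-integer")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tstart_aa\tend_aa", "Exon 2\t88\t117"), path)
  expect_equal(read_partition_table(path)$start_aa, 88L)
})

test_that("aligned_set enforces its invariants and normalises gaps", {
  expect_error(aligned_set(c(a = "MK")), "at least 2")
  expect_error(aligned_set(c(a = "MK", b = "MKL")), "differ in length")
  msa <- aligned_set(c(a = "M.K", b = "MLK"))
  expect_equal(msa[["a"]], "M-K")
  expect_error(aligned_set(c(a = "M1", b = "ML")), "illegal")
})

test_that("clade tables reject duplicate species within a clade", {
  expect_error(clade_table(tibble::tibble(
    id = c("x", "y"), clade = c("A", "A"), species = c("h", "h"))), "twice")
})
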