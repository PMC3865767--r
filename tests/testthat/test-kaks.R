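test_that("NG86 site counts match the frozen enumeration values", {
  expect_equal(ng86_sites("TTT"), c(s_sites = 1 / 3, n_sites = 8 / 3))
  expect_equal(ng86_sites("TTA"), c(s_sites = 2 / 3, n_sites = 5 / 3))
  expect_equal(ng86_sites("TGG"), c(s_sites = 0, n_sites = 7 / 3))
  expect_error(ng86_sites("TAA"), "sense")
})

test_that("pairwise NG86 counts differences, symmetry and gap skipping", {
  r <- ng86_pair("TTT", "TTT")
  expect_equal(r$sd + r$nd, 0)
  expect_equal(r$flag, "no-differences")

  r <- ng86_pair("TTT", "TTA")
  expect_equal(r$sd, 0)
  expect_equal(r$nd, 1)
  expect_equal(r$s_sites, 0.5)
  expect_equal(r$n_sites, 13 / 6)

  expect_equal(ng86_pair("TTTAAA", "TTAAAG"),
               ng86_pair("TTAAAG", "TTTAAA"))

  # gap codon column dropped pairwise
  g <- ng86_pair("TTT---AAA", "TTAGGGAAA")
  expect_equal(g$n_codons, 2L)
  expect_equal(g$nd, 1)

  # two-hit codon: average over both step orderings
  # AAA (K) -> AGG (R): via AGA (R) one N + one S; via AAG (K) one S + one N
  two <- ng86_pair("AAA", "AGG")
  expect_equal(two$sd, 1)
  expect_equal(two$nd, 1)
})

test_that("the Jukes-Cantor correction has the right small-p expansion", {
  # one nonsynonymous difference over many codons: ka ~ pN (1 + 2 pN / 3)
  row_a <- strrep("AAG", 4000)
  row_b <- paste0("ATG", strrep("AAG", 3999))
  r <- ng86_pair(row_a, row_b)
  expect_equal(r$ka, r$p_n * (1 + 2 * r$p_n / 3), tolerance = 1e-3)
})

test_that("back-translation expands residues to codons and validates", {
  msa <- aligned_set(c(x = "M-K", y = "MLK"))
  cds <- c(x = "ATGAAA", y = "ATGCTGAAA")
  cm <- back_translate(msa, cds)
  expect_equal(cm[["x"]], "ATG---AAA")
  expect_equal(cm[["y"]], "ATGCTGAAA")
  expect_error(back_translate(msa, c(x = "ATGGAA", y = "ATGCTGAAA")),
               "residue 2")
  expect_error(back_translate(msa, c(y = "ATGCTGAAA")), "missing CDS")
  fam <- make_family(n_species = 3, codons = 50, seed = 6)
  cds2 <- setNames(gsub("-", "", unclass(fam$codon_msa)),
                   names(fam$codon_msa))
  expect_identical(unclass(back_translate(fam$protein_msa, cds2)),
                   unclass(fam$codon_msa))
})

test_that("Fitch reconstruction solves the hand examples", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  same <- aligned_set(c(A = "ATG", B = "ATG", C = "ATG", D = "ATG"), "codon")
  f <- fitch_ancestral(tr, same)
  expect_true(all(f$states == "ATG"))
  expect_equal(f$score, 0)

  split2 <- aligned_set(c(A = "AAA", B = "AAA", C = "AAG", D = "AAG"), "codon")
  f2 <- fitch_ancestral(tr, split2)
  expect_equal(f2$score, 1)
  expect_setequal(unique(f2$states[5:7, 1]), c("AAA", "AAG"))
})

test_that("SLAC counting reproduces the 4-leaf hand classification", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  msa <- aligned_set(c(A = "AAA", B = "AAA", C = "AAG", D = "AAG"), "codon")
  s <- kaks_slac(tr, msa)$summary
  expect_equal(s$sd, 1)                      # AAA<->AAG is synonymous (Lys)
  expect_equal(s$nd, 0)
  expect_equal(s$ka_ks, 0)
  star <- aligned_set(c(A = "ATG", B = "ATG", C = "ATG", D = "ATG"), "codon")
  s0 <- kaks_slac(tr, star)$summary
  expect_equal(s0$sd + s0$nd, 0)
  expect_equal(s0$flag, "no-differences")
})

test_that("dataset NG86 equals the pair for 2 rows and flags 0/0", {
  msa2 <- aligned_set(c(a = "TTTAAA", b = "TTAAAA"), "codon")
  ds <- kaks_ng86(msa2)
  pr <- ng86_pair("TTTAAA", "TTAAAA")
  expect_equal(ds$summary$ka, pr$ka)
  expect_equal(ds$summary$ks, pr$ks)
  msa3 <- aligned_set(c(a = "TTT", b = "TTT", c = "TTT"), "codon")
  expect_equal(kaks_ng86(msa3)$summary$flag, "no-differences")
})

test_that("partitions map through reference gaps and tile to the whole", {
  fam <- make_family(n_species = 3, r = 1, codons = 90, seed = 12)
  parts <- tibble::tibble(name = c("first", "rest"),
                          start_aa = c(1L, 31L), end_aa = c(30L, 90L))
  ref <- names(fam$codon_msa)[1]
  tab <- kaks_partition(fam$codon_msa, parts, reference_id = ref,
                        method = "ng86")
  expect_equal(tab$partition, c("All", "first", "rest"))
  whole <- tab[tab$partition == "All", ]
  expect_equal(sum(tab$sd[-1]), whole$sd)
  expect_equal(sum(tab$nd[-1]), whole$nd)

  # Table-3-like layout: 9 exons + 6 domains + All = 16 rows
  bounds <- sort(sample(2:89, 8))
  exons <- tibble::tibble(name = paste("Exon", 1:9),
                          start_aa = c(1L, bounds + 1L),
                          end_aa = c(bounds, 90L))
  dbounds <- sort(sample(2:89, 5))
  doms <- tibble::tibble(name = paste("Dom", 1:6),
                         start_aa = c(1L, dbounds + 1L),
                         end_aa = c(dbounds, 90L))
  tab16 <- kaks_partition(fam$codon_msa, rbind(exons, doms),
                          reference_id = ref, method = "ng86")
  expect_equal(nrow(tab16), 16L)
  expect_error(kaks_partition(fam$codon_msa,
                              tibble::tibble(name = "bad", start_aa = 1L,
                                             end_aa = 91L),
                              reference_id = ref, method = "ng86"),
               "beyond")

  # a gapped reference maps residue coordinates through its gaps
  msa <- aligned_set(c(ref = "ATG---AAATTT", oth = "ATGCCCAAATTA"), "codon")
  tabg <- kaks_partition(msa, tibble::tibble(name = "tail", start_aa = 2L,
                                             end_aa = 3L),
                         reference_id = "ref", method = "ng86")
  expect_equal(tabg$n_codons[tabg$partition == "tail"], 2L)
})

test_that("estimated ratios order with generative omega", {
  ranks <- vapply(1:5, function(s) {
    lo <- make_family(n_species = 3, r = 1, codons = 150, seed = s,
                      omega = 0.05, height = 0.1)
    hi <- make_family(n_species = 3, r = 1, codons = 150, seed = s,
                      omega = 0.5, height = 0.1)
    kaks_ng86(hi$codon_msa)$summary$ka_ks >
      kaks_ng86(lo$codon_msa)$summary$ka_ks
  }, logical(1))
  expect_true(all(ranks))
})
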