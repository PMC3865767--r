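test_that("species trees are Yule-shaped, rescaled and deterministic", {
  tr <- simulate_species_tree(3, 0.25, seed = 5)
  expect_equal(length(tr$tip.label), 3L)
  expect_identical(ape::write.tree(simulate_species_tree(7, 0.25, seed = 9)),
                   ape::write.tree(simulate_species_tree(7, 0.25, seed = 9)))
  expect_error(simulate_species_tree(2, 0.25, 1), ">= 3")
  # rescaling contract: mean root-to-tip ~ total_height (Monte-Carlo)
  depths <- vapply(1:50, function(s) {
    tr <- simulate_species_tree(20, 0.5, seed = s)
    mean(ape::node.depth.edgelength(tr)[1:20])
  }, numeric(1))
  expect_true(mean(depths) >= 0.45 && mean(depths) <= 0.55)
})

test_that("the duplication graft doubles leaves and scales clade B by r", {
  sp <- simulate_species_tree(5, 0.25, seed = 2)
  g1 <- graft_duplication(sp, r = 1, stem = 0.1)
  expect_equal(length(g1$tip.label), 10L)
  expect_setequal(sub("_[AB]$", "", g1$tip.label), sp$tip.label)
  sum_clade <- function(tree, suffix) {
    node <- ape::getMRCA(tree, grep(suffix, tree$tip.label))
    sub <- ape::extract.clade(tree, node)
    sum(sub$edge.length)
  }
  expect_equal(sum_clade(g1, "_A$"), sum_clade(g1, "_B$"), tolerance = 1e-9)
  g2 <- graft_duplication(sp, r = 2, stem = 0.1)
  expect_equal(sum_clade(g2, "_B$"), 2 * sum_clade(g2, "_A$"),
               tolerance = 1e-9)
  expect_error(graft_duplication(sp, r = 0), "> 0")
})

test_that("codon simulation honours zero branches, omega = 0 and the seed", {
  flat <- read_newick("((a:0,b:0):0,(c:0,d:0):0);")
  params <- sim_params(tree = flat, n_species = 4, codon_length = 30, seed = 3,
                       omega = tibble::tibble(name = "all", start = 1,
                                              end = 30, omega = 0.5))
  sim <- simulate_codon_msa(flat, params)
  expect_equal(length(unique(unclass(sim$alignment))), 1L)

  # omega = 0 forbids nonsynonymous change: all rows translate identically
  deep <- read_newick("((a:0.4,b:0.4):0.2,(c:0.4,d:0.4):0.2);")
  p0 <- sim_params(tree = deep, n_species = 4, codon_length = 40, seed = 8,
                   omega = tibble::tibble(name = "all", start = 1, end = 40,
                                          omega = 0))
  sim0 <- simulate_codon_msa(deep, p0)
  prot <- translate_alignment(sim0$alignment)
  expect_equal(length(unique(unclass(prot))), 1L)
  expect_gt(p_distance(sim0$alignment, "a", "c"), 0)  # synonymous change ran

  s1 <- simulate_codon_msa(deep, p0)
  expect_identical(unclass(s1$alignment), unclass(sim0$alignment))
})

test_that("pairwise divergence tracks the Jukes-Cantor expectation", {
  # two leaves at distance 0.2 nt subs/site, omega = 1, kappa = 1: the process
  # is nucleotide-JC apart from stop-codon exclusion, so the mean p-distance
  # should sit near 3/4 (1 - exp(-4/3 * 0.2)) = 0.1697
  two <- read_newick("(x:0.1,y:0.1);")
  ps <- vapply(1:60, function(s) {
    params <- sim_params(tree = two, n_species = 3, codon_length = 60,
                         seed = s, kappa = 1,
                         omega = tibble::tibble(name = "all", start = 1,
                                                end = 60, omega = 1))
    sim <- simulate_codon_msa(two, params)
    p_distance(sim$alignment, "x", "y")
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-4 / 3 * 0.2))
  # 60 replicates x 180 nt: binomial se of the mean ~ 0.0036; allow 4 se plus
  # a small stop-exclusion deviation
  expect_equal(mean(ps), expected, tolerance = 0.02 / expected)
})

test_that("architecture decoys carry their designed features", {
  b <- decorate_architecture("bace-like", seed = 21)
  ct <- decorate_architecture("cathepsin-like", seed = 22)
  expect_true(predict_signal_peptide(b)$present)
  expect_true(predict_ctm(b)$present)
  expect_equal(nrow(find_active_site_motifs(b)), 1L)
  expect_true(predict_signal_peptide(ct)$present)
  expect_false(predict_ctm(ct)$present)
  expect_equal(nrow(find_active_site_motifs(ct)), 2L)
  expect_gt(nchar(b), nchar(ct))
  expect_identical(decorate_architecture("bace-like", seed = 21), b)
})
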