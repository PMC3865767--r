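test_that("self-alignment is perfect and score is symmetric", {
  s <- random_protein(30, seed = 1)
  r <- local_align(s, s)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$gap_pct, 0)
  expect_equal(r$aligned_length, 30L)
  a <- random_protein(25, seed = 2); b <- random_protein(40, seed = 3)
  expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  expect_error(local_align("", "MK"), "empty")
})

test_that("hydropathy profiles match direct arithmetic", {
  expect_equal(hydropathy_profile(strrep("I", 9), 3), rep(4.5, 9))
  expect_equal(hydropathy_profile(strrep("R", 9), 3), rep(-4.5, 9))
  seq9 <- "MKVLAIRDE"
  kd <- c(M = 1.9, K = -3.9, V = 4.2, L = 3.8, A = 1.8, I = 4.5, R = -4.5,
          D = -3.5, E = -3.5)
  prof <- hydropathy_profile(seq9, 9)
  expect_equal(prof[5], mean(kd))           # full window at the centre
  expect_equal(prof[1], mean(kd[1:5]))      # truncated window at the end
  expect_error(hydropathy_profile("MKV", 5), "exceeds")
  expect_error(hydropathy_profile("MKVLA", 4), "odd")
})

test_that("signal peptide and CTM windows behave at their thresholds", {
  sp_yes <- paste0("M", strrep("L", 10), random_protein(30, seed = 4))
  expect_true(predict_signal_peptide(sp_yes)$present)
  sp_no <- paste0(strrep("DE", 20), random_protein(20, seed = 5))
  expect_false(predict_signal_peptide(sp_no)$present)
  expect_error(predict_signal_peptide("MKVLA"), "25")

  ctm_yes <- paste0(random_protein(100, seed = 6), strrep("LVIF", 6),
                    random_protein(25, seed = 7))
  expect_true(predict_ctm(ctm_yes)$present)
  span <- predict_ctm(ctm_yes)
  expect_gte(span$start, nchar(ctm_yes) - 79)
  ctm_no <- paste0(random_protein(60, seed = 8), strrep("DEKN", 25))
  expect_false(predict_ctm(ctm_no)$present)
})

test_that("PROSITE matching finds non-overlapping leftmost hits", {
  expect_equal(prosite_to_regex("D-[ST]-G"), "D[ST]G")
  expect_equal(prosite_to_regex("x(2)-A"), ".{2}A")
  expect_equal(prosite_to_regex("{P}-A"), "[^P]A")
  expect_error(prosite_to_regex("D-[st]-G"), "malformed")

  ctx <- "LLVDTGSSNLWV"                      # full PS00141 context
  noctx <- "EEPDSGTSELWV"                    # D-[ST]-G core, context rejected
  seq <- paste0(random_protein(20, seed = 9), ctx,
                random_protein(20, seed = 10), noctx,
                random_protein(20, seed = 11), ctx)
  hits <- find_active_site_motifs(seq)
  expect_equal(nrow(hits), 2L)
  expect_true(all(diff(hits$start) > 0))
  expect_equal(substr(seq, hits$asp_pos[1], hits$asp_pos[1]), "D")
})

test_that("reciprocal best hits resolve identity and asymmetry", {
  db <- c(p1 = random_protein(60, seed = 12),
          p2 = random_protein(60, seed = 13))
  q <- setNames(db[["p2"]], "q")
  r <- reciprocal_best_hit(q, db, home_db = c(q, other = db[["p1"]]),
                           query_id = "q")
  expect_equal(r$best_id, "p2")
  expect_true(r$reciprocal)
})

test_that("classification separates decoys and grades borderline evidence", {
  bace_refs <- setNames(vapply(1:2, decorate_architecture, character(1),
                               kind = "bace-like"), c("br1", "br2"))
  cath_refs <- setNames(vapply(3:5, decorate_architecture, character(1),
                               kind = "cathepsin-like"), c("cr1", "cr2", "cr3"))
  cands <- c(bx = decorate_architecture("bace-like", 31),
             cx = decorate_architecture("cathepsin-like", 32))
  v <- triage_classify(cands, bace_refs, cath_refs)
  expect_equal(v$label[v$id == "bx"], "bace-like")
  expect_equal(v$label[v$id == "cx"], "cathepsin-like")
  expect_false(v$ctm_ok[v$id == "cx"])
  expect_false(v$length_ok[v$id == "cx"])

  # mandatory criteria met but motif count off -> borderline
  bb <- decorate_architecture("bace-like", 33)
  extra <- paste0(substr(bb, 1, 150), "LLVDTGSSNLWV",
                  substr(bb, 163, nchar(bb)))
  expect_equal(nrow(find_active_site_motifs(extra)), 2L)
  v2 <- triage_classify(c(bx = extra), bace_refs, cath_refs)
  expect_equal(v2$label, "borderline")
})

test_that("relaxing thresholds never demotes a bace-like call", {
  bace_refs <- setNames(vapply(6:7, decorate_architecture, character(1),
                               kind = "bace-like"), c("br1", "br2"))
  cath_refs <- setNames(vapply(8:9, decorate_architecture, character(1),
                               kind = "cathepsin-like"), c("cr1", "cr2"))
  cand <- c(bx = decorate_architecture("bace-like", 41))
  strict <- triage_classify(cand, bace_refs, cath_refs)
  relaxed <- triage_classify(cand, bace_refs, cath_refs,
                             criteria = triage_criteria(
                               min_identity_pct = 20, min_coverage_frac = 0.4,
                               max_gap_pct = 40, min_length_delta = 20))
  rank <- c(`cathepsin-like` = 1, borderline = 2, `bace-like` = 3)
  expect_gte(rank[relaxed$label], rank[strict$label])
})

test_that("substrate presence/absence follows the thresholds", {
  substrate <- c(sub1 = random_protein(80, seed = 20))
  unrelated <- c(x1 = random_protein(90, seed = 21))
  proteomes <- list(
    has_it = c(unrelated, hit = substrate[[1]]),
    empty = character(0),
    unrelated_only = unrelated)
  pa <- presence_absence(substrate, proteomes)
  expect_true(pa$present[pa$proteome == "has_it"])
  expect_false(pa$present[pa$proteome == "empty"])
  expect_false(pa$present[pa$proteome == "unrelated_only"])
})
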