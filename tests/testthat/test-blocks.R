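test_that("column information matches its closed forms", {
  expect_equal(column_information(rep("D", 8)), log2(20))
  expect_equal(column_information(aa20), 0)
  expect_equal(column_information(c(rep("D", 4), rep("E", 4))), log2(20) - 1)
  expect_equal(column_information(rep("D", 10), "small-sample"),
               log2(20) - 19 / (2 * log(2) * 10))
  expect_equal(column_information(aa20, "small-sample"), 0)  # floored
  expect_error(column_information(character(0)), "empty")
  expect_equal(column_information(c("D", "-", "D")), log2(20))  # gaps excluded
})

test_that("a fully conserved gapless alignment is one block", {
  msa <- aligned_set(setNames(rep(strrep("DKLMNPQR", 3), 4), paste0("s", 1:4)))
  b <- find_blocks(msa, min_width = 6)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_col, b$end_col), c(1L, 24L))
})

test_that("an embedded invariant run is recovered exactly", {
  # columns 5-14 invariant; all other columns carry a gap in some row, so they
  # can never be block-eligible regardless of their information content
  set.seed(3)
  core <- paste(sample(aa20, 10, replace = TRUE), collapse = "")
  rows <- vapply(1:6, function(i) {
    left <- paste(sample(aa20, 4, replace = TRUE), collapse = "")
    right <- paste(sample(aa20, 6, replace = TRUE), collapse = "")
    substr(left, (i %% 4) + 1, (i %% 4) + 1) <- "-"
    substr(right, (i %% 6) + 1, (i %% 6) + 1) <- "-"
    paste0(left, core, right)
  }, character(1))
  msa <- aligned_set(setNames(rows, paste0("s", 1:6)))
  b <- find_blocks(msa, min_width = 8)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_col, b$end_col), c(5L, 14L))
})

test_that("block extraction is invariant to row order and excluded rows", {
  fam <- make_family(n_species = 3, codons = 100, seed = 14)
  b1 <- find_blocks(fam$protein_msa, min_mean_ic = 1.0)
  perm <- sample(names(fam$protein_msa))
  b2 <- find_blocks(fam$protein_msa[perm], min_mean_ic = 1.0)
  strip <- function(x) {
    attr(x, "rows") <- NULL; attr(x, "column_ic") <- NULL
    as.data.frame(x)
  }
  expect_equal(strip(b1), strip(b2))
  expect_setequal(attr(b1, "rows"), attr(b2, "rows"))
  # appending an all-gap-heavy row changes nothing once it is filtered out
  gappy <- c(unclass(fam$protein_msa),
             junk = paste0(strrep("-", 80), substr(fam$protein_msa[[1]], 81, 100)))
  b3 <- find_blocks(aligned_set(gappy), min_mean_ic = 1.0)
  expect_equal(strip(b1), strip(b3))
  expect_false("junk" %in% attr(b3, "rows"))
})

test_that("raising the information threshold never adds blocked columns", {
  fam <- make_family(n_species = 4, codons = 120, seed = 15, height = 0.6)
  total <- vapply(c(0.5, 1.5, 2.5, 3.5), function(th) {
    b <- find_blocks(fam$protein_msa, min_mean_ic = th)
    sum(b$width)
  }, numeric(1))
  expect_true(all(diff(total) <= 0))
})

test_that("logo heights are frequency-weighted information", {
  msa <- aligned_set(c(a = "DDE", b = "DEE", c = "DDE"))
  lt <- logo_table(msa, 1, 3)
  expect_equal(lt$height[lt$pos == 1], log2(20))
  col2 <- lt[lt$pos == 2, ]
  expect_equal(sum(col2$height), column_information(c("D", "D", "E")))
  expect_equal(sort(col2$residue), c("D", "E"))
  b <- find_blocks(aligned_set(c(a = "DKLMNP", b = "DKLMNP")), min_width = 3,
                   min_mean_ic = 2)
  lt2 <- logo_table(aligned_set(c(a = "DKLMNP", b = "DKLMNP")),
                    b$start_col[1], b$end_col[1], rows = attr(b, "rows"))
  ic <- attr(b, "column_ic")
  sums <- vapply(split(lt2$height, lt2$pos), sum, numeric(1))
  expect_equal(unname(sums), unname(ic[b$start_col[1]:b$end_col[1]]))
})
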