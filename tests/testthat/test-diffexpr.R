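make_counts <- function(mat, samples = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(mat)))
  dimnames(mat) <- list(paste0("g", seq_len(nrow(mat))), samples)
  mat
}

test_that("CPM normalization scales each sample to one million", {
  m <- make_counts(matrix(c(10L, 90L, 0L, 5L, 45L, 0L), ncol = 2))
  norm <- normalize_counts(m)
  cpm <- 2^as.matrix(norm[, -1]) - 1
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(unname(unlist(norm[3, -1])), c(0, 0)) # all-zero gene stays 0
  # proportional columns normalize identically
  expect_equal(norm$s1, norm$s2)
})

test_that("zero-sum samples are rejected by name", {
  m <- make_counts(matrix(c(1L, 2L, 0L, 0L), ncol = 2),
                   samples = c("ok", "empty"))
  expect_error(normalize_counts(m), "empty")
})

test_that("strong planted effects are flagged with the right direction", {
  set.seed(21)
  base <- matrix(rnbinom(600, mu = 300, size = 20), ncol = 6)
  base[1, 4:6] <- rnbinom(3, mu = 300 * 8, size = 20) # log2FC ~ 3 up
  base[2, 4:6] <- rnbinom(3, mu = 300 / 8, size = 20) # down
  m <- make_counts(base)
  d <- call_degs(m, rep(c("A", "B"), each = 3), "A", "B")
  expect_identical(d$direction[1], "up")
  expect_identical(d$direction[2], "down")
  expect_true(all(glance(d)$n_flagged == glance(d)$n_up + glance(d)$n_down))
})

test_that("a gene identical across groups is never flagged", {
  m <- make_counts(matrix(rep(c(50L, 100L), each = 6), nrow = 2,
                          byrow = TRUE))
  d <- call_degs(m, rep(c("A", "B"), each = 3), "A", "B")
  expect_equal(d$log2fc, c(0, 0))
  expect_false(any(d$flagged))
})

test_that("fewer than two replicates is an error", {
  m <- make_counts(matrix(1:9, ncol = 3))
  expect_error(call_degs(m, c("A", "B", "B"), "A", "B"), "2 replicates")
})

test_that("relaxing the p threshold never shrinks the flagged set", {
  g <- gen_counts(tiny_config(seed = 3))
  d1 <- call_degs(g$counts, g$groups, "Con", "TNF", p_cutoff = 0.01)
  d2 <- call_degs(g$counts, g$groups, "Con", "TNF", p_cutoff = 0.05)
  d3 <- call_degs(g$counts, g$groups, "Con", "TNF", p_cutoff = 0.2)
  expect_true(all(d1$gene[d1$flagged] %in% d2$gene[d2$flagged]))
  expect_true(all(d2$gene[d2$flagged] %in% d3$gene[d3$flagged]))
})

test_that("counter-regulation follows the opposite-direction definition", {
  mk <- function(lfc, p) {
    structure(tibble::tibble(
      gene = paste0("g", seq_along(lfc)), log2fc = lfc, p_value = p,
      flagged = abs(lfc) >= 1 & p < 0.05,
      direction = ifelse(abs(lfc) >= 1 & p < 0.05,
                         ifelse(lfc > 0, "up", "down"), NA_character_)),
      class = c("deg_table", "tbl_df", "tbl", "data.frame"))
  }
  d1 <- mk(c(2, 1.5, -2, 0.2), c(0.001, 0.01, 0.01, 0.5))
  d2 <- mk(c(-1.5, 1.2, -1.1, -3), c(0.01, 0.01, 0.01, 0.001))
  # g1 reversed, g2 same direction, g3 same direction, g4 not flagged in d1
  expect_identical(counter_regulated(d1, d2), "g1")
  expect_identical(counter_regulated(d1, d2), counter_regulated(d2, d1))
})

test_that("mismatched gene universes raise an informative error", {
  g <- gen_counts(tiny_config(seed = 5))
  d1 <- call_degs(g$counts, g$groups, "Con", "TNF")
  d2 <- call_degs(g$counts[-1, ], g$groups, "TNF", "TNF_WBT")
  expect_error(counter_regulated(d1, d2), "universes differ")
})

test_that("planted counter-regulated genes are recovered exactly", {
  g <- gen_counts(tiny_config(seed = 8, dispersion = 0.01))
  d1 <- call_degs(g$counts, g$groups, "Con", "TNF")
  d2 <- call_degs(g$counts, g$groups, "TNF", "TNF_WBT")
  got <- counter_regulated(d1, d2)
  expect_setequal(got, g$ground_truth$counter)
  expect_true(all(got %in% d1$gene[d1$flagged]))
  expect_true(all(got %in% d2$gene[d2$flagged]))
})
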