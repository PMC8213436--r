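pred_row <- function(sim, qed, constituent = "c1", gene = "g1") {
  tibble::tibble(constituent = constituent, gene = gene,
                 similarity = sim, qed = qed)
}

test_that("similarity and QED cutoffs are inclusive at the stated bounds", {
  expect_equal(nrow(filter_predictions(pred_row(0.85, 0.60))), 1)
  expect_equal(nrow(filter_predictions(pred_row(0.79, 0.60))), 0)
  expect_equal(nrow(filter_predictions(pred_row(0.80, 0.60))), 1)
  expect_equal(nrow(filter_predictions(pred_row(0.85, 0.489))), 0)
  expect_equal(nrow(filter_predictions(pred_row(0.85, 0.49))), 1)
})

test_that("out-of-range scores fail validation with the row index", {
  bad <- dplyr::bind_rows(pred_row(0.9, 0.5), pred_row(1.2, 0.5, gene = "g2"))
  expect_error(filter_predictions(bad), "row\\(s\\): 2")
})

test_that("filtering deduplicates pairs and is idempotent", {
  p <- dplyr::bind_rows(pred_row(0.9, 0.6), pred_row(0.9, 0.6),
                        pred_row(0.85, 0.7, gene = "g2"))
  f1 <- filter_predictions(p)
  expect_equal(nrow(f1), 2)
  expect_identical(as.data.frame(filter_predictions(f1)), as.data.frame(f1))
})

test_that("hub-target frequency counts distinct hub genes only", {
  preds <- tibble::tibble(
    constituent = c("c1", "c1", "c1", "c2", "c2", "c3"),
    gene = c("g1", "g2", "g3", "g2", "g2", "g9"),
    similarity = 0.9, qed = 0.6)
  info <- tibble::tibble(constituent = c("c1", "c2", "c3", "c4"),
                         content = c(10, 5, 2, 1),
                         herb = c("h1", "h1", "h2", "h2"))
  sc <- hub_target_frequency(preds, hubs = c("g2", "g3", "g9"), info)
  expect_equal(sc$frequency[match(c("c1", "c2", "c3", "c4"), sc$constituent)],
               c(2L, 1L, 1L, 0L)) # c2 duplicates collapse; c4 kept at 0
})

test_that("dual-median selection is strict on both medians", {
  sc <- tibble::tibble(constituent = c("a", "b", "c"),
                       frequency = c(5L, 3L, 1L),
                       content = c(10, 2, 8))
  sel <- select_key_constituents(sc)
  expect_identical(sel$constituent[sel$selected], "a")
  expect_equal(attr(sel, "median_frequency"), 3)
  expect_equal(attr(sel, "median_content"), 8)
})

test_that("identical constituents yield an empty selection", {
  sc <- tibble::tibble(constituent = letters[1:4], frequency = 2L,
                       content = 7)
  expect_equal(sum(select_key_constituents(sc)$selected), 0)
})

test_that("selection respects the strict-median cardinality bound", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    sc <- tibble::tibble(constituent = paste0("c", 1:n),
                         frequency = sample(0:8, n, replace = TRUE),
                         content = stats::rlnorm(n, 3, 1))
    sel <- select_key_constituents(sc)
    expect_lte(sum(sel$selected), ceiling(n / 2))
    expect_true(all(sel$constituent[sel$selected] %in% sc$constituent))
  }
})

test_that("selection is invariant under increasing transforms of content", {
  set.seed(14)
  sc <- tibble::tibble(constituent = paste0("c", 1:15),
                       frequency = sample(0:6, 15, replace = TRUE),
                       content = stats::rlnorm(15, 2, 1))
  sel <- select_key_constituents(sc)$selected
  sc2 <- dplyr::mutate(sc, content = log1p(content) * 100)
  expect_identical(select_key_constituents(sc2)$selected, sel)
})

test_that("the planted key block is recovered with its herb roll-up", {
  cfg <- tiny_config(seed = 9)
  ms <- gen_library_and_features(cfg)
  nw <- gen_network_inputs(cfg)
  filtered <- filter_predictions(nw$target_map)
  info <- dplyr::select(
    dplyr::filter(ms$library, compound %in% nw$target_map$constituent),
    constituent = "compound", content = "response", herb = "herb")
  sel <- select_key_constituents(
    hub_target_frequency(filtered, nw$ground_truth$hub_tier, info))
  expect_setequal(sel$constituent[sel$selected], nw$ground_truth$key_constituents)
  gl <- glance(sel)
  expect_equal(gl$n_selected, cfg$n_key)
  roll <- attr(sel, "herb_rollup")
  expect_equal(sum(roll$n_selected), cfg$n_key)
})
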