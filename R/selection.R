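# Constituent filtering and the dual-median key-constituent rule.

#' Filter constituent-target predictions by similarity and drug-likeness
#'
#' Keeps predictions with structural-similarity score >= `min_similarity`
#' (moderate-to-high similarity) and QED >= `min_qed`; predictions strictly
#' below either bound are dropped. Rows are deduplicated to one per
#' (constituent, gene) pair first. The operation is idempotent.
#'
#' @param preds Tibble with columns `constituent`, `gene`, `similarity`,
#'   `qed` (both scores in \[0, 1\]).
#' @param min_similarity Similarity cutoff, default 0.80.
#' @param min_qed QED cutoff, default 0.49.
#' @return The filtered prediction tibble.
#' @export
filter_predictions <- function(preds, min_similarity = 0.80, min_qed = 0.49) {
  preds <- tibble::as_tibble(preds)
  stopifnot(all(c("constituent", "gene", "similarity", "qed") %in% names(preds)))
  bad <- which(preds$similarity < 0 | preds$similarity > 1 |
                 preds$qed < 0 | preds$qed > 1 |
                 is.na(preds$similarity) | is.na(preds$qed))
  if (length(bad) > 0L) {
    stop("similarity/QED out of [0, 1] at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  preds |>
    dplyr::distinct(.data$constituent, .data$gene, .keep_all = TRUE) |>
    dplyr::filter(.data$similarity >= min_similarity, .data$qed >= min_qed)
}

#' Hub-target binding frequency per constituent
#'
#' Frequency is the number of DISTINCT hub genes a constituent binds among
#' its (filtered) predicted targets. Constituents with no hub target are
#' retained with frequency 0, so the medians of the downstream selection are
#' taken over the full constituent panel.
#'
#' @param preds Filtered prediction tibble (`constituent`, `gene`).
#' @param hubs Non-empty character vector of hub gene symbols.
#' @param constituent_info Tibble with one row per constituent: `constituent`,
#'   `content` (MS response or other abundance proxy, >= 0) and optionally
#'   `herb`.
#' @return A tibble with columns `constituent`, `frequency`, `content`,
#'   `herb`.
#' @export
hub_target_frequency <- function(preds, hubs, constituent_info) {
  stopifnot(length(hubs) > 0L)
  info <- tibble::as_tibble(constituent_info)
  stopifnot(all(c("constituent", "content") %in% names(info)),
            all(info$content >= 0))
  if (!"herb" %in% names(info)) info$herb <- NA_character_
  freq <- tibble::as_tibble(preds) |>
    dplyr::filter(.data$gene %in% hubs) |>
    dplyr::distinct(.data$constituent, .data$gene) |>
    dplyr::count(.data$constituent, name = "frequency")
  info |>
    dplyr::left_join(freq, by = "constituent") |>
    dplyr::mutate(frequency = as.integer(tidyr::replace_na(.data$frequency, 0L))) |>
    dplyr::select("constituent", "frequency", "content", "herb")
}

#' Dual-median key-constituent selection
#'
#' A constituent is a key constituent when its hub-target frequency and its
#' content both STRICTLY exceed the respective medians, medians taken over
#' all scored constituents. Because the rule is rank-based, the selection is
#' invariant under any strictly increasing transform of content.
#'
#' @param scores Tibble from [hub_target_frequency()] (`constituent`,
#'   `frequency`, `content`, optionally `herb`).
#' @return A `constituent_selection` tibble (scores plus a logical
#'   `selected` column) with the medians and per-herb roll-up of selected
#'   constituents as attributes; see [glance.constituent_selection()].
#' @export
select_key_constituents <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot(nrow(scores) >= 1L,
            all(c("constituent", "frequency", "content") %in% names(scores)))
  if (!"herb" %in% names(scores)) scores$herb <- NA_character_
  med_f <- stats::median(scores$frequency)
  med_c <- stats::median(scores$content)
  scores$selected <- scores$frequency > med_f & scores$content > med_c
  herb_rollup <- scores |>
    dplyr::filter(.data$selected) |>
    dplyr::count(.data$herb, name = "n_selected") |>
    dplyr::arrange(dplyr::desc(.data$n_selected))
  structure(scores,
            class = c("constituent_selection", class(scores)),
            median_frequency = med_f, median_content = med_c,
            herb_rollup = herb_rollup)
}

#' @method tidy constituent_selection
#' @export
tidy.constituent_selection <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a key-constituent selection
#'
#' @param x A `constituent_selection` from [select_key_constituents()].
#' @param ... Unused.
#' @return A tibble with the panel size, the two medians, the number of
#'   selected key constituents and the number of distinct contributing herbs.
#' @method glance constituent_selection
#' @export
glance.constituent_selection <- function(x, ...) {
  roll <- attr(x, "herb_rollup")
  tibble::tibble(
    n_scored = nrow(x),
    median_frequency = attr(x, "median_frequency"),
    median_content = attr(x, "median_content"),
    n_selected = sum(x$selected),
    n_herbs = sum(!is.na(roll$herb))
  )
}
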