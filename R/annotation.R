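#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
#' @examples
#' ppm_error(823.3022, 823.301906)
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

.within_tolerance <- function(error_mda, error_ppm, tol_mda, tol_ppm) {
  abs(error_mda) <= tol_mda | abs(error_ppm) <= tol_ppm
}

#' Match observed MS features against a compound library
#'
#' Every (feature, compound, adduct) combination of matching polarity whose
#' absolute mass error is within `tol_mda` mDa OR within `tol_ppm` ppm (both
#' bounds inclusive) is emitted; a feature may therefore carry several
#' candidate annotations, and no winner is picked automatically. Retention
#' time is carried through but never used for matching.
#'
#' @param features Tibble of observed ions with columns `mz`, `polarity`
#'   (`"+"`/`"-"`) and optionally `feature_id`, `rt`, `response`.
#' @param library Compound library tibble with columns `compound`, `formula`
#'   and optionally `herb`, `response`.
#' @param adducts Adduct registry, default [adduct_rules()].
#' @param tol_mda,tol_ppm Tolerance bounds; defaults 5 mDa / 10 ppm.
#' @return A tibble with one row per candidate match (feature columns plus
#'   `compound`, `formula`, `herb`, `adduct`, `theo_mz`, `error_mda`,
#'   `error_ppm`), sorted by absolute error with compound name as tie-breaker.
#' @export
match_features <- function(features, library, adducts = adduct_rules(),
                           tol_mda = 5, tol_ppm = 10) {
  stopifnot(tol_mda > 0, tol_ppm > 0)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("mz", "polarity") %in% names(features)))
  stopifnot(all(features$mz > 0), all(features$polarity %in% c("+", "-")))
  empty <- tibble::tibble(
    feature_id = integer(0), rt = numeric(0), mz = numeric(0),
    polarity = character(0), response = numeric(0), compound = character(0),
    formula = character(0), herb = character(0), adduct = character(0),
    theo_mz = numeric(0), error_mda = numeric(0), error_ppm = numeric(0)
  )
  if (is.null(library) || nrow(library) == 0L) {
    warning("empty compound library: no annotations produced", call. = FALSE)
    return(empty)
  }
  library <- tibble::as_tibble(library)
  stopifnot(all(c("compound", "formula") %in% names(library)))
  if (!"herb" %in% names(library)) library$herb <- NA_character_
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- seq_len(nrow(features))
  }
  if (!"rt" %in% names(features)) features$rt <- NA_real_
  if (!"response" %in% names(features)) features$response <- NA_real_

  library$mass <- vapply(library$formula, monoisotopic_mass, numeric(1),
                         USE.NAMES = FALSE)
  theo <- tidyr::crossing(
    library[, c("compound", "formula", "herb", "mass")],
    adducts
  ) |>
    dplyr::mutate(theo_mz = .data$multiplicity * .data$mass + .data$delta)

  out <- dplyr::inner_join(
    features[, c("feature_id", "rt", "mz", "polarity", "response")],
    dplyr::select(theo, "compound", "formula", "herb", adduct = "label",
                  "polarity", "theo_mz"),
    by = "polarity", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      error_mda = 1e3 * (.data$mz - .data$theo_mz),
      error_ppm = ppm_error(.data$mz, .data$theo_mz)
    ) |>
    dplyr::filter(.within_tolerance(.data$error_mda, .data$error_ppm,
                                    tol_mda, tol_ppm)) |>
    dplyr::arrange(abs(.data$error_mda), .data$compound, .data$adduct)
  out
}

#' Assign fragment ions by neutral-loss combinations
#'
#' Searches multisets of neutral losses (up to `max_losses` losses in total,
#' each individual loss used at most `max_per_loss` times) whose summed mass
#' explains `precursor_mz - fragment m/z` within the matching tolerance
#' (`tol_mda` mDa OR `tol_ppm` ppm, relative to the implied theoretical
#' fragment m/z). The best-fitting (smallest absolute error) multiset is
#' reported per fragment; unexplained fragments come back unassigned.
#'
#' @param precursor_mz Theoretical precursor m/z (one value).
#' @param fragment_mzs Numeric vector of observed fragment m/z.
#' @param losses Neutral-loss table, default [neutral_losses()].
#' @param max_losses Total losses per combination (default 4).
#' @param max_per_loss Repeats allowed per loss (default 3).
#' @param tol_mda,tol_ppm Tolerance bounds; defaults 5 mDa / 10 ppm.
#' @return Tibble with columns `fragment_mz`, `loss_label` (e.g. `"-2rha"`,
#'   NA when unassigned), `theo_mz`, `error_mda`, `error_ppm`, `n_losses`.
#' @export
annotate_fragments <- function(precursor_mz, fragment_mzs,
                               losses = neutral_losses(),
                               max_losses = 4L, max_per_loss = 3L,
                               tol_mda = 5, tol_ppm = 10) {
  stopifnot(length(precursor_mz) == 1L, precursor_mz > 0,
            nrow(losses) > 0L, max_losses >= 1L)
  losses <- tibble::as_tibble(losses)
  # Enumerate loss multisets once: counts per loss in 0..max_per_loss with
  # total in 1..max_losses.
  grids <- rep(list(0:max_per_loss), nrow(losses))
  names(grids) <- losses$label
  combos <- expand.grid(grids)
  tot <- rowSums(combos)
  combos <- combos[tot >= 1L & tot <= max_losses, , drop = FALSE]
  combo_mass <- as.matrix(combos) %*% losses$mass
  combo_label <- unname(apply(combos, 1L, function(cnt) {
    used <- cnt > 0
    paste0("-", ifelse(cnt[used] > 1L, cnt[used], ""), losses$label[used],
           collapse = "")
  }))
  combo_n <- rowSums(combos)

  assign_one <- function(fmz) {
    theo <- precursor_mz - combo_mass[, 1L]
    ok <- theo > 0
    err_mda <- 1e3 * (fmz - theo)
    err_ppm <- 1e6 * (fmz - theo) / theo
    hit <- ok & .within_tolerance(err_mda, err_ppm, tol_mda, tol_ppm)
    if (!any(hit)) {
      return(tibble::tibble(fragment_mz = fmz, loss_label = NA_character_,
                            theo_mz = NA_real_, error_mda = NA_real_,
                            error_ppm = NA_real_, n_losses = NA_integer_))
    }
    best <- which(hit)[which.min(abs(err_mda[hit]))]
    tibble::tibble(fragment_mz = fmz, loss_label = combo_label[best],
                   theo_mz = theo[best], error_mda = err_mda[best],
                   error_ppm = err_ppm[best],
                   n_losses = as.integer(combo_n[best]))
  }
  purrr::map_dfr(fragment_mzs, assign_one)
}
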