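# Over-representation analysis: exact hypergeometric upper tail with
# Benjamini-Hochberg control. This is a local stand-in for web-service
# enrichment: pathway membership comes from user-supplied GMT collections.

#' Upper-tail hypergeometric p-value
#'
#' Exact probability of drawing at least `k` genes of a `K`-gene set when
#' sampling `n` genes without replacement from a universe of `N`.
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return `P(X >= k)` for X ~ Hypergeometric(N, K, n).
#' @export
#' @examples
#' hypergeom_p(5, 5, 5, 20) # 1 / choose(20, 5)
hypergeom_p <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1, K <= N, n <= N, k <= min(K, n))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in the original order (monotone, bounded by 1).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each set of a collection for over-representation in the query via
#' the exact hypergeometric upper tail, then controls the FDR across the
#' tested (overlapping) sets with Benjamini-Hochberg. Query genes outside
#' the universe are dropped with a warning; sets without overlap are not
#' reported.
#'
#' @param query Character vector of query genes (e.g. hub genes).
#' @param collection Named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param universe Optional character vector; defaults to the union of all
#'   collection genes.
#' @param top Optional cap on the number of returned rows (by ascending p).
#' @return An `enrichment_table` tibble with columns `set`, `set_size`,
#'   `query_size`, `overlap`, `p_value`, `q_value`, `genes`, sorted by
#'   ascending p with set name as tie-breaker.
#' @export
enrich <- function(query, collection, universe = NULL, top = NULL) {
  stopifnot(is.list(collection), length(collection) > 0L,
            !is.null(names(collection)), all(nzchar(names(collection))))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("empty query gene set", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(collection, use.names = FALSE))
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap_dfr(collection, function(genes, nm) {
    genes <- intersect(unique(genes), universe)
    ov <- intersect(query, genes)
    if (length(ov) == 0L) return(NULL)
    tibble::tibble(
      set = nm, set_size = length(genes), query_size = n,
      overlap = length(ov),
      p_value = hypergeom_p(length(ov), length(genes), n, N),
      genes = paste(sort(ov), collapse = ";")
    )
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(set = character(0), set_size = integer(0),
                           query_size = integer(0), overlap = integer(0),
                           p_value = numeric(0), q_value = numeric(0),
                           genes = character(0))
  } else {
    rows$q_value <- bh_adjust(rows$p_value)
    rows <- dplyr::arrange(rows, .data$p_value, .data$set)
    rows <- dplyr::select(rows, "set", "set_size", "query_size", "overlap",
                          "p_value", "q_value", "genes")
    if (!is.null(top)) rows <- utils::head(rows, top)
  }
  structure(rows, class = c("enrichment_table", class(rows)),
            universe_size = N, query_size = n)
}

#' @method tidy enrichment_table
#' @export
tidy.enrichment_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance enrichment_table
#' @export
glance.enrichment_table <- function(x, ...) {
  tibble::tibble(
    n_sets_tested = nrow(x),
    n_significant = sum(x$q_value < 0.05),
    universe_size = attr(x, "universe_size"),
    query_size = attr(x, "query_size")
  )
}
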