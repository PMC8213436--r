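# Counts come in either as a genes x samples matrix with rownames, or as a
# tibble whose first column `gene` indexes the rows. Internally everything is
# a matrix; the public surface returns tibbles.
.as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot("gene" %in% names(counts))
    m <- as.matrix(counts[, setdiff(names(counts), "gene"), drop = FALSE])
    rownames(m) <- counts$gene
    m
  } else {
    stopifnot(is.matrix(counts), !is.null(rownames(counts)))
    counts
  }
}

#' Library-size normalization: counts per million, then log2
#'
#' Each sample is scaled so its counts sum to one million, then transformed
#' with `log2(x + 1)`.
#'
#' @param counts Genes x samples matrix (non-negative, with rownames) or a
#'   tibble with a `gene` column.
#' @return A tibble with a `gene` column and one log2-CPM column per sample.
#' @export
normalize_counts <- function(counts) {
  m <- .as_count_matrix(counts)
  stopifnot(all(m >= 0))
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("zero-sum sample(s): ", paste(colnames(m)[cs == 0], collapse = ", "),
         call. = FALSE)
  }
  cpm <- sweep(m, 2L, cs, "/") * 1e6
  out <- tibble::as_tibble(log2(cpm + 1))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)), out)
}

# Welch two-sided t-test on each row of a normalized matrix; constant rows
# (zero variance in both groups) are untestable and get p = 1.
.welch_row_test <- function(norm, idx_a, idx_b) {
  apply(norm, 1L, function(x) {
    a <- x[idx_a]; b <- x[idx_b]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(b, a)$p.value
  })
}

#' Call differentially expressed genes between two groups
#'
#' Normalizes to log2-CPM, computes per-gene log2 fold change as
#' `mean(group_b) - mean(group_a)` and a p-value from a two-sided Welch
#' t-test on the normalized values. A gene is flagged when
#' `|log2FC| >= lfc_cutoff` (fold change of 2 or more by default) and
#' `p < p_cutoff`. P-values are not adjusted: [bh_adjust()] is available for
#' callers who want FDR control.
#'
#' @param counts Genes x samples count matrix (rownames) or tibble with a
#'   `gene` column.
#' @param groups Character vector of group labels, one per sample column.
#' @param group_a,group_b Labels of the reference and comparison group; the
#'   reported fold change is `group_b` relative to `group_a`.
#' @param lfc_cutoff Absolute log2 fold-change threshold (default 1).
#' @param p_cutoff P-value threshold (default 0.05, strict).
#' @param test Row-wise testing function taking `(normalized_matrix, idx_a,
#'   idx_b)` and returning a p-value per gene; default Welch t.
#' @return A `deg_table` tibble with columns `gene`, `log2fc`, `p_value`,
#'   `flagged`, `direction` (`"up"`/`"down"` for flagged genes, NA otherwise)
#'   and the contrast metadata as attributes.
#' @export
call_degs <- function(counts, groups, group_a, group_b,
                      lfc_cutoff = 1, p_cutoff = 0.05,
                      test = .welch_row_test) {
  m <- .as_count_matrix(counts)
  stopifnot(length(groups) == ncol(m))
  idx_a <- which(groups == group_a)
  idx_b <- which(groups == group_b)
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    stop(sprintf("need >= 2 replicates per group (got %d in '%s', %d in '%s')",
                 length(idx_a), group_a, length(idx_b), group_b), call. = FALSE)
  }
  norm_tbl <- normalize_counts(m)
  norm <- as.matrix(norm_tbl[, -1L])
  rownames(norm) <- norm_tbl$gene

  log2fc <- unname(rowMeans(norm[, idx_b, drop = FALSE]) -
                     rowMeans(norm[, idx_a, drop = FALSE]))
  pval <- unname(test(norm, idx_a, idx_b))

  out <- tibble::tibble(
    gene = rownames(norm),
    log2fc = log2fc,
    p_value = pval,
    flagged = abs(log2fc) >= lfc_cutoff & pval < p_cutoff
  )
  out$direction <- ifelse(out$flagged, ifelse(out$log2fc > 0, "up", "down"),
                          NA_character_)
  structure(out,
            class = c("deg_table", class(out)),
            contrast = paste(group_b, "vs", group_a),
            group_a = group_a, group_b = group_b,
            lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff)
}

#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast"),
    n_genes = nrow(x),
    n_flagged = sum(x$flagged),
    n_up = sum(x$direction == "up", na.rm = TRUE),
    n_down = sum(x$direction == "down", na.rm = TRUE),
    lfc_cutoff = attr(x, "lfc_cutoff"),
    p_cutoff = attr(x, "p_cutoff")
  )
}

#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Genes counter-regulated between two contrasts
#'
#' A gene is counter-regulated when it is flagged in both contrasts with
#' opposite directions: induced in the first contrast and reversed in the
#' second (or vice versa). This is the treatment-reverses-disease signature.
#'
#' @param deg1,deg2 Two [call_degs()] tables over the same gene universe.
#' @return Sorted character vector of counter-regulated gene symbols.
#' @export
counter_regulated <- function(deg1, deg2) {
  miss1 <- setdiff(deg2$gene, deg1$gene)
  miss2 <- setdiff(deg1$gene, deg2$gene)
  if (length(miss1) > 0L || length(miss2) > 0L) {
    stop("gene universes differ; missing from first table: ",
         paste(utils::head(miss1, 10L), collapse = ", "),
         "; missing from second: ",
         paste(utils::head(miss2, 10L), collapse = ", "), call. = FALSE)
  }
  j <- dplyr::inner_join(
    tidy.deg_table(deg1)[, c("gene", "flagged", "direction")],
    tidy.deg_table(deg2)[, c("gene", "flagged", "direction")],
    by = "gene", suffix = c("_1", "_2")
  )
  sort(j$gene[j$flagged_1 & j$flagged_2 & j$direction_1 != j$direction_2])
}
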