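# Readers and writers for the plain-text formats the pipeline consumes:
# CSV tables with documented headers, two-column TSV edge lists, GMT gene
# sets, GraphML export, JSON reports. Parsing is strict: schema violations
# name the offending line. Raw-spectrum formats (mzML) are out of scope;
# feature tables are expected as CSV with the schema of read_features().

.read_csv_strict <- function(path, required, numeric_cols = character(0)) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (col in numeric_cols) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl[[col]]))) &
                   !is.na(tbl[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric '%s' at data line(s): %s", path, col,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  tbl
}

#' Read a compound library CSV (`compound,formula,herb,response`)
#' @param path File path.
#' @return A tibble.
#' @export
read_compound_library <- function(path) {
  tbl <- .read_csv_strict(path, c("compound", "formula"))
  if ("response" %in% names(tbl)) tbl$response <- as.numeric(tbl$response)
  bad <- which(vapply(tbl$formula, function(f) {
    inherits(tryCatch(parse_formula(f), error = identity), "error")
  }, logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("%s: unparseable formula at data line(s): %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  tbl
}

#' Read an MS feature table CSV (`feature_id,rt,mz,response,polarity`)
#' @param path File path.
#' @return A tibble.
#' @export
read_features <- function(path) {
  tbl <- .read_csv_strict(path, c("mz", "polarity"), c("mz"))
  bad <- which(!tbl$polarity %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: polarity must be '+' or '-' at data line(s): %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  tbl
}

#' Read a gene expression count matrix from CSV (first column `gene`)
#' @param path File path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  tbl <- .read_csv_strict(path, "gene")
  m <- as.matrix(tbl[, setdiff(names(tbl), "gene"), drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) stop(path, ": negative counts", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$gene
  m
}

#' Write a count matrix as CSV with a `gene` column
#' @param counts Matrix with rownames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  readr::write_csv(dplyr::bind_cols(tibble::tibble(gene = rownames(counts)),
                                    tibble::as_tibble(counts)), path)
}

#' Read a two-column TSV edge list
#'
#' Self-loops and duplicate (undirected) edges are dropped with a warning.
#'
#' @param path File path (tab-separated, header `from<TAB>to`).
#' @return Edge tibble with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) stop(path, ": expected two tab-separated columns",
                           call. = FALSE)
  .clean_edges(tbl)
}

#' Write a two-column TSV edge list
#' @param edges Edge tibble.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(tibble::as_tibble(edges)[, 1:2], path)
}

#' Read gene sets from a GMT file
#'
#' GMT rows are tab-separated: set name, description, then member genes.
#' Empty sets are a validation error.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions kept as an
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: empty or malformed gene set at line(s): %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional description per set (defaults to the name).
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(!is.null(names(collection)), all(lengths(collection) > 0L))
  if (is.null(descriptions)) descriptions <- names(collection)
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Export a network to GraphML with role tags and centralities
#'
#' @param net igraph network (e.g. from [build_network()]).
#' @param path Output path.
#' @param centrality_table Optional [centralities()] table to attach as node
#'   attributes.
#' @export
write_graphml <- function(net, path, centrality_table = NULL) {
  if (!is.null(centrality_table)) {
    idx <- match(igraph::V(net)$name, centrality_table$node)
    igraph::V(net)$degree <- centrality_table$degree[idx]
    igraph::V(net)$betweenness <- centrality_table$betweenness[idx]
    igraph::V(net)$closeness <- centrality_table$closeness[idx]
  }
  igraph::write_graph(net, path, format = "graphml")
}

#' Write a list as pretty JSON
#' @param x List (e.g. a run report or ground truth).
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
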