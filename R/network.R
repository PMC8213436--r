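# The netcore module: tripartite gene network construction, exact
# centralities, and the median-threshold two-stage hub extraction. Graph
# machinery is igraph; this file owns the screening rule itself.

.clean_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(ncol(edges) >= 2L)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, ]
  }
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to), paste(edges$to, edges$from))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate edge(s)", sum(dup)), call. = FALSE)
    edges <- edges[!dup, ]
  }
  edges[, c("from", "to")]
}

#' Build the compound-target-disease gene interaction network
#'
#' Nodes are the union of the anti-inflammatory gene set, the predicted
#' target genes, and the disease genes; edges are the supplied PPI edges
#' whose both endpoints fall inside that union (self-loops and duplicate
#' edges are dropped). Role tags are kept as logical vertex attributes and
#' may overlap. Compound nodes are not part of the gene network by default;
#' set `include_constituent_edges = TRUE` to also add constituent nodes with
#' bipartite constituent-gene edges.
#'
#' @param anti_genes Character vector of anti-inflammatory/effect genes.
#' @param target_map Tibble with columns `constituent`, `gene` (predicted
#'   targets), or NULL.
#' @param disease_genes Character vector of disease genes.
#' @param ppi Two-column edge tibble (gene, gene).
#' @param include_constituent_edges Add bipartite compound-target edges
#'   (default FALSE: PPI-only among tagged genes).
#' @return An undirected simple `igraph` with vertex attributes `role_anti`,
#'   `role_target`, `role_disease` (and `role_constituent` when bipartite
#'   edges are included).
#' @export
build_network <- function(anti_genes, target_map, disease_genes, ppi,
                          include_constituent_edges = FALSE) {
  target_genes <- if (is.null(target_map)) character(0) else {
    as.character(tibble::as_tibble(target_map)$gene)
  }
  nodes <- sort(unique(c(as.character(anti_genes), target_genes,
                         as.character(disease_genes))))
  if (length(nodes) == 0L) stop("empty gene union", call. = FALSE)
  edges <- .clean_edges(ppi)
  edges <- edges[edges$from %in% nodes & edges$to %in% nodes, ]
  if (nrow(edges) == 0L) {
    warning("no PPI edges connect the supplied gene sets (edgeless network)",
            call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$role_anti <- nodes %in% anti_genes
  igraph::V(g)$role_target <- nodes %in% target_genes
  igraph::V(g)$role_disease <- nodes %in% disease_genes
  if (include_constituent_edges && !is.null(target_map)) {
    tm <- tibble::as_tibble(target_map)
    consts <- sort(unique(as.character(tm$constituent)))
    g <- igraph::add_vertices(g, length(consts), name = consts,
                              role_anti = FALSE, role_target = FALSE,
                              role_disease = FALSE)
    bip <- unique(tm[, c("constituent", "gene")])
    g <- igraph::add_edges(g, rbind(as.character(bip$constituent),
                                    as.character(bip$gene)))
    igraph::V(g)$role_constituent <- igraph::V(g)$name %in% consts
    g <- igraph::simplify(g)
  }
  g
}

#' Degree, betweenness and closeness of every node
#'
#' Degree is the plain edge count; betweenness is the raw (unnormalized)
#' shortest-path count; closeness is `(n_component - 1) / sum(distances)`
#' restricted to each node's connected component, with isolated nodes
#' assigned closeness 0.
#'
#' @param net An igraph network.
#' @return A tibble with columns `node`, `degree`, `betweenness`, `closeness`.
#' @export
centralities <- function(net) {
  stopifnot(igraph::vcount(net) > 0L)
  cl <- suppressWarnings(igraph::closeness(net, normalized = TRUE))
  cl[!is.finite(cl)] <- 0
  tibble::tibble(
    node = igraph::V(net)$name,
    degree = as.integer(igraph::degree(net)),
    betweenness = unname(igraph::betweenness(net, directed = FALSE)),
    closeness = unname(cl)
  )
}

#' Median-threshold core/hub node selection
#'
#' Selects the nodes whose degree is at least twice the median degree and
#' whose betweenness and closeness are at least the respective medians, all
#' medians taken over every node of the current network and all three
#' comparisons inclusive.
#'
#' @param table Centrality table from [centralities()].
#' @param degree_mult,betweenness_mult,closeness_mult Median multipliers
#'   (defaults 2, 1, 1).
#' @return Sorted character vector of selected node names.
#' @export
select_core <- function(table, degree_mult = 2, betweenness_mult = 1,
                        closeness_mult = 1) {
  stopifnot(all(c("node", "degree", "betweenness", "closeness") %in%
                  names(table)))
  keep <- table$degree >= degree_mult * stats::median(table$degree) &
    table$betweenness >= betweenness_mult * stats::median(table$betweenness) &
    table$closeness >= closeness_mult * stats::median(table$closeness)
  sort(table$node[keep])
}

#' Network density under the ordered-pair convention
#'
#' @param nodes Node count (>= 2).
#' @param edges Undirected edge count.
#' @return `edges / (nodes * (nodes - 1))`, unrounded.
#' @export
#' @examples
#' round(network_density(2251, 53254), 3)
network_density <- function(nodes, edges) {
  stopifnot(nodes >= 2, edges >= 0)
  edges / (nodes * (nodes - 1))
}

#' Two-stage median-threshold hub extraction
#'
#' Stage 1 applies the median screen ([select_core()]) to the full network,
#' yielding the core node set. Stage 2 builds the PPI network induced on the
#' core nodes (from `ppi` when supplied, otherwise the induced subgraph),
#' recomputes centralities and medians on that smaller network, and applies
#' the same screen again to yield the hub set. Densities of both stages are
#' recorded; hub screens are expected to concentrate the network, so a
#' warning (not a failure) is raised when stage-2 density does not exceed
#' stage-1 density. When fewer than 2 core nodes survive stage 1, stage 2 is
#' skipped and the hub set is empty.
#'
#' @param net Stage-1 igraph network (e.g. from [build_network()]).
#' @param ppi Optional edge tibble used to wire the stage-2 network among
#'   core nodes; defaults to the edges of `net`.
#' @inheritParams select_core
#' @return A `hub_result` list with elements `core`, `hubs`, `stages` (per
#'   stage: nodes, edges, density raw and rounded to 3 decimals, medians),
#'   `centralities` (per-stage tables) and `stage2_skipped`.
#' @export
extract_hubs <- function(net, ppi = NULL, degree_mult = 2,
                         betweenness_mult = 1, closeness_mult = 1) {
  ct1 <- centralities(net)
  core <- select_core(ct1, degree_mult, betweenness_mult, closeness_mult)
  d1 <- network_density(igraph::vcount(net), igraph::ecount(net))
  med1 <- c(degree = stats::median(ct1$degree),
            betweenness = stats::median(ct1$betweenness),
            closeness = stats::median(ct1$closeness))

  stage_row <- function(stage, n, e, dens, med) {
    tibble::tibble(stage = stage, nodes = n, edges = e,
                   density = dens, density_3dp = round(dens, 3),
                   median_degree = med[["degree"]],
                   median_betweenness = med[["betweenness"]],
                   median_closeness = med[["closeness"]])
  }
  stages <- stage_row(1L, igraph::vcount(net), igraph::ecount(net), d1, med1)

  if (length(core) < 2L) {
    warning("fewer than 2 core nodes: stage 2 skipped", call. = FALSE)
    res <- list(core = core, hubs = character(0), stages = stages,
                centralities = list(stage1 = ct1, stage2 = NULL),
                stage2_skipped = TRUE)
    class(res) <- "hub_result"
    return(res)
  }

  g2 <- if (is.null(ppi)) {
    igraph::induced_subgraph(net, core)
  } else {
    e <- .clean_edges(ppi)
    e <- e[e$from %in% core & e$to %in% core, ]
    igraph::graph_from_data_frame(e, directed = FALSE,
                                  vertices = data.frame(name = sort(core)))
  }
  ct2 <- centralities(g2)
  hubs <- select_core(ct2, degree_mult, betweenness_mult, closeness_mult)
  d2 <- network_density(igraph::vcount(g2), igraph::ecount(g2))
  med2 <- c(degree = stats::median(ct2$degree),
            betweenness = stats::median(ct2$betweenness),
            closeness = stats::median(ct2$closeness))
  stages <- dplyr::bind_rows(
    stages, stage_row(2L, igraph::vcount(g2), igraph::ecount(g2), d2, med2))
  if (d2 <= d1) {
    warning(sprintf(
      "stage-2 density (%.4f) does not exceed stage-1 density (%.4f)", d2, d1),
      call. = FALSE)
  }
  res <- list(core = core, hubs = hubs, stages = stages,
              centralities = list(stage1 = ct1, stage2 = ct2),
              stage2_skipped = FALSE)
  class(res) <- "hub_result"
  res
}

#' @method print hub_result
#' @export
print.hub_result <- function(x, ...) {
  s <- x$stages
  cat(sprintf("Two-stage hub extraction: %d nodes -> %d core -> %d hubs\n",
              s$nodes[1], length(x$core), length(x$hubs)))
  cat(sprintf("  stage 1: %d nodes, %d edges, density %.3f\n",
              s$nodes[1], s$edges[1], s$density[1]))
  if (!x$stage2_skipped) {
    cat(sprintf("  stage 2: %d nodes, %d edges, density %.3f\n",
                s$nodes[2], s$edges[2], s$density[2]))
  } else {
    cat("  stage 2: skipped (fewer than 2 core nodes)\n")
  }
  invisible(x)
}

#' @method tidy hub_result
#' @export
tidy.hub_result <- function(x, ...) {
  out <- x$centralities$stage1
  out$in_core <- out$node %in% x$core
  out$in_hub <- out$node %in% x$hubs
  dplyr::arrange(out, dplyr::desc(.data$in_hub), dplyr::desc(.data$in_core),
                 dplyr::desc(.data$degree))
}

#' @method glance hub_result
#' @export
glance.hub_result <- function(x, ...) {
  s <- x$stages
  tibble::tibble(
    n_nodes = s$nodes[1], n_edges = s$edges[1], density_stage1 = s$density[1],
    n_core = length(x$core),
    n_edges_stage2 = if (x$stage2_skipped) NA_integer_ else s$edges[2],
    density_stage2 = if (x$stage2_skipped) NA_real_ else s$density[2],
    n_hubs = length(x$hubs),
    density_increased = if (x$stage2_skipped) NA else s$density[2] > s$density[1]
  )
}
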