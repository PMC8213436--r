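# Seeded generators for every pipeline input, with planted ground truth so
# each downstream stage can be scored without external databases. Each
# generator draws from its own RNG stream (an offset of the master seed), so
# adding or re-running one generator never perturbs another. All planted
# labels (which gene ids carry effects, which tier a node belongs to, which
# constituents are the key block) are deterministic functions of the sizes
# in the config; only the measured values (edges, counts, scores, noise) are
# random.

.stream_seed <- function(seed, offset) {
  (as.integer(seed) %% 2100000L) * 1000L + offset
}

#' Configuration for the synthetic-data generators
#'
#' Defaults shadow the study design this package emulates at one-fifth scale
#' (fast tests): a ~59-compound library, a 3-replicate/3-group count matrix
#' with planted differential and counter-regulated genes, a 450-gene
#' interaction network with a planted two-tier hub structure, a
#' constituent-target table with a planted key-constituent block, and a
#' gene-set collection with one planted enriched set. `full_scale = TRUE`
#' switches to the full printed sizes (293 compounds, 376/217 and 92/85
#' differential genes with a 45-gene counter-regulated subset, a 135-node
#' hub tier, 48 key constituents).
#'
#' @param seed Master seed (small integer).
#' @param full_scale Use full study sizes instead of the 1/5-scale default.
#' @param ... Named overrides of any config field.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, full_scale = FALSE, ...) {
  cfg <- if (full_scale) {
    list(
      n_compounds = 293L, mz_sigma_mda = 1, n_herbs = 16L,
      n_genes = 12000L, reps = 3L,
      planted_up = 376L, planted_down = 217L, planted_counter = 45L,
      planted_wbt_up = 47L, planted_wbt_down = 40L,
      dispersion = 0.05, effect_log2fc = 2, mean_log = log(200), sd_log = 1,
      n_nodes = 2251L, hub_tier = 135L, core_tier = 270L, er_mean_degree = 1,
      n_key = 48L, key_hub_frac = 0.8,
      n_sets = 50L, set_size_range = c(20L, 60L)
    )
  } else {
    list(
      n_compounds = 59L, mz_sigma_mda = 1, n_herbs = 16L,
      n_genes = 2000L, reps = 3L,
      planted_up = 75L, planted_down = 43L, planted_counter = 9L,
      planted_wbt_up = 9L, planted_wbt_down = 8L,
      dispersion = 0.05, effect_log2fc = 2, mean_log = log(200), sd_log = 1,
      n_nodes = 450L, hub_tier = 27L, core_tier = 54L, er_mean_degree = 1,
      n_key = 10L, key_hub_frac = 0.8,
      n_sets = 50L, set_size_range = c(20L, 60L)
    )
  }
  cfg$seed <- as.integer(seed)
  cfg$full_scale <- full_scale
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  # planted subsets must fit within totals
  stopifnot(cfg$planted_counter <= cfg$planted_up + cfg$planted_down,
            cfg$n_key <= cfg$n_compounds,
            cfg$hub_tier + cfg$core_tier < cfg$n_nodes,
            cfg$n_nodes <= cfg$n_genes)
  class(cfg) <- "generator_config"
  cfg
}

.gene_ids <- function(n) sprintf("g%05d", seq_len(n))
.compound_ids <- function(n) sprintf("cmp%03d", seq_len(n))

# Deterministic tier layout over the gene namespace: the first hub_tier ids
# are the planted hub tier, the next core_tier ids the planted middle tier,
# the remaining network ids the periphery; counter-regulated genes sit at
# the start of the periphery so they participate in the network stage.
.network_layout <- function(cfg) {
  ids <- .gene_ids(cfg$n_genes)
  nodes <- ids[seq_len(cfg$n_nodes)]
  list(
    genes = ids,
    nodes = nodes,
    hub = nodes[seq_len(cfg$hub_tier)],
    core = nodes[cfg$hub_tier + seq_len(cfg$core_tier)],
    periphery = nodes[(cfg$hub_tier + cfg$core_tier + 1L):cfg$n_nodes]
  )
}

#' Generate a compound library and a noisy MS feature table
#'
#' Formulas are drawn from a CHO grammar (C 10-50, H within valence bounds,
#' O 2-20), rejecting masses that would be ambiguous under the adduct rules
#' (closer than 20 mDa to an accepted mass or to twice/half of one), so each
#' feature is identifiable in the noiseless limit. Every compound yields one
#' positive-mode and one negative-mode feature at its adduct m/z plus
#' Gaussian mass noise of `mz_sigma_mda` mDa. Responses are log-normal, with
#' the planted key-constituent block (the first `n_key` compounds) drawn
#' from a clearly higher abundance range so content-based selection has
#' ground truth. The two literature anchor compounds C39H50O19 and C47H76O18
#' are always appended as fixtures.
#'
#' @param cfg A [generator_config()].
#' @return List with `library` (compound, formula, herb, response),
#'   `features` (feature_id, rt, mz, response, polarity) and `ground_truth`
#'   (per-feature source compound and adduct; key-constituent ids).
#' @export
gen_library_and_features <- function(cfg) {
  set.seed(.stream_seed(cfg$seed, 101L))
  n <- cfg$n_compounds
  masses <- numeric(0)
  formulas <- character(0)
  while (length(formulas) < n) {
    C <- sample(10:50, 1L)
    H <- sample(seq.int(C, 2L * C + 2L), 1L)
    O <- sample(2:20, 1L)
    f <- format_formula(c(C = C, H = H, O = O))
    m <- monoisotopic_mass(f)
    cand <- c(masses, masses * 2, masses / 2)
    if (length(masses) == 0L || min(abs(cand - m)) > 0.020) {
      formulas <- c(formulas, f)
      masses <- c(masses, m)
    }
  }
  herbs <- sprintf("herb%02d", sample.int(cfg$n_herbs, n, replace = TRUE))
  response <- pmin(exp(stats::rnorm(n, log(50), 1)), 400)
  if (cfg$n_key > 0L) {
    response[seq_len(cfg$n_key)] <- stats::runif(cfg$n_key, 500, 2000)
  }
  lib <- tibble::tibble(
    compound = .compound_ids(n), formula = formulas,
    herb = herbs, response = response
  )
  anchors <- tibble::tibble(
    compound = c("baohuoside VI", "akebiasaponin D"),
    formula = c("C39H50O19", "C47H76O18"),
    herb = c("herb01", "herb02"),
    response = c(120, 150)
  )
  lib <- dplyr::bind_rows(lib, anchors)

  pos <- adduct_rules("+")
  neg <- adduct_rules("-")
  mk <- function(polarity, rules) {
    rule_i <- sample.int(nrow(rules), nrow(lib), replace = TRUE,
                         prob = c(0.7, rep(0.3 / (nrow(rules) - 1),
                                           nrow(rules) - 1)))
    theo <- vapply(seq_len(nrow(lib)), function(i) {
      adduct_mz(monoisotopic_mass(lib$formula[i]), rules[rule_i[i], ])
    }, numeric(1))
    tibble::tibble(
      compound = lib$compound, adduct = rules$label[rule_i],
      theo_mz = theo, polarity = polarity,
      mz = theo + stats::rnorm(nrow(lib), 0, cfg$mz_sigma_mda / 1e3),
      rt = stats::runif(nrow(lib), 1, 30),
      response = lib$response
    )
  }
  feat <- dplyr::bind_rows(mk("+", pos), mk("-", neg))
  feat$feature_id <- seq_len(nrow(feat))
  features <- feat[, c("feature_id", "rt", "mz", "response", "polarity")]
  gt <- list(
    feature_source = feat[, c("feature_id", "compound", "adduct", "theo_mz")],
    key_constituents = .compound_ids(n)[seq_len(cfg$n_key)]
  )
  list(library = lib, features = features, ground_truth = gt)
}

#' Generate a three-group negative-binomial count matrix with planted DEGs
#'
#' Counts are negative binomial with log-normal baseline means (floored at
#' 5) and the configured dispersion, over three groups (`Con`, `TNF`,
#' `TNF_WBT`) with `reps` replicates each. Planted structure: `planted_up` /
#' `planted_down` genes change by `effect_log2fc` in TNF vs Con; the first
#' `planted_counter` of them revert to baseline under TNF_WBT (the
#' counter-regulated subset, placed on network periphery gene ids so the
#' transcriptome and network stages share a namespace); `planted_wbt_*`
#' genes change only in TNF_WBT (treatment-specific effects).
#'
#' @param cfg A [generator_config()].
#' @return List with `counts` (genes x samples integer matrix), `groups`
#'   (label per column) and `ground_truth` (id vectors per planted class).
#' @export
gen_counts <- function(cfg) {
  set.seed(.stream_seed(cfg$seed, 303L))
  lay <- .network_layout(cfg)
  n <- cfg$n_genes
  ids <- lay$genes
  n_de1 <- cfg$planted_up + cfg$planted_down
  stopifnot(cfg$planted_counter <= length(lay$periphery),
            n_de1 - cfg$planted_counter + cfg$planted_wbt_up +
              cfg$planted_wbt_down <= n - cfg$n_nodes)

  counter_ids <- lay$periphery[seq_len(cfg$planted_counter)]
  free <- ids[(cfg$n_nodes + 1L):n]
  extra1 <- free[seq_len(n_de1 - cfg$planted_counter)]
  de1 <- c(counter_ids, extra1)
  up1 <- de1[seq_len(cfg$planted_up)]
  down1 <- de1[setdiff(seq_len(n_de1), seq_len(cfg$planted_up))]
  free2 <- free[setdiff(seq_along(free), seq_len(n_de1 - cfg$planted_counter))]
  wbt_up <- free2[seq_len(cfg$planted_wbt_up)]
  wbt_down <- free2[cfg$planted_wbt_up + seq_len(cfg$planted_wbt_down)]

  base <- pmax(exp(stats::rnorm(n, cfg$mean_log, cfg$sd_log)), 5)
  names(base) <- ids
  eff <- cfg$effect_log2fc
  mu_con <- base
  mu_tnf <- base
  mu_tnf[up1] <- base[up1] * 2^eff
  mu_tnf[down1] <- base[down1] * 2^-eff
  mu_wbt <- mu_tnf # persistence of the disease state unless counter-regulated
  mu_wbt[counter_ids] <- base[counter_ids]
  mu_wbt[wbt_up] <- mu_tnf[wbt_up] * 2^eff
  mu_wbt[wbt_down] <- mu_tnf[wbt_down] * 2^-eff

  groups <- rep(c("Con", "TNF", "TNF_WBT"), each = cfg$reps)
  mus <- cbind(replicate(cfg$reps, mu_con), replicate(cfg$reps, mu_tnf),
               replicate(cfg$reps, mu_wbt))
  size <- 1 / cfg$dispersion
  counts <- matrix(stats::rnbinom(length(mus), mu = mus, size = size),
                   nrow = n, dimnames = list(
                     ids, paste0(groups, "_", rep(seq_len(cfg$reps), 3L))))
  storage.mode(counts) <- "integer"
  gt <- list(up1 = up1, down1 = down1, counter = counter_ids,
             wbt_up = wbt_up, wbt_down = wbt_down)
  list(counts = counts, groups = groups, ground_truth = gt)
}

#' Generate PPI edges, a target map and disease genes with planted hubs
#'
#' The planted topology has two tiers above a sparse periphery: the hub tier
#' is a clique wired to every other node; the middle tier is wired to all
#' hubs plus `hub_tier + 10` random periphery nodes (enough connectivity to
#' pass the stage-1 median screen but not the stage-2 screen); the periphery
#' is an Erdos-Renyi graph of mean degree `er_mean_degree`. The target map
#' links constituents to network genes: the planted key block binds
#' `key_hub_frac` of the hub tier at filter-passing scores, every background
#' constituent binds exactly one hub gene (at filter-passing scores) plus a
#' few non-hub genes at mixed scores, so hub-target frequencies separate the
#' key block from the background by construction. Disease genes cover the
#' node set not otherwise tagged, as in curated disease-gene collections
#' that dominate such unions.
#'
#' @param cfg A [generator_config()].
#' @return List with `ppi` (edge tibble), `target_map` (constituent, gene,
#'   similarity, qed), `disease_genes`, `anti_genes` (the planted
#'   counter-regulated ids), and `ground_truth` (hub/core tiers, key block,
#'   edge count).
#' @export
gen_network_inputs <- function(cfg) {
  set.seed(.stream_seed(cfg$seed, 404L))
  lay <- .network_layout(cfg)
  hub <- lay$hub; core <- lay$core; peri <- lay$periphery
  nodes <- lay$nodes

  # hub tier: clique + spokes to every non-hub node
  e_hub <- t(utils::combn(hub, 2L))
  e_spokes <- cbind(rep(hub, each = length(c(core, peri))),
                    rep(c(core, peri), times = length(hub)))
  # Middle tier: extra periphery links beyond the hub spokes. The count is
  # chosen self-consistently: those links also raise periphery degrees by
  # core_tier * k / n_peri on average, so k must satisfy
  # hub + k >= 2 * (hub + er + core_tier * k / n_peri) + margin
  # for the middle tier to clear the stage-1 degree screen.
  np0 <- length(peri)
  margin <- max(6, cfg$hub_tier / 5)
  k_extra <- ceiling((cfg$hub_tier + 2 * cfg$er_mean_degree + margin) /
                       (1 - 2 * cfg$core_tier / np0))
  stopifnot(2 * cfg$core_tier < np0, k_extra < np0)
  e_core <- do.call(rbind, lapply(core, function(v) {
    cbind(v, sample(peri, k_extra))
  }))
  # periphery: Erdos-Renyi with the configured mean degree
  np <- length(peri)
  n_er <- round(cfg$er_mean_degree * np / 2)
  er_pairs <- unique(t(replicate(n_er * 2L, sort(sample(peri, 2L)))))
  er_pairs <- er_pairs[seq_len(min(n_er, nrow(er_pairs))), , drop = FALSE]
  ppi <- tibble::tibble(
    from = c(e_hub[, 1], e_spokes[, 1], e_core[, 1], er_pairs[, 1]),
    to = c(e_hub[, 2], e_spokes[, 2], e_core[, 2], er_pairs[, 2])
  )

  # constituent -> target predictions
  key <- .compound_ids(cfg$n_compounds)[seq_len(cfg$n_key)]
  bg <- setdiff(.compound_ids(cfg$n_compounds), key)
  n_hub_bind <- max(2L, ceiling(cfg$key_hub_frac * cfg$hub_tier))
  key_rows <- purrr::map_dfr(key, function(cid) {
    tibble::tibble(constituent = cid, gene = sample(hub, n_hub_bind),
                   similarity = stats::runif(n_hub_bind, 0.85, 1),
                   qed = stats::runif(n_hub_bind, 0.6, 0.95))
  })
  bg_rows <- purrr::map_dfr(bg, function(cid) {
    n_other <- sample(3:8, 1L)
    dplyr::bind_rows(
      tibble::tibble(constituent = cid, gene = sample(hub, 1L),
                     similarity = stats::runif(1L, 0.85, 1),
                     qed = stats::runif(1L, 0.6, 0.95)),
      tibble::tibble(constituent = cid,
                     gene = sample(c(core, peri), n_other),
                     similarity = stats::runif(n_other, 0.5, 1),
                     qed = stats::runif(n_other, 0.2, 1))
    )
  })
  target_map <- dplyr::bind_rows(key_rows, bg_rows)

  anti <- peri[seq_len(cfg$planted_counter)]
  tagged <- unique(c(anti, target_map$gene))
  disease <- sort(unique(c(setdiff(nodes, tagged),
                           sample(nodes, round(0.3 * length(nodes))))))
  gt <- list(hub_tier = hub, core_tier = core,
             key_constituents = key, n_edges = nrow(ppi))
  list(ppi = ppi, target_map = target_map, disease_genes = disease,
       anti_genes = anti, ground_truth = gt)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Random sets are drawn uniformly from the network gene universe; the
#' planted set consists of `key_hub_frac` of the planted hub tier plus
#' random filler, so a query of hub genes is strongly over-represented in it
#' and (with high probability) in no other set.
#'
#' @param cfg A [generator_config()].
#' @return List with `collection` (named list of gene vectors), `universe`
#'   and `ground_truth` (the planted set name).
#' @export
gen_genesets <- function(cfg) {
  set.seed(.stream_seed(cfg$seed, 505L))
  lay <- .network_layout(cfg)
  universe <- lay$nodes
  sizes <- sample(seq.int(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_sets, replace = TRUE)
  collection <- lapply(sizes, function(s) sample(universe, s))
  names(collection) <- sprintf("set%02d", seq_len(cfg$n_sets))
  n_hub_in <- max(2L, ceiling(cfg$key_hub_frac * cfg$hub_tier))
  planted <- unique(c(sample(lay$hub, n_hub_in),
                      sample(setdiff(universe, lay$hub), 20L)))
  planted_name <- sprintf("set%02d", cfg$n_sets + 1L)
  collection[[planted_name]] <- planted
  list(collection = collection, universe = universe,
       ground_truth = list(enriched_set = planted_name))
}

#' Generate every pipeline input in one call
#'
#' Runs all four generators (each on its own RNG stream) and merges their
#' ground truth.
#'
#' @param cfg A [generator_config()].
#' @return List with `library`, `features`, `counts`, `groups`, `ppi`,
#'   `target_map`, `disease_genes`, `anti_genes`, `collection`, `universe`
#'   and `ground_truth`.
#' @export
gen_all <- function(cfg) {
  ms <- gen_library_and_features(cfg)
  cx <- gen_counts(cfg)
  nw <- gen_network_inputs(cfg)
  gs <- gen_genesets(cfg)
  list(
    library = ms$library, features = ms$features,
    counts = cx$counts, groups = cx$groups,
    ppi = nw$ppi, target_map = nw$target_map,
    disease_genes = nw$disease_genes, anti_genes = nw$anti_genes,
    collection = gs$collection, universe = gs$universe,
    ground_truth = c(ms$ground_truth, cx$ground_truth, nw$ground_truth,
                     gs$ground_truth)
  )
}
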