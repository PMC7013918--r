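#' Configuration for the synthetic study generator
#'
#' Builds (and validates) the parameter list consumed by
#' [generate_synthetic_study()]. The defaults describe a compact but
#' structurally faithful analogue of a multi-subtype expression/PPI study:
#' three disease subtypes sharing a block of over-expressed genes (among
#' them ten high-degree hubs, three seeds that no interaction record ever
#' mentions, and four planted protein complexes) plus fifteen
#' disease-unique over-expressed genes each; log-normal FPKM marginals with
#' a shifted distribution for over-expressed genes so that an FPKM-3 cutoff
#' is informative rather than saturated; STRING-style integer confidence
#' scores with planted structure at 900+ and background noise below;
#' a small fraction of cross-taxon contaminant records; one planted
#' GO term enriched among the disease-unique genes; and id maps with ~20%
#' of symbols unmappable to Ensembl ids.
#'
#' @param n_genes Size of the gene universe.
#' @param diseases Character vector of disease condition names.
#' @param n_isolated_seeds Shared over-expressed seeds planted with no
#'   interaction record in any dialect.
#' @param n_hubs,hub_degree Number of planted hub seeds and their degree.
#' @param complex_sizes Sizes of the planted complexes (cliques among shared
#'   seeds).
#' @param n_shared_plain Additional shared over-expressed seeds with
#'   ordinary (non-hub, non-complex) connectivity.
#' @param plain_partner_degree Planted interactions given to each plain
#'   shared seed.
#' @param n_unique,partners_per_unique Disease-unique over-expressed seeds
#'   and the number of dedicated interactors planted for each.
#' @param hub_pool_size Size of the pool the hub interactors are drawn from.
#' @param fpkm_background,fpkm_overexpressed `(meanlog, sdlog)` of the
#'   log-normal FPKM distributions.
#' @param missing_cell_prob Probability that a background expression cell is
#'   written as blank (explicitly missing).
#' @param noise_edge_prob Per-pair probability of a background noise
#'   interaction.
#' @param noise_high_score_prob Fraction of noise edges drawn with a
#'   confidence score above 0.9.
#' @param contaminant_fraction Cross-taxon contaminant records added to the
#'   BioGRID-dialect table, as a fraction of the core record count.
#' @param enriched_study_rate,enriched_background_rate Annotation rates of
#'   the planted enriched GO term among disease-unique seeds and among
#'   background genes.
#' @param n_filler_terms,filler_rate Number and per-gene annotation rate of
#'   unenriched filler GO terms.
#' @param idmap_missing_fraction Fraction of symbol-map rows lacking an
#'   Ensembl gene id.
#' @param entrez_missing_fraction Same for the Entrez-sourced map.
#' @param seed RNG seed; the whole study is reproducible from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 600,
                             diseases = c("glioma", "glioblastoma",
                                          "astrocytoma"),
                             n_isolated_seeds = 3,
                             n_hubs = 10, hub_degree = 30,
                             complex_sizes = c(5, 5, 6, 6),
                             n_shared_plain = 10,
                             plain_partner_degree = 2,
                             n_unique = 15, partners_per_unique = 3,
                             hub_pool_size = 150,
                             fpkm_background = c(meanlog = -1, sdlog = 1),
                             fpkm_overexpressed = c(meanlog = 3,
                                                    sdlog = 0.5),
                             missing_cell_prob = 0.01,
                             noise_edge_prob = 2e-4,
                             noise_high_score_prob = 0.1,
                             contaminant_fraction = 0.05,
                             enriched_study_rate = 0.9,
                             enriched_background_rate = 0.02,
                             n_filler_terms = 20, filler_rate = 0.05,
                             idmap_missing_fraction = 0.2,
                             entrez_missing_fraction = 0.02,
                             seed = 1) {
  cfg <- as.list(environment())
  n_shared <- n_isolated_seeds + n_hubs + sum(complex_sizes) + n_shared_plain
  n_d <- length(diseases)
  needed <- n_shared + n_d * n_unique + hub_pool_size +
    n_d * n_unique * partners_per_unique
  if (needed > n_genes) {
    abort(sprintf(paste0("inconsistent generator config: %d genes needed ",
                         "for the planted structure but n_genes = %d"),
                  needed, n_genes))
  }
  probs <- c(missing_cell_prob, noise_edge_prob, noise_high_score_prob,
             contaminant_fraction, enriched_study_rate,
             enriched_background_rate, filler_rate,
             idmap_missing_fraction, entrez_missing_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("generator config fractions must lie in [0, 1]")
  }
  if (n_d < 1 || n_isolated_seeds < 0 || n_hubs < 0 || hub_degree < 1) {
    abort("inconsistent generator config counts")
  }
  structure(cfg, class = "generator_config")
}

gene_universe <- function(n_genes) {
  i <- seq_len(n_genes)
  tibble(gene_id = sprintf("ENSG%08d", i),
         gene_symbol = sprintf("SYG%04d", i),
         ensembl_protein = sprintf("ENSP%08d", i),
         entrez = as.character(100000L + i))
}

#' Generate a complete synthetic study with planted truth
#'
#' Emits every input the pipeline consumes — per-disease expression TSVs, a
#' DEG table, interaction tables in both dialects, a GO annotation table
#' (pair dialect), symbol- and Entrez-sourced id maps — together with a
#' `synthetic_truth` object recording the planted structure. All outputs are
#' fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return A list with `paths` (named file paths), `truth`
#'   (`synthetic_truth`) and `config`, invisibly classed as
#'   `synthetic_study`.
#' @export
generate_synthetic_study <- function(config = generator_config(),
                                     dir = tempfile("synthstudy")) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  uni <- gene_universe(config$n_genes)
  n_d <- length(config$diseases)

  # --- deterministic allocation of planted roles over the universe
  cursor <- 0L
  take <- function(n) {
    out <- seq_len(n) + cursor
    cursor <<- cursor + n
    uni$gene_id[out]
  }
  isolated <- take(config$n_isolated_seeds)
  hubs <- take(config$n_hubs)
  complexes <- map(config$complex_sizes, take)
  shared_plain <- take(config$n_shared_plain)
  unique_sets <- setNames(map(seq_len(n_d), ~ take(config$n_unique)),
                          config$diseases)
  hub_pool <- take(config$hub_pool_size)
  partner_sets <- setNames(map(seq_len(n_d), function(d) {
    map(seq_len(config$n_unique),
        ~ take(config$partners_per_unique))
  }), config$diseases)
  shared <- c(isolated, hubs, unlist(complexes), shared_plain)
  planted_union <- c(shared, unlist(unique_sets))

  # --- core interaction records (shared across dialects)
  edges <- list()
  for (cx in complexes) {
    pairs <- utils::combn(cx, 2)
    edges[[length(edges) + 1]] <- tibble(id_a = pairs[1, ],
                                         id_b = pairs[2, ])
  }
  for (h in hubs) {
    partners <- sample(hub_pool, config$hub_degree)
    edges[[length(edges) + 1]] <- tibble(id_a = h, id_b = partners)
  }
  for (s in shared_plain) {
    partners <- sample(hub_pool, config$plain_partner_degree)
    edges[[length(edges) + 1]] <- tibble(id_a = s, id_b = partners)
  }
  for (d in config$diseases) {
    for (i in seq_len(config$n_unique)) {
      edges[[length(edges) + 1]] <- tibble(
        id_a = unique_sets[[d]][i], id_b = partner_sets[[d]][[i]])
    }
  }
  core <- bind_rows(edges)
  core$planted <- TRUE

  # background noise among pairs not touching the always-isolated seeds
  n_pairs <- choose(config$n_genes, 2)
  n_noise <- rbinom(1, n_pairs, config$noise_edge_prob)
  if (n_noise > 0) {
    pick <- sample(n_pairs, n_noise)
    a <- ceiling((sqrt(8 * pick + 1) - 1) / 2)  # pair index -> (row, col)
    b <- pick - a * (a - 1) / 2
    noise <- tibble(id_a = uni$gene_id[a + 1], id_b = uni$gene_id[b],
                    planted = FALSE)
    noise <- filter(noise, !.data$id_a %in% isolated,
                    !.data$id_b %in% isolated)
    core <- bind_rows(core, noise)
  }
  key <- paste(pmin(core$id_a, core$id_b), pmax(core$id_a, core$id_b))
  core <- core[!duplicated(key), , drop = FALSE]

  score_int <- integer(nrow(core))
  n_pl <- sum(core$planted)
  score_int[core$planted] <- sample(900:1000, n_pl, replace = TRUE)
  noise_idx <- which(!core$planted)
  hi_noise <- runif(length(noise_idx)) < config$noise_high_score_prob
  score_int[noise_idx] <- sample(150:899, length(noise_idx), replace = TRUE)
  score_int[noise_idx[hi_noise]] <- sample(900:1000, sum(hi_noise),
                                           replace = TRUE)
  evidence_pool <- c("Two-hybrid", "Affinity Capture-MS", "Co-fractionation")
  sym <- setNames(uni$gene_symbol, uni$gene_id)
  records <- tibble(id_a = core$id_a, id_b = core$id_b,
                    symbol_a = unname(sym[core$id_a]),
                    symbol_b = unname(sym[core$id_b]),
                    taxon_a = 9606L, taxon_b = 9606L,
                    score = score_int / 1000,
                    evidence = sample(evidence_pool, nrow(core),
                                      replace = TRUE))

  # cross-taxon contaminants (BioGRID dialect only)
  n_cont <- round(config$contaminant_fraction * nrow(records))
  contaminants <- NULL
  if (n_cont > 0) {
    # partners come from otherwise-unused genes, so taxonomy filtering
    # visibly shrinks the unfiltered network
    bystanders <- uni$gene_id[(cursor + 1):config$n_genes]
    ca <- sample(setdiff(planted_union, isolated), n_cont, replace = TRUE)
    cb <- sample(bystanders, n_cont, replace = TRUE)
    contaminants <- tibble(id_a = ca, id_b = cb,
                           symbol_a = unname(sym[ca]),
                           symbol_b = unname(sym[cb]),
                           taxon_a = 9606L, taxon_b = 10090L,
                           score = NA_real_,
                           evidence = sample(evidence_pool, n_cont,
                                             replace = TRUE))
    contaminants <- filter(contaminants, .data$id_a != .data$id_b)
  }
  biogrid <- bind_rows(records, contaminants)
  biogrid$score <- NA_real_

  # --- expression tables (one condition column per disease table)
  hi <- config$fpkm_overexpressed
  lo <- config$fpkm_background
  expr_tables <- list()
  # disease-unique genes must really be unique: in the other diseases their
  # FPKM is drawn from the background distribution truncated below 3 FPKM
  # (the boundary between background and over-expressed regimes), so the
  # planted uniqueness labels are exact
  trunc_q <- stats::plnorm(3, lo[["meanlog"]], lo[["sdlog"]])
  for (d in config$diseases) {
    over <- uni$gene_id %in% c(shared, unique_sets[[d]])
    foreign_unique <- uni$gene_id %in%
      setdiff(unlist(unique_sets), unique_sets[[d]])
    vals <- numeric(config$n_genes)
    vals[over] <- rlnorm(sum(over), hi[["meanlog"]], hi[["sdlog"]])
    vals[!over] <- rlnorm(sum(!over), lo[["meanlog"]], lo[["sdlog"]])
    vals[foreign_unique] <- stats::qlnorm(
      runif(sum(foreign_unique)) * trunc_q, lo[["meanlog"]], lo[["sdlog"]])
    vals <- round(vals, 3)
    chr <- format(vals, trim = TRUE, scientific = FALSE)
    blank <- !over & runif(config$n_genes) < config$missing_cell_prob
    chr[blank] <- ""
    tbl <- tibble(`Gene ID` = uni$gene_id, `Gene Name` = uni$gene_symbol)
    tbl[[d]] <- chr
    expr_tables[[d]] <- tbl
  }

  # --- DEG table (IDH-style contrast): a handful of clear up/down genes
  deg_n <- 60
  deg_genes <- sample(uni$gene_id, deg_n)
  deg <- tibble(`Gene ID` = deg_genes,
                `Gene Name` = unname(sym[deg_genes]),
                log2foldchange = round(stats::rnorm(deg_n, 0, 1.5), 3),
                `p-value` = signif(stats::runif(deg_n)^2, 4))

  # --- annotations
  prolif_acc <- "GO:0008283"
  enriched_acc <- "GO:0099990"
  terms <- tibble(
    accession = c(prolif_acc, enriched_acc,
                  sprintf("GO:%07d", 9900000 + seq_len(config$n_filler_terms))),
    name = c("cell population proliferation",
             "synthetic planted process",
             sprintf("synthetic background process %02d",
                     seq_len(config$n_filler_terms))),
    namespace = "biological_process")
  entries <- list(tibble(gene_id = planted_union, accession = prolif_acc))
  study_hit <- unlist(unique_sets)[
    runif(length(unlist(unique_sets))) < config$enriched_study_rate]
  bg_pool <- setdiff(uni$gene_id, unlist(unique_sets))
  bg_hit <- bg_pool[runif(length(bg_pool)) < config$enriched_background_rate]
  entries[[2]] <- tibble(gene_id = c(study_hit, bg_hit),
                         accession = enriched_acc)
  for (j in seq_len(config$n_filler_terms)) {
    hit <- uni$gene_id[runif(config$n_genes) < config$filler_rate]
    entries[[j + 2]] <- tibble(gene_id = hit,
                               accession = terms$accession[j + 2])
  }
  ann <- annotation_table(bind_rows(entries), terms)

  # --- id maps: symbol-sourced (incomplete) and entrez-sourced (nearly full)
  sym_missing <- runif(config$n_genes) < config$idmap_missing_fraction
  symbol_map <- tibble(
    ensembl_gene_id = ifelse(sym_missing, NA, uni$gene_id),
    ensembl_protein_id = uni$ensembl_protein,
    entrez_id = NA_character_,
    symbol = uni$gene_symbol)
  ent_missing <- runif(config$n_genes) < config$entrez_missing_fraction
  entrez_map <- tibble(
    ensembl_gene_id = ifelse(ent_missing, NA, uni$gene_id),
    ensembl_protein_id = uni$ensembl_protein,
    entrez_id = uni$entrez,
    symbol = NA_character_)

  # --- write everything
  paths <- list()
  for (d in config$diseases) {
    p <- file.path(dir, paste0("expression_", d, ".tsv"))
    readr::write_tsv(expr_tables[[d]], p)
    paths[[paste0("expression_", d)]] <- p
  }
  paths$deg <- file.path(dir, "deg_idh_contrast.tsv")
  readr::write_tsv(deg, paths$deg)
  paths$biogrid <- file.path(dir, "interactions_biogrid.tsv")
  write_interactions(biogrid, paths$biogrid, "biogrid_tab")
  paths$string <- file.path(dir, "interactions_string.txt")
  write_interactions(records, paths$string, "string_links")
  paths$annotations <- file.path(dir, "annotations_genes.tsv")
  paths$terms <- file.path(dir, "annotations_terms.tsv")
  write_annotations(ann, paths$annotations, paths$terms)
  paths$idmap_symbol <- file.path(dir, "idmap_symbol.tsv")
  readr::write_tsv(symbol_map, paths$idmap_symbol, na = "")
  paths$idmap_entrez <- file.path(dir, "idmap_entrez.tsv")
  readr::write_tsv(entrez_map, paths$idmap_entrez, na = "")

  truth <- structure(list(
    universe = uni,
    diseases = config$diseases,
    shared = shared,
    unique_sets = unique_sets,
    seed_sets = setNames(map(config$diseases,
                             ~ sort(c(shared, unique_sets[[.x]]))),
                         config$diseases),
    complexes = complexes,
    hubs = hubs,
    always_isolated = isolated,
    partner_sets = partner_sets,
    record_pairs = tibble(id_a = core$id_a, id_b = core$id_b),
    enriched_term = enriched_acc,
    proliferation_term = prolif_acc,
    unmappable_symbols = uni$gene_symbol[sym_missing]),
    class = "synthetic_truth")
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(diseases = config$diseases, shared = shared,
         unique_sets = unique_sets, complexes = complexes, hubs = hubs,
         always_isolated = isolated, enriched_term = enriched_acc,
         unmappable_symbols = truth$unmappable_symbols),
    paths$truth, auto_unbox = FALSE, pretty = TRUE)

  invisible(structure(list(paths = paths, truth = truth, config = config),
                      class = "synthetic_study"))
}

#' Planted-clique benchmark graph
#'
#' `k` disjoint `m`-cliques plus isolated nodes and optional uniform noise
#' edges: the canonical benchmark on which cohesiveness clustering must
#' recover every planted clique.
#'
#' @param k Number of cliques.
#' @param m Clique size.
#' @param n_isolated Number of additional isolated nodes.
#' @param noise_edge_prob Per-pair probability of a noise edge between
#'   distinct planted positions.
#' @param seed RNG seed.
#' @return A list with `graph` (PPI network) and `cliques` (list of member
#'   vectors) and `isolated`.
#' @export
simulate_planted_cliques <- function(k = 3, m = 5, n_isolated = 2,
                                     noise_edge_prob = 0, seed = 1) {
  set.seed(seed)
  n <- k * m + n_isolated
  ids <- sprintf("N%03d", seq_len(n))
  cliques <- map(seq_len(k), ~ ids[((.x - 1) * m + 1):(.x * m)])
  iso <- if (n_isolated > 0) ids[(k * m + 1):n] else character()
  edges <- bind_rows(map(cliques, function(cl) {
    pairs <- utils::combn(cl, 2)
    tibble(id_a = pairs[1, ], id_b = pairs[2, ])
  }))
  if (noise_edge_prob > 0) {
    live <- ids[seq_len(k * m)]
    pairs <- utils::combn(live, 2)
    existing <- paste(pmin(edges$id_a, edges$id_b),
                      pmax(edges$id_a, edges$id_b))
    cand <- paste(pmin(pairs[1, ], pairs[2, ]),
                  pmax(pairs[1, ], pairs[2, ]))
    free <- which(!cand %in% existing)
    hit <- free[runif(length(free)) < noise_edge_prob]
    if (length(hit) > 0) {
      edges <- bind_rows(edges, tibble(id_a = pairs[1, hit],
                                       id_b = pairs[2, hit]))
    }
  }
  g <- ppi_network(edges, nodes = tibble(gene_id = ids, is_seed = TRUE),
                   label = "planted_cliques")
  list(graph = g, cliques = cliques, isolated = iso)
}
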