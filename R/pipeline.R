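#' Read a pipeline configuration file
#'
#' The configuration is plain YAML whose keys mirror the arguments of
#' [run_pipeline()]; see that function for the schema.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' Pipeline configuration for a generated synthetic study
#'
#' Convenience builder wiring the file layout of
#' [generate_synthetic_study()] into a [run_pipeline()] configuration with
#' the standard filter settings (FPKM cutoff 3, keyword "proliferation",
#' STRING confidence 0.9, human taxonomy for the BioGRID dialect).
#'
#' @param study A `synthetic_study` from [generate_synthetic_study()].
#' @param out_dir Output directory for pipeline artifacts.
#' @return A configuration list.
#' @export
synthetic_pipeline_config <- function(study, out_dir = tempfile("pipe")) {
  cfg <- list(
    diseases = setNames(map(study$config$diseases, function(d) {
      list(expression = study$paths[[paste0("expression_", d)]],
           condition = d)
    }), study$config$diseases),
    databases = list(
      biogrid = list(path = study$paths$biogrid, dialect = "biogrid_tab",
                     taxon = 9606),
      string = list(path = study$paths$string, dialect = "string_links",
                    min_score = 0.9, organism = 9606)),
    annotations = list(entries = study$paths$annotations,
                       terms = study$paths$terms),
    idmaps = list(symbol = study$paths$idmap_symbol,
                  entrez = study$paths$idmap_entrez),
    cutoff = 3, go_keyword = "proliferation",
    clustering = list(penalty = 2, min_size = 3, min_density = 0.5,
                      overlap_max = 0.8),
    alpha = 0.05, top_k = 10,
    out_dir = out_dir)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  need <- c("diseases", "databases", "annotations", "out_dir")
  missing_key <- setdiff(need, names(cfg))
  if (length(missing_key) > 0) {
    abort(sprintf("pipeline config lacks key '%s'", missing_key[1]))
  }
  cfg$cutoff <- cfg$cutoff %||% 3
  cfg$go_keyword <- cfg$go_keyword %||% "proliferation"
  cfg$clustering <- modifyList(list(penalty = 2, min_size = 3,
                                    min_density = 0.5, overlap_max = 0.8),
                               cfg$clustering %||% list())
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$top_k <- cfg$top_k %||% 10
  paths <- c(map_chr(cfg$diseases, "expression"),
             map_chr(cfg$databases, "path"),
             cfg$annotations$entries, cfg$annotations$terms,
             unlist(cfg$idmaps))
  gone <- paths[!file.exists(paths)]
  if (length(gone) > 0) {
    abort(sprintf("pipeline input does not exist: %s", gone[1]))
  }
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full differential-network pipeline
#'
#' Executes filter, build (per disease by database), graph algebra
#' (merged intersection, merged union, per-disease unique difference
#' networks), topology statistics, cohesiveness clustering, GO
#' over-representation of each difference network, and the cross-database
#' consensus reports. Every intermediate artifact is written under
#' `config$out_dir`; re-running with unchanged inputs reproduces identical
#' outputs (only the manifest timestamps differ).
#'
#' The configuration is a list with:
#' \describe{
#'   \item{diseases}{Named list; each entry has `expression` (TSV path) and
#'     `condition` (column name).}
#'   \item{databases}{Named list; each entry has `path`, `dialect`
#'     (`"biogrid_tab"`/`"string_links"`) and optionally `min_score`,
#'     `taxon`, `organism`, `evidence`.}
#'   \item{annotations}{`entries` and `terms` TSV paths (pair dialect).}
#'   \item{idmaps}{Optional named list of id-map TSV paths, highest
#'     precedence first.}
#'   \item{cutoff, go_keyword, clustering, alpha, top_k, out_dir}{Filter and
#'     analysis parameters; defaults 3, "proliferation",
#'     list(penalty = 2, min_size = 3, min_density = 0.5,
#'     overlap_max = 0.8), 0.05, 10.}
#' }
#'
#' @param config Configuration list (see above), from
#'   [read_pipeline_config()] or [synthetic_pipeline_config()].
#' @return Invisibly, a list of class `ppi_pipeline_result` with components
#'   `seeds`, `networks` (database by disease), `algebra`, `stats`,
#'   `clusterings`, `enrichments`, `consensus`, `background`, `config` and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  for (sub in c("seeds", "networks", "algebra", "stats", "clusters",
                "enrichment", "consensus")) {
    dir.create(file.path(out, sub), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("glionet")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_checksums = as.list(tools::md5sum(unique(c(
      map_chr(config$diseases, "expression"),
      map_chr(config$databases, "path"),
      config$annotations$entries, config$annotations$terms,
      unlist(config$idmaps))))),
    stages = list())
  manifest_path <- file.path(out, "manifest.json")
  write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
  }
  write_manifest()

  ann <- pipeline_stage("annotations", read_annotations(
    config$annotations$entries, config$annotations$terms))
  idmap <- if (length(config$idmaps %||% list()) > 0) {
    pipeline_stage("idmap", merge_idmaps(
      imap(config$idmaps, ~ read_idmap(.x, provenance = .y))))
  } else NULL

  # filter: expression cutoff, then GO keyword
  seeds <- imap(config$diseases, function(dcfg, d) {
    pipeline_stage(paste0("filter/", d), {
      expr <- read_expression_table(dcfg$expression)
      s <- filter_by_cutoff(expr, dcfg$condition, cutoff = config$cutoff)
      s <- filter_by_go_keyword(s, ann, keyword = config$go_keyword)
      write_gene_set(s, file.path(out, "seeds", paste0(d, ".txt")),
                     file.path(out, "seeds", paste0(d, ".tsv")))
      s
    })
  })
  manifest$stages$seeds <- map_int(seeds, nrow)

  # build: first-order networks per database x disease
  networks <- imap(config$databases, function(dbcfg, db) {
    recs <- pipeline_stage(paste0("parse/", db), parse_interactions(
      dbcfg$path, dialect = dbcfg$dialect,
      organism = dbcfg$organism %||% 9606L))
    imap(seeds, function(s, d) {
      pipeline_stage(paste0("build/", db, "/", d), {
        g <- build_first_order_network(
          recs, s, min_score = dbcfg$min_score,
          taxon = dbcfg$taxon, evidence = dbcfg$evidence,
          label = paste(d, db, sep = "_"))
        write_network_graphml(g, file.path(out, "networks",
                                           paste0(d, "_", db, ".graphml")))
        g
      })
    })
  })
  manifest$stages$networks <- map(networks, ~ map_int(.x, igraph::vcount))

  # algebra + stats per database
  algebra <- imap(networks, function(nets, db) {
    pipeline_stage(paste0("algebra/", db), {
      inter <- intersect_networks(nets,
                                  label = paste0(db, "_intersection"))
      uni <- union_networks(nets, label = paste0(db, "_union"))
      diffs <- imap(nets, ~ difference_network(.x, inter))
      walk(c(list(intersection = inter, union = uni), diffs), function(g) {
        write_network_graphml(g, file.path(
          out, "algebra",
          paste0(db, "_", igraph::graph_attr(g, "label"), ".graphml")))
      })
      list(intersection = inter, union = uni, diffs = diffs)
    })
  })
  stats <- imap(networks, function(nets, db) {
    pipeline_stage(paste0("stats/", db), {
      tbl <- compare_stats_table(nets)
      readr::write_tsv(tbl, file.path(out, "stats",
                                      paste0(db, "_stats.tsv")))
      tbl
    })
  })

  # clustering of every disease network
  clusterings <- imap(networks, function(nets, db) {
    imap(nets, function(g, d) {
      pipeline_stage(paste0("cluster/", db, "/", d), {
        cl <- do.call(cluster_network, c(list(g), config$clustering))
        write_clustering(
          cl,
          file.path(out, "clusters", paste0(d, "_", db, "_clusters.tsv")),
          file.path(out, "clusters", paste0(d, "_", db, "_roles.tsv")))
        cl
      })
    })
  })

  # enrichment of every unique difference network
  backgrounds <- imap(config$databases, function(dbcfg, db) {
    recs <- parse_interactions(dbcfg$path, dialect = dbcfg$dialect,
                               organism = dbcfg$organism %||% 9606L)
    gene_set(unique(c(recs$id_a, recs$id_b,
                      unlist(map(seeds, ~ .x$gene_id)))))
  })
  enrichments <- imap(algebra, function(alg, db) {
    imap(alg$diffs, function(dg, d) {
      pipeline_stage(paste0("enrich/", db, "/", d), {
        study_ids <- net_nodes(dg)$gene_id
        if (length(study_ids) == 0) return(NULL)
        res <- enrich(gene_set(study_ids), backgrounds[[db]], ann,
                      alpha = config$alpha)
        readr::write_tsv(as_tibble(res),
                         file.path(out, "enrichment",
                                   paste0(d, "_", db, "_go.tsv")))
        res
      })
    })
  })

  # consensus across databases
  consensus <- pipeline_stage("consensus", {
    db_names <- names(networks)
    hubs <- map(networks, ~ map(.x, top_hubs, k = config$top_k))
    hub_matches <- if (length(db_names) >= 2) {
      map(names(config$diseases), function(d) {
        hc <- hub_consensus(hubs[[db_names[1]]][[d]],
                            hubs[[db_names[2]]][[d]], idmap = NULL)
        list(disease = d, match_count = hc$match_count,
             matched = hc$matched$gene_id)
      })
    } else list()
    all_nets <- unlist(networks, recursive = FALSE)
    ci <- common_isolated(all_nets)
    merges <- if (length(db_names) >= 2) {
      bind_rows(map(names(config$diseases), function(d) {
        mutate(cross_db_merge(networks[[db_names[1]]][[d]],
                              networks[[db_names[2]]][[d]]),
               Samples = d, .before = 1)
      }))
    } else NULL
    if (!is.null(merges)) {
      readr::write_tsv(
        rename(merges, `Intersecting Nodes` = "intersecting_nodes",
               `Union of Nodes` = "union_nodes"),
        file.path(out, "consensus", "cross_db_merge.tsv"))
    }
    res <- list(hub_lists = hubs, hub_matches = hub_matches,
                common_isolated = ci$gene_id, merge_table = merges)
    jsonlite::write_json(
      list(hub_matches = hub_matches, common_isolated = ci$gene_id,
           merge_table = merges),
      file.path(out, "consensus", "consensus.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res
  })

  manifest$stages$clusters <- map(clusterings,
                                  ~ map_int(.x, ~ length(.x$clusters)))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()

  invisible(structure(
    list(seeds = seeds, networks = networks, algebra = algebra,
         stats = stats, clusterings = clusterings,
         enrichments = enrichments, consensus = consensus,
         background = backgrounds, config = config,
         manifest_path = manifest_path),
    class = "ppi_pipeline_result"))
}

#' Score pipeline outputs against the planted truth
#'
#' Compares a [run_pipeline()] result produced from a generated synthetic
#' study with the study's `synthetic_truth`:
#' \describe{
#'   \item{isolated}{Are the planted always-isolated seeds recovered exactly
#'     as the common isolated nodes of every network?}
#'   \item{hubs}{Fraction of planted hubs among the top-`k` degree hubs,
#'     per network.}
#'   \item{complexes}{Best-match Jaccard index of every planted complex
#'     against the detected clusters, per network.}
#'   \item{difference purity}{Fraction of each unique difference network's
#'     nodes that are planted disease-unique genes or their exclusive
#'     neighbours.}
#'   \item{enrichment}{Rank of the planted enriched term (1 = smallest
#'     p-value) in each difference network's GO table.}
#' }
#'
#' @param truth A `synthetic_truth`.
#' @param result A `ppi_pipeline_result` computed from the same generated
#'   inputs.
#' @return A list of class `recovery_report` with per-network tibbles and
#'   scalar summary fields.
#' @export
score_recovery <- function(truth, result) {
  nets <- unlist(result$networks, recursive = FALSE)
  net_ids <- map(nets, ~ net_nodes(.x)$gene_id)
  if (!all(unlist(net_ids) %in% truth$universe$gene_id)) {
    abort("pipeline outputs and truth come from different gene universes")
  }

  iso <- common_isolated(nets)$gene_id
  isolated_exact <- setequal(iso, truth$always_isolated)

  hub_tbl <- bind_rows(imap(result$networks, function(dnets, db) {
    bind_rows(imap(dnets, function(g, d) {
      top <- top_hubs(g, k = result$config$top_k)
      tibble(database = db, disease = d,
             hub_recovery = mean(truth$hubs %in% top$gene_id))
    }))
  }))

  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  complex_tbl <- bind_rows(imap(result$clusterings, function(dcl, db) {
    bind_rows(imap(dcl, function(cl, d) {
      best <- map_dbl(truth$complexes, function(cx) {
        if (length(cl$clusters) == 0) return(0)
        max(map_dbl(cl$clusters, ~ jacc(cx, .x)))
      })
      tibble(database = db, disease = d,
             mean_best_jaccard = mean(best))
    }))
  }))

  # exclusive neighbourhood of the disease-unique genes, from the planted
  # record table (noise edges included: a noise partner touched only by a
  # unique gene is a legitimate exclusive neighbour)
  rp <- truth$record_pairs
  nbrs_of <- function(ids) {
    unique(c(rp$id_b[rp$id_a %in% ids], rp$id_a[rp$id_b %in% ids]))
  }
  purity_tbl <- bind_rows(imap(result$algebra, function(alg, db) {
    bind_rows(imap(alg$diffs, function(dg, d) {
      nodes <- net_nodes(dg)$gene_id
      other <- setdiff(unlist(truth$seed_sets), truth$seed_sets[[d]])
      shared_side <- unique(c(truth$shared, nbrs_of(truth$shared), other))
      allowed <- setdiff(c(truth$unique_sets[[d]],
                           nbrs_of(truth$unique_sets[[d]])), shared_side)
      tibble(database = db, disease = d,
             n_unique_nodes = length(nodes),
             purity = if (length(nodes) == 0) NA_real_
                      else mean(nodes %in% allowed))
    }))
  }))

  enrich_tbl <- bind_rows(imap(result$enrichments, function(den, db) {
    bind_rows(imap(den, function(res, d) {
      rank <- if (is.null(res)) NA_integer_ else {
        match(truth$enriched_term, res$accession)
      }
      tibble(database = db, disease = d, enriched_term_rank = rank)
    }))
  }))

  structure(list(
    isolated_exact = isolated_exact,
    common_isolated = sort(iso),
    hub_recovery = hub_tbl,
    complex_recovery = complex_tbl,
    difference_purity = purity_tbl,
    enrichment_rank = enrich_tbl,
    summary = tibble(
      isolated_exact = isolated_exact,
      min_hub_recovery = min(hub_tbl$hub_recovery),
      mean_complex_jaccard = mean(complex_tbl$mean_best_jaccard),
      mean_difference_purity = mean(purity_tbl$purity, na.rm = TRUE),
      max_enriched_rank = max(enrich_tbl$enriched_term_rank, na.rm = TRUE))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("# Recovery against planted truth\n")
  print(x$summary)
  invisible(x)
}
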