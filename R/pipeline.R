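# End-to-end orchestration: classification, trait assignment, trait-nutrient
# statistics and network inference from a flat key=value config, with every
# stage seed derived from one master seed and a run manifest for
# reproducibility.

#' Read a flat key=value run configuration
#'
#' One `key = value` (or `key<TAB>value`) pair per line; `#` starts a
#' comment. Recognized keys: `otu_table`, `taxonomy`, `traitdb`, `env`,
#' `tree` (optional), `outdir`, `seed`, `abundance_cutoff`, `freq_cutoff`,
#' `occurrence_cutoff`, `min_occurrence`, `scan_min`, `scan_max`,
#' `scan_step`, `permutations`, `n_nulls`.
#'
#' @param path config file
#' @return named list (numbers parsed to numeric)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input("config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  cfg <- list()
  for (p in kv) {
    if (length(p) < 2) abort_input("malformed config line: ", paste(p, collapse = ""))
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

default_config <- function() {
  list(abundance_cutoff = 0.001, freq_cutoff = 0.5, occurrence_cutoff = 0.8,
       min_occurrence = 0.3, scan_min = 0.30, scan_max = 0.99,
       scan_step = 0.01, permutations = 999, n_nulls = 100, seed = 1)
}

# fixed per-stage seed offsets from the master seed
stage_seed <- function(master, stage)
  as.integer(master) + c(mantel = 101L, nulls = 102L)[[stage]]

#' Run the full analysis pipeline
#'
#' Stages: read and validate inputs; biosphere classification; rrn
#' assignment and the per-sample community-level rrn profile; Pearson
#' trait-nutrient correlations; partial Mantel of trait distance vs nutrient
#' distance controlling phylogenetic (weighted UniFrac) structure (when a
#' tree is supplied); occurrence filter, Spearman matrix, RMT threshold,
#' network build, fast-greedy modules, rewired nulls, link-sign and
#' degree-by-category summaries. All report tables are written to `outdir`
#' together with a JSON manifest (config, derived seeds, chosen threshold,
#' package version, input hashes). A stage failure aborts with the stage
#' name and leaves a FAILED marker in `outdir`.
#'
#' @param config a named list (see [read_run_config]) or a path to a config
#'   file
#' @return invisibly, a list with the in-memory results of every stage
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  for (key in c("otu_table", "taxonomy", "traitdb", "env", "outdir"))
    if (is.null(cfg[[key]]))
      abort_input("config is missing required key `", key, "`")
  for (key in c("otu_table", "taxonomy", "traitdb", "env"))
    if (!file.exists(cfg[[key]]))
      abort_input("config `", key, "` points to a missing file: ", cfg[[key]])
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(cfg$outdir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), fail_marker)
      abort_input("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  out <- list(config = cfg)

  stage("read_inputs", {
    out$table <- read_otu_table(cfg$otu_table)
    out$taxonomy <- read_taxonomy(cfg$taxonomy)
    out$db <- read_trait_db(cfg$traitdb)
    out$env <- read_env_table(cfg$env)
    out$tree <- if (!is.null(cfg$tree)) read_phylo_tree(cfg$tree) else NULL
    ct_log(sprintf("inputs: %d OTUs x %d samples, %d db records, %d covariates",
                   n_otus(out$table), n_samples(out$table), nrow(out$db),
                   ncol(out$env) - 1L))
  })

  stage("classify", {
    out$labels <- classify_biospheres(out$table, a = cfg$abundance_cutoff,
                                      f1 = cfg$freq_cutoff,
                                      f2 = cfg$occurrence_cutoff)
    write_tsv(as.data.frame(out$labels),
              file.path(cfg$outdir, "biosphere_labels.tsv"))
    sm <- biosphere_summary(out$labels, out$table)
    ct_log(sprintf("biospheres: %s",
                   paste(names(sm$counts), sm$counts, collapse = ", ")))
  })

  stage("trait", {
    out$traits <- assign_rrn(out$taxonomy, out$db)
    write_tsv(as.data.frame(out$traits),
              file.path(cfg$outdir, "trait_assignment.tsv"))
    out$rrn <- community_rrn_profile(out$table, out$traits, out$labels)
    write_tsv(out$rrn, file.path(cfg$outdir, "community_rrn.tsv"))
    ct_log(sprintf("trait: %d/%d OTUs assigned; mean community rrn %.3f",
                   sum(!out$traits$missing), nrow(out$traits),
                   mean(out$rrn$rrn_weighted)))
  })

  stage("pearson", {
    vals <- stats::setNames(out$rrn$rrn_weighted, out$rrn$sample_id)
    vars <- setdiff(names(out$env), "sample_id")
    out$pearson <- do.call(rbind, lapply(vars, function(v) {
      cr <- pearson_trait_env(vals, out$env, v)
      data.frame(variable = v, r = cr$r, p = cr$p, n = cr$n,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(out$pearson, file.path(cfg$outdir, "pearson_trait_nutrient.tsv"))
  })

  stage("partial_mantel", {
    if (is.null(out$tree)) {
      ct_log("no tree supplied: partial Mantel stage skipped")
    } else {
      vals <- stats::setNames(out$rrn$rrn_weighted, out$rrn$sample_id)
      dt <- trait_distance(vals)
      de <- env_distance(out$env)
      ids <- rownames(de)  # env rows may shrink under missing values
      du <- unifrac_matrix(out$table, out$tree)
      mt <- partial_mantel(dt[ids, ids], de[ids, ids], du[ids, ids],
                           permutations = cfg$permutations,
                           seed = stage_seed(cfg$seed, "mantel"))
      out$mantel <- mt
      write_tsv(data.frame(comparison = "trait_vs_nutrients_given_phylogeny",
                           r = mt$r, p = mt$p, n = mt$n,
                           permutations = mt$permutations),
                file.path(cfg$outdir, "partial_mantel.tsv"))
    }
  })

  stage("network", {
    filt <- occurrence_filter(out$table, cfg$min_occurrence)
    rho <- spearman_matrix(filt)
    out$scan <- rmt_threshold(rho, cfg$scan_min, cfg$scan_max, cfg$scan_step)
    write_tsv(out$scan$scan, file.path(cfg$outdir, "rmt_scan.tsv"))
    net <- build_network(rho, out$scan$threshold, out$labels)
    net <- greedy_modularity(net)
    out$network <- net
    write_network(net, file.path(cfg$outdir, "network_edges.tsv"),
                  "edge_list_tsv")
    write_network(net, file.path(cfg$outdir, "network.graphml"), "graphml")
    nulls <- rewire_null(net, n_nulls = cfg$n_nulls,
                         seed = stage_seed(cfg$seed, "nulls"))
    out$nulls <- nulls
    write_tsv(data.frame(index = names(nulls$observed),
                         observed = nulls$observed,
                         null_mean = nulls$null_mean,
                         null_sd = nulls$null_sd, z = nulls$z),
              file.path(cfg$outdir, "topology_null.tsv"))
    write_tsv(link_sign_summary(net),
              file.path(cfg$outdir, "link_sign_summary.tsv"))
    write_tsv(degree_by_category(net)$summary,
              file.path(cfg$outdir, "degree_by_category.tsv"))
    ct_log(sprintf("network: s_t = %.2f, %d nodes, %d links, Q = %.3f",
                   net$s_t, nrow(net$nodes), nrow(net$edges), net$modularity))
  })

  stage("manifest", {
    inputs <- c("otu_table", "taxonomy", "traitdb", "env",
                if (!is.null(cfg$tree)) "tree")
    manifest <- list(
      package_version = as.character(utils::packageVersion("commtrait")),
      r_version = R.version.string,
      config = cfg,
      derived_seeds = list(mantel = stage_seed(cfg$seed, "mantel"),
                           nulls = stage_seed(cfg$seed, "nulls")),
      chosen_threshold = out$scan$threshold,
      input_md5 = as.list(tools::md5sum(unlist(cfg[inputs]))))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(out)
}
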