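PIPELINE_NUMERIC_KEYS <- c(
  "alpha", "min_combine_score", "score_scale_gg", "min_score_mm",
  "min_score_gm", "min_score_pp", "lambda_jump", "beta", "eta_phenotype",
  "top_k_metabolites", "top_n_genes", "score_threshold", "tol", "max_iter",
  "rng_seed"
)

#' Assemble a pipeline configuration
#'
#' Bundles the input file paths and every tunable parameter of the pipeline.
#' Defaults follow the conventions of the analysis: FDR cutoff 0.05, gene
#' interaction combine-score threshold 0.8, no confidence filter on the
#' metabolite-metabolite and gene-metabolite edges, cross-layer jump 0.5,
#' restart probability 0.7, phenotype restart share 0.5, top 50 metabolites
#' and top 100 co-expressed genes.
#'
#' @param gg_path,mm_path,pp_path,gm_path,gp_path,mp_path Paths to the six
#'   edge-set files; `gg`, `mm`, `pp` are scored 3-column files, `gp`, `mp`
#'   unweighted 2-column pair files, `gm` scored.
#' @param expression_path,labels_path Expression matrix and label TSVs.
#' @param seeds_path Seed TSV (`type`, `id`).
#' @param mapping_path Optional 2-column TSV mapping gene-network source IDs
#'   (e.g. protein IDs) to gene symbols; `NULL` to skip.
#' @param out_dir Output directory.
#' @param alpha DEG FDR cutoff.
#' @param min_combine_score Combine-score threshold for `gg` edges.
#' @param score_scale_gg Score scale of the `gg` file (1000 for STRING-style
#'   integers, 1 for normalized).
#' @param min_score_mm,min_score_gm,min_score_pp Optional confidence
#'   thresholds for the other scored parts (default 0: keep all).
#' @param lambda_jump Cross-layer jump probability.
#' @param beta Restart probability.
#' @param eta_phenotype Phenotype share of the restart mass.
#' @param top_k_metabolites,top_n_genes Ranking truncations.
#' @param score_threshold Reporting threshold for the score report.
#' @param tol,max_iter RWR convergence controls.
#' @param rng_seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gg_path, mm_path, pp_path, gm_path, gp_path,
                            mp_path, expression_path, labels_path,
                            seeds_path, mapping_path = NULL, out_dir,
                            alpha = 0.05, min_combine_score = 0.8,
                            score_scale_gg = 1, min_score_mm = 0,
                            min_score_gm = 0, min_score_pp = 0,
                            lambda_jump = 0.5, beta = 0.7,
                            eta_phenotype = 0.5, top_k_metabolites = 50,
                            top_n_genes = 100, score_threshold = 0,
                            tol = 1e-10, max_iter = 1000, rng_seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` pair per line; `#` lines are comments. Keys are the
#' arguments of [pipeline_config()]. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path Config file path.
#' @param overrides Optional named character vector of key overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = character()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  vals <- setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
  if (length(overrides)) vals[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  args <- list()
  for (k in names(vals)) {
    v <- trimws(vals[[k]])
    if (k %in% PIPELINE_NUMERIC_KEYS) {
      args[[k]] <- as.numeric(v)
    } else if (endsWith(k, "_path") || k == "out_dir") {
      args[[k]] <- if (grepl("^([/~]|[A-Za-z]:)", v)) v else file.path(base, v)
    } else {
      args[[k]] <- v
    }
  }
  do.call(pipeline_config, args)
}

# Dialect-aware part reader: files beginning with "#part=" are the package's
# own EdgeSet dialect (weights already in (0,1]); otherwise scored parts are
# read as 3-column source files and association parts as 2-column unit files.
read_part_file <- function(path, part, min_score = 0, score_scale = 1) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^#part=", first)) {
    es <- read_edgeset(path)
    if (es$part != part) {
      stop("file ", path, " declares part ", es$part, ", expected ", part)
    }
    if (min_score > 0) {
      sel <- es$edges$weight >= min_score
      es <- edgeset(part, es$edges$node_a[sel], es$edges$node_b[sel],
                    es$edges$weight[sel])
    }
    es
  } else if (part %in% c("gp", "mp")) {
    read_unit_edges(path, part)
  } else {
    read_scored_edges(path, part, min_score = min_score,
                      score_scale = score_scale)
  }
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Executes every stage in order: DEG calling, edge-set parsing and
#' filtering, heterogeneous-network assembly, transition-model construction,
#' random walk with restart, metabolite ranking, co-expressed gene
#' extraction, subnetwork induction and degree analysis. All outputs plus a
#' run manifest (parameters, input checksums, network sizes, iteration
#' count, convergence flag) are written to `config$out_dir`. The run is
#' deterministic given its inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`deg`, `net`,
#'   `scores`, `ranking`, `coexpressed`, `subnetwork_degrees`,
#'   `coexpr_degrees`, `manifest`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  deg <- with_stage("deg", {
    em <- read_expression(config$expression_path, config$labels_path)
    call_degs(em, alpha = config$alpha)
  })

  parts <- with_stage("network_build", {
    gg <- read_part_file(config$gg_path, "gg",
                         min_score = config$min_combine_score,
                         score_scale = config$score_scale_gg)
    if (!is.null(config$mapping_path) && nzchar(config$mapping_path)) {
      map_dt <- data.table::fread(config$mapping_path, sep = "\t",
                                  header = TRUE, data.table = FALSE)
      mapping <- setNames(as.character(map_dt[[2L]]),
                          as.character(map_dt[[1L]]))
      mapped <- map_node_ids(gg, mapping)
      if (length(mapped$unmapped)) {
        message(length(mapped$unmapped),
                " unmapped gene-network IDs dropped")
      }
      gg <- mapped$edges
    }
    mm <- read_part_file(config$mm_path, "mm",
                         min_score = config$min_score_mm)
    pp <- read_part_file(config$pp_path, "pp",
                         min_score = config$min_score_pp)
    gm <- read_part_file(config$gm_path, "gm",
                         min_score = config$min_score_gm)
    gp <- read_part_file(config$gp_path, "gp")
    mp <- read_part_file(config$mp_path, "mp")

    # informative gene network: background interactions restricted to DEGs
    gg_inf <- restrict_to_genes(gg, deg$gene_id[deg$is_deg])
    # association parts restricted to nodes of the backing layer networks
    bg_genes <- edgeset_nodes(gg)
    mm_nodes <- edgeset_nodes(mm)
    pp_nodes <- edgeset_nodes(pp)
    gm <- cross_filter(gm, bg_genes, mm_nodes)
    gp <- cross_filter(gp, bg_genes, pp_nodes)
    mp <- cross_filter(mp, mm_nodes, pp_nodes)
    list(gg = gg_inf, mm = mm, pp = pp, gm = gm, gp = gp, mp = mp)
  })

  net <- with_stage("hetnet", {
    keep <- parts[vapply(parts, n_edges, 1L) > 0L]
    if (!length(keep)) stop("no edges survive filtering; nothing to assemble")
    assemble_hetnet(keep)
  })

  seeds <- with_stage("seeds", {
    s <- read_seeds(config$seeds_path)
    seed_set(s$seed_genes, s$seed_phenotypes, s$seed_metabolites,
             eta_phenotype = config$eta_phenotype)
  })

  walk <- with_stage("rwr", {
    model <- build_transition(net, lambda_jump = config$lambda_jump)
    p0 <- build_restart_vector(net, seeds)
    rwr_power(model, p0, beta = config$beta, tol = config$tol,
              max_iter = as.integer(config$max_iter))
  })

  outputs <- with_stage("prioritize", {
    ranking <- rank_metabolites(walk$scores, net,
                                k = config$top_k_metabolites,
                                exclude = seeds$seed_metabolites)
    coexpr <- top_coexpressed_genes(walk$scores, net, ranking,
                                    n = config$top_n_genes)
    report <- score_threshold_report(ranking, config$score_threshold)
    sub_nodes <- unique(c(ranking$metabolite_id, seeds$seed_genes,
                          seeds$seed_phenotypes))
    sub_nodes <- intersect(sub_nodes, net$nodes$id)
    sub <- extract_subnetwork(net, sub_nodes)
    sub_deg <- degree_table(sub)
    co_nodes <- unique(c(ranking$metabolite_id, coexpr$gene_id,
                         seeds$seed_genes))
    co_nodes <- intersect(co_nodes, net$nodes$id)
    co_sub <- extract_subnetwork(net, co_nodes)
    co_deg <- degree_table(co_sub)
    list(ranking = ranking, coexpr = coexpr, report = report, sub = sub,
         sub_deg = sub_deg, co_sub = co_sub, co_deg = co_deg)
  })

  with_stage("write", {
    od <- config$out_dir
    write_deg_table(deg, file.path(od, "deg_table.tsv"))
    write_node_table(net, file.path(od, "nodes.tsv"))
    write_scores(walk$scores, net, file.path(od, "scores.tsv"))
    data.table::fwrite(outputs$ranking,
                       file.path(od, "metabolite_ranking.tsv"), sep = "\t")
    data.table::fwrite(outputs$coexpr,
                       file.path(od, "coexpressed_genes.tsv"), sep = "\t")
    write_subnetwork(outputs$sub, file.path(od, "subnetwork_edges.tsv"))
    data.table::fwrite(outputs$sub_deg,
                       file.path(od, "subnetwork_degrees.tsv"), sep = "\t")
    write_subnetwork(outputs$co_sub, file.path(od, "coexpr_network_edges.tsv"))
    data.table::fwrite(outputs$co_deg,
                       file.path(od, "coexpr_network_degrees.tsv"), sep = "\t")
  })

  input_paths <- unlist(config[endsWith(names(config), "_path")])
  input_paths <- input_paths[!is.na(input_paths) & nzchar(input_paths)]
  checksums <- setNames(as.list(unname(tools::md5sum(input_paths))),
                        basename(input_paths))
  manifest <- list(
    package_version = as.character(utils::packageVersion("metrwr")),
    parameters = config[PIPELINE_NUMERIC_KEYS],
    inputs = checksums,
    n_nodes = nrow(net$nodes),
    n_edges = net$n_edges,
    n_nodes_per_layer = as.list(table(net$nodes$layer)),
    n_degs = sum(deg$is_deg),
    rwr_iterations = walk$n_iter,
    rwr_converged = walk$converged,
    score_threshold_report = list(
      threshold = config$score_threshold,
      count = outputs$report$count,
      metabolite_ids = outputs$report$metabolite_ids)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(deg = deg, net = net, scores = walk$scores,
                 ranking = outputs$ranking, coexpressed = outputs$coexpr,
                 subnetwork_degrees = outputs$sub_deg,
                 coexpr_degrees = outputs$co_deg, manifest = manifest))
}

#' Simulate a complete runnable input bundle
#'
#' Generates a synthetic heterogeneous network and expression matrix, writes
#' every pipeline input plus the planted truth to `out_dir`, and also writes
#' a ready-to-run `config.txt` pointing at the generated files.
#'
#' @param net_config A [synthetic_net_config()].
#' @param expr_config A [synthetic_expr_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `paths`, `truth` and `de_genes`.
#' @export
run_simulate <- function(net_config = synthetic_net_config(),
                         expr_config = synthetic_expr_config(),
                         out_dir) {
  net <- generate_hetnet(net_config)
  expr <- generate_expression(expr_config)
  paths <- write_synthetic_bundle(net, expr, out_dir)
  cfg_lines <- c(
    "# pipeline configuration (paths relative to this file)",
    "gg_path = gg.tsv", "mm_path = mm.tsv", "pp_path = pp.tsv",
    "gm_path = gm.tsv", "gp_path = gp.tsv", "mp_path = mp.tsv",
    "expression_path = expression.tsv", "labels_path = labels.tsv",
    "seeds_path = seeds.tsv", "out_dir = results",
    "# synthetic edge weights are final confidences; no further score filter",
    "min_combine_score = 0",
    sprintf("rng_seed = %d", net_config$rng_seed)
  )
  writeLines(cfg_lines, file.path(out_dir, "config.txt"))
  invisible(list(paths = paths, truth = net$truth, de_genes = expr$de_genes))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("missing value for ", a)
    opts[[sub("^--", "", a)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic input bundle), `deg` (call
#' DEGs from an expression matrix), `build-net` (parse the six edge files
#' and write the node table), `rank` / `run-all` (full pipeline from a
#' config file), `report` (threshold report on a written ranking).
#' Installed as `inst/cli/metrwr.R`; see the package README.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly on success; errors propagate.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: metrwr <simulate|deg|build-net|rank|run-all|report> ",
         "[--key value ...]")
  }
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  num <- function(key, default) {
    if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
  }
  switch(cmd,
    simulate = {
      if (is.null(opts$out)) stop("simulate requires --out DIR")
      seed <- as.integer(num("seed", 1))
      res <- run_simulate(
        synthetic_net_config(rng_seed = seed),
        synthetic_expr_config(rng_seed = seed + 1L),
        out_dir = opts$out)
      message("simulated bundle written to ", opts$out)
    },
    deg = {
      for (k in c("expression", "labels", "out")) {
        if (is.null(opts[[k]])) stop("deg requires --", k)
      }
      em <- read_expression(opts$expression, opts$labels)
      deg <- call_degs(em, alpha = num("alpha", 0.05))
      write_deg_table(deg, opts$out)
      message(sum(deg$is_deg), " DEGs at FDR < ", num("alpha", 0.05))
    },
    `build-net` = ,
    rank = ,
    `run-all` = {
      if (is.null(opts$config)) stop(cmd, " requires --config FILE")
      overrides <- unlist(opts[setdiff(names(opts), "config")])
      cfg <- read_pipeline_config(opts$config, overrides = overrides)
      res <- run_full(cfg)
      message("pipeline complete: ", nrow(res$net$nodes), " nodes, ",
              res$net$n_edges, " edges, ", sum(res$deg$is_deg),
              " DEGs; outputs in ", cfg$out_dir)
    },
    report = {
      if (is.null(opts$ranking)) stop("report requires --ranking FILE")
      rk <- data.table::fread(opts$ranking, sep = "\t", data.table = FALSE)
      rep <- score_threshold_report(rk, num("threshold", 0))
      message(rep$count, " metabolites above score ", num("threshold", 0),
              ": ", paste(rep$metabolite_ids, collapse = ", "))
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
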