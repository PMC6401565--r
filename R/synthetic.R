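#' Configuration for the synthetic heterogeneous network generator
#'
#' Defines the stated world for benchmark networks: three layers (genes,
#' metabolites, phenotypes) with independent-edge (Erdos-Renyi per block)
#' intra- and cross-layer connectivity, uniform edge weights, and a planted
#' disease neighborhood that wires seed genes to a disease phenotype and to
#' true-positive metabolites. Defaults mirror a desk-scale version of a
#' disease network study: 1000 genes, 400 metabolites, 100 phenotypes, 6 seed
#' genes, 10 true metabolites, with sparse biological-network densities.
#'
#' @param n_genes,n_metabolites,n_phenotypes Layer sizes.
#' @param intra_density_g,intra_density_m,intra_density_p Edge probability
#'   within each layer, in `[0, 1]`.
#' @param cross_density_gm,cross_density_gp,cross_density_mp Edge probability
#'   across layer pairs, in `[0, 1]`.
#' @param n_seed_genes Number of planted disease genes (`<= n_genes`).
#' @param n_true_metabolites Number of planted true metabolites
#'   (`<= n_metabolites`).
#' @param planted_boost Weight multiplier (>= 1) applied to the planted
#'   seed-gene/true-metabolite edges, capped at 1.
#' @param weight_low,weight_high Bounds of the uniform edge-weight draw,
#'   `0 < weight_low <= weight_high <= 1`.
#' @param rng_seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class `synth_net_config`.
#' @export
synthetic_net_config <- function(n_genes = 1000, n_metabolites = 400,
                                 n_phenotypes = 100,
                                 intra_density_g = 0.01,
                                 intra_density_m = 0.02,
                                 intra_density_p = 0.05,
                                 cross_density_gm = 0.005,
                                 cross_density_gp = 0.002,
                                 cross_density_mp = 0.01,
                                 n_seed_genes = 6, n_true_metabolites = 10,
                                 planted_boost = 5,
                                 weight_low = 0.4, weight_high = 1,
                                 rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_metabolites = as.integer(n_metabolites),
              n_phenotypes = as.integer(n_phenotypes),
              intra_density_g = intra_density_g,
              intra_density_m = intra_density_m,
              intra_density_p = intra_density_p,
              cross_density_gm = cross_density_gm,
              cross_density_gp = cross_density_gp,
              cross_density_mp = cross_density_mp,
              n_seed_genes = as.integer(n_seed_genes),
              n_true_metabolites = as.integer(n_true_metabolites),
              planted_boost = planted_boost,
              weight_low = weight_low, weight_high = weight_high,
              rng_seed = as.integer(rng_seed))
  dens <- unlist(cfg[grep("density", names(cfg))])
  if (any(dens < 0 | dens > 1)) stop("densities must be in [0, 1]")
  if (cfg$n_genes < 1 || cfg$n_metabolites < 1 || cfg$n_phenotypes < 1) {
    stop("layer sizes must be positive")
  }
  if (cfg$n_seed_genes > cfg$n_genes) stop("n_seed_genes > n_genes")
  if (cfg$n_true_metabolites > cfg$n_metabolites) {
    stop("n_true_metabolites > n_metabolites")
  }
  if (cfg$planted_boost < 1) stop("planted_boost must be >= 1")
  if (cfg$weight_low <= 0 || cfg$weight_high > 1 ||
      cfg$weight_low > cfg$weight_high) {
    stop("require 0 < weight_low <= weight_high <= 1")
  }
  structure(cfg, class = "synth_net_config")
}

layer_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

# Draw an Erdos-Renyi edge index set over n_pairs possible pairs: the number
# of edges is Binomial(n_pairs, p) and the identities are a uniform subset,
# which is distributionally identical to independent Bernoulli edges but
# avoids materializing every pair.
draw_pair_indices <- function(n_pairs, p) {
  if (n_pairs == 0 || p <= 0) return(integer())
  if (p >= 1) return(seq_len(n_pairs))
  m <- rbinom(1L, n_pairs, p)
  if (m == 0) return(integer())
  sort(sample.int(n_pairs, m))
}

# Decode linear index k (1-based, pairs i<j of n nodes ordered by i then j)
# into endpoint indices.
decode_intra_pairs <- function(k, n) {
  if (!length(k)) {
    return(list(i = integer(), j = integer()))
  }
  ends <- cumsum(seq(n - 1, 1))  # pairs with first index <= i
  i <- findInterval(k - 0.5, c(0, ends))
  j <- i + (k - c(0, ends)[i])
  list(i = i, j = j)
}

decode_cross_pairs <- function(k, n_b) {
  if (!length(k)) {
    return(list(i = integer(), j = integer()))
  }
  list(i = (k - 1L) %/% n_b + 1L, j = (k - 1L) %% n_b + 1L)
}

draw_intra_edges <- function(part, ids, density, wlo, whi) {
  n <- length(ids)
  idx <- draw_pair_indices(n * (n - 1) / 2, density)
  pr <- decode_intra_pairs(idx, n)
  edgeset(part, ids[pr$i], ids[pr$j], runif(length(idx), wlo, whi))
}

draw_cross_edges <- function(part, ids_a, ids_b, density, wlo, whi) {
  idx <- draw_pair_indices(length(ids_a) * length(ids_b), density)
  pr <- decode_cross_pairs(idx, length(ids_b))
  edgeset(part, ids_a[pr$i], ids_b[pr$j], runif(length(idx), wlo, whi))
}

#' Generate a synthetic heterogeneous network with planted truth
#'
#' Draws the six edge sets as independent Bernoulli edges with uniform
#' weights, then plants a disease neighborhood: every seed gene is connected
#' to the disease phenotype with a gene-phenotype edge of weight exactly 1
#' (the curated-association convention), and every true metabolite is
#' connected to at least one seed gene by a gene-metabolite edge whose weight
#' is multiplied by `planted_boost` and capped at 1. Node IDs are
#' layer-prefixed (`G0001`, `M0001`, `P0001`) so layer membership is
#' checkable from the ID alone.
#'
#' @param config A [synthetic_net_config()].
#' @return A list with `edgesets` (named list of the six [edgeset()]s:
#'   `gg`, `mm`, `pp`, `gm`, `gp`, `mp`) and `truth` (list with
#'   `seed_genes`, `true_metabolites`, `disease_phenotype`).
#' @export
generate_hetnet <- function(config) {
  stopifnot(inherits(config, "synth_net_config"))
  withr::with_seed(config$rng_seed, {
    g <- layer_ids("G", config$n_genes)
    m <- layer_ids("M", config$n_metabolites)
    p <- layer_ids("P", config$n_phenotypes)
    wlo <- config$weight_low
    whi <- config$weight_high

    gg <- draw_intra_edges("gg", g, config$intra_density_g, wlo, whi)
    mm <- draw_intra_edges("mm", m, config$intra_density_m, wlo, whi)
    pp <- draw_intra_edges("pp", p, config$intra_density_p, wlo, whi)
    gm <- draw_cross_edges("gm", g, m, config$cross_density_gm, wlo, whi)
    gp <- draw_cross_edges("gp", g, p, config$cross_density_gp, wlo, whi)
    mp <- draw_cross_edges("mp", m, p, config$cross_density_mp, wlo, whi)

    seed_genes <- sort(sample(g, config$n_seed_genes))
    true_mets <- sort(sample(m, config$n_true_metabolites))
    disease_phen <- sample(p, 1L)

    # planted gp edges: weight exactly 1 (dedupe keeps the max, so these win)
    gp <- edgeset("gp",
                  c(gp$edges$node_a, seed_genes),
                  c(gp$edges$node_b, rep(disease_phen, length(seed_genes))),
                  c(gp$edges$weight, rep(1, length(seed_genes))))

    # planted gm edges: each true metabolite tied to >= 1 seed gene, boosted
    anchor <- sample(seed_genes, length(true_mets), replace = TRUE)
    w_pl <- pmin(1, runif(length(true_mets), wlo, whi) * config$planted_boost)
    gm <- edgeset("gm",
                  c(gm$edges$node_a, anchor),
                  c(gm$edges$node_b, true_mets),
                  c(gm$edges$weight, w_pl))

    list(
      edgesets = list(gg = gg, mm = mm, pp = pp, gm = gm, gp = gp, mp = mp),
      truth = list(seed_genes = seed_genes,
                   true_metabolites = true_mets,
                   disease_phenotype = disease_phen)
    )
  })
}

#' Configuration for the synthetic expression generator
#'
#' The default design emulates a two-group whole-blood microarray comparison
#' with 13 case and 21 control samples; the first `n_de` genes receive a mean
#' shift of `effect_size` within-group standard deviations in the case group.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Sample counts per group (each >= 2).
#' @param n_de Number of planted differential genes (`<= n_genes`).
#' @param effect_size Mean shift in units of `noise_sd` (>= 0).
#' @param noise_sd Within-group standard deviation (> 0).
#' @param rng_seed Integer seed.
#' @return A validated list of class `synth_expr_config`.
#' @export
synthetic_expr_config <- function(n_genes = 200, n_case = 13, n_control = 21,
                                  n_de = 20, effect_size = 3, noise_sd = 1,
                                  rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control), n_de = as.integer(n_de),
              effect_size = effect_size, noise_sd = noise_sd,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_de > cfg$n_genes) stop("n_de > n_genes")
  if (cfg$n_case < 2L || cfg$n_control < 2L) {
    stop("n_case and n_control must each be >= 2 (t-test undefined otherwise)")
  }
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  structure(cfg, class = "synth_expr_config")
}

#' Generate a synthetic two-group expression matrix
#'
#' Gaussian noise with standard deviation `noise_sd` everywhere; the first
#' `n_de` genes get a `+effect_size * noise_sd` mean shift in the case group.
#' Gene IDs follow the same `G%04d` scheme as [generate_hetnet()] so the
#' matrix plugs directly into the network pipeline.
#'
#' @param config A [synthetic_expr_config()].
#' @return A list with `matrix` (an [expression_matrix()]) and `de_genes`
#'   (character vector of planted differential gene IDs).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_expr_config"))
  withr::with_seed(config$rng_seed, {
    n_samp <- config$n_case + config$n_control
    vals <- matrix(rnorm(config$n_genes * n_samp, 0, config$noise_sd),
                   nrow = config$n_genes)
    rownames(vals) <- layer_ids("G", config$n_genes)
    colnames(vals) <- sprintf("S%03d", seq_len(n_samp))
    labels <- setNames(rep(c("case", "control"),
                           c(config$n_case, config$n_control)),
                       colnames(vals))
    de_genes <- head(rownames(vals), config$n_de)
    if (config$n_de > 0L) {
      shift <- config$effect_size * config$noise_sd
      vals[seq_len(config$n_de), labels == "case"] <-
        vals[seq_len(config$n_de), labels == "case"] + shift
    }
    list(matrix = expression_matrix(vals, labels), de_genes = de_genes)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits everything the pipeline consumes: the six edge-set TSVs, the
#' expression matrix and label TSVs, a seed file (seed genes + disease
#' phenotype), and the planted truth for later evaluation.
#'
#' @param net A [generate_hetnet()] result.
#' @param expr A [generate_expression()] result.
#' @param out_dir Output directory, created if absent.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic_bundle <- function(net, expr, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (part in names(net$edgesets)) {
    p <- file.path(out_dir, paste0(part, ".tsv"))
    write_edgeset(net$edgesets[[part]], p)
    paths[part] <- p
  }
  expr_path <- file.path(out_dir, "expression.tsv")
  em <- expr$matrix
  expr_dt <- data.table::data.table(gene_id = rownames(em$values))
  expr_dt <- cbind(expr_dt, data.table::as.data.table(em$values))
  data.table::fwrite(expr_dt, expr_path, sep = "\t")
  paths["expression"] <- expr_path

  labels_path <- file.path(out_dir, "labels.tsv")
  data.table::fwrite(data.table::data.table(sample_id = names(em$labels),
                                            group = unname(em$labels)),
                     labels_path, sep = "\t")
  paths["labels"] <- labels_path

  seeds_path <- file.path(out_dir, "seeds.tsv")
  tr <- net$truth
  data.table::fwrite(
    data.table::data.table(
      type = c(rep("gene", length(tr$seed_genes)), "phenotype"),
      id = c(tr$seed_genes, tr$disease_phenotype)),
    seeds_path, sep = "\t")
  paths["seeds"] <- seeds_path

  truth_path <- file.path(out_dir, "planted_truth.tsv")
  data.table::fwrite(
    data.table::data.table(
      type = c(rep("seed_gene", length(tr$seed_genes)),
               rep("true_metabolite", length(tr$true_metabolites)),
               "disease_phenotype",
               rep("de_gene", length(expr$de_genes))),
      id = c(tr$seed_genes, tr$true_metabolites, tr$disease_phenotype,
             expr$de_genes)),
    truth_path, sep = "\t")
  paths["truth"] <- truth_path
  invisible(paths)
}

#' Read a seed file
#'
#' Two-column TSV (`type`, `id`) with type in gene/phenotype/metabolite.
#'
#' @param path Seed file path.
#' @return List with `seed_genes`, `seed_phenotypes`, `seed_metabolites`.
#' @export
read_seeds <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ty <- as.character(dt[[1L]])
  id <- as.character(dt[[2L]])
  if (!all(ty %in% c("gene", "phenotype", "metabolite"))) {
    stop("seed types must be gene, phenotype or metabolite")
  }
  list(seed_genes = id[ty == "gene"],
       seed_phenotypes = id[ty == "phenotype"],
       seed_metabolites = id[ty == "metabolite"])
}
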