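#' Define the seed set of the walk
#'
#' Seeds carry the prior disease knowledge: known disease genes, the disease
#' phenotype, and (when any exist) known disease metabolites. The restart
#' vector gives fraction `eta_phenotype` of its mass to the phenotype seeds
#' (split equally) and the rest to the gene and metabolite seeds (split
#' equally); if either category is empty, its mass goes to the other.
#'
#' @param seed_genes,seed_phenotypes,seed_metabolites Character ID vectors;
#'   at least one seed overall.
#' @param eta_phenotype Fraction of restart mass for the phenotype seeds,
#'   in `[0, 1]` (default 0.5).
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(seed_genes = character(),
                     seed_phenotypes = character(),
                     seed_metabolites = character(),
                     eta_phenotype = 0.5) {
  if (!is.numeric(eta_phenotype) || eta_phenotype < 0 || eta_phenotype > 1) {
    stop("eta_phenotype must be in [0, 1]")
  }
  seeds <- list(seed_genes = unique(as.character(seed_genes)),
                seed_phenotypes = unique(as.character(seed_phenotypes)),
                seed_metabolites = unique(as.character(seed_metabolites)),
                eta_phenotype = eta_phenotype)
  if (!length(c(seeds$seed_genes, seeds$seed_phenotypes,
                seeds$seed_metabolites))) {
    stop("at least one seed is required")
  }
  structure(seeds, class = "seed_set")
}

#' Build the restart (teleport) vector from a seed set
#'
#' @param net A `hetnet`.
#' @param seeds A [seed_set()]; every seed ID must exist in the network (a
#'   missing ID is an error naming it).
#' @return Numeric vector over `net$nodes$id`, summing to 1.
#' @export
build_restart_vector <- function(net, seeds) {
  stopifnot(inherits(net, "hetnet"), inherits(seeds, "seed_set"))
  ids <- net$nodes$id
  all_seeds <- c(seeds$seed_genes, seeds$seed_phenotypes,
                 seeds$seed_metabolites)
  missing <- setdiff(all_seeds, ids)
  if (length(missing)) {
    stop("seed ID not in network: ", paste(missing, collapse = ", "))
  }
  gm_seeds <- c(seeds$seed_genes, seeds$seed_metabolites)
  ph_seeds <- seeds$seed_phenotypes
  eta <- seeds$eta_phenotype
  if (!length(ph_seeds)) eta <- 0
  if (!length(gm_seeds)) eta <- 1
  p0 <- setNames(numeric(length(ids)), ids)
  if (length(ph_seeds)) p0[ph_seeds] <- eta / length(ph_seeds)
  if (length(gm_seeds)) p0[gm_seeds] <- (1 - eta) / length(gm_seeds)
  p0
}

check_rwr_params <- function(beta, tol, max_iter) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1) {
    stop("beta must be in (0, 1]")
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (!is.numeric(max_iter) || max_iter < 1) stop("max_iter must be >= 1")
}

#' Random walk with restart by power iteration
#'
#' Iterates `p <- (1 - beta) * W p + beta * p0 + (1 - beta) * m_d * p0`,
#' where `m_d` is the probability mass sitting on dangling (isolated) nodes —
#' teleporting dangling mass back to the seeds keeps every iterate a proper
#' probability vector. At each step the walker either moves to a neighbor
#' (probability `1 - beta`) or restarts at the seeds (probability `beta`).
#' Iteration stops when the L1 change drops below `tol`.
#'
#' @param model A `transition_model` from [build_transition()].
#' @param p0 Restart vector over the model's nodes, non-negative, sum 1.
#' @param beta Restart probability in `(0, 1]` (default 0.7).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Maximum iterations (default 1000); non-convergence
#'   returns with `converged = FALSE` and a warning, never an error.
#' @return List with `scores` (named numeric vector, sums to 1), `n_iter`,
#'   `converged` and `residuals` (L1 change per iteration).
#' @export
rwr_power <- function(model, p0, beta = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(model, "transition_model"))
  check_rwr_params(beta, tol, max_iter)
  p0 <- as.numeric(p0)
  n <- length(model$node_ids)
  if (length(p0) != n) stop("p0 length does not match network size")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8) {
    stop("p0 must be non-negative and sum to 1")
  }
  W <- model$W
  dang <- model$dangling
  p <- p0
  converged <- FALSE
  it <- 0L
  residuals <- numeric()
  while (it < max_iter) {
    it <- it + 1L
    pn <- (1 - beta) * as.numeric(W %*% p) + beta * p0
    if (any(dang)) pn <- pn + (1 - beta) * sum(p[dang]) * p0
    delta <- sum(abs(pn - p))
    residuals[it] <- delta
    p <- pn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("RWR did not converge in ", max_iter, " iterations")
  }
  list(scores = setNames(p, model$node_ids), n_iter = it,
       converged = converged, residuals = residuals)
}

#' Direct linear-solve reference for the walk
#'
#' Solves the fixed point `p = (1 - beta) (W + p0 d^T) p + beta p0` exactly
#' by a dense solve (`d` is the dangling-node indicator, so dangling mass is
#' teleported identically to [rwr_power()]). Intended as an independent
#' verification oracle on small networks; guarded to at most 2000 nodes.
#'
#' @param model A `transition_model`.
#' @param p0 Restart vector, non-negative, sum 1.
#' @param beta Restart probability in `(0, 1]`.
#' @return Named numeric score vector summing to 1.
#' @export
rwr_solve_oracle <- function(model, p0, beta = 0.7) {
  stopifnot(inherits(model, "transition_model"))
  check_rwr_params(beta, tol = 1, max_iter = 1)
  n <- length(model$node_ids)
  if (n > 2000L) stop("oracle solve is guarded to <= 2000 nodes, got ", n)
  p0 <- as.numeric(p0)
  if (length(p0) != n) stop("p0 length does not match network size")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8) {
    stop("p0 must be non-negative and sum to 1")
  }
  M <- as.matrix(model$W)
  if (any(model$dangling)) {
    M <- M + outer(p0, as.numeric(model$dangling))
  }
  A <- diag(n) - (1 - beta) * M
  p <- solve(A, beta * p0)
  p <- p / sum(p)
  setNames(p, model$node_ids)
}

#' Write a score vector as TSV
#'
#' Columns: `node_id`, `layer`, `score`, `rank_in_layer` (dense rank of the
#' score within its layer, descending, ties broken by ID).
#'
#' @param scores Named score vector over the network's nodes.
#' @param net The `hetnet` the scores refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, net, path) {
  df <- data.frame(node_id = net$nodes$id, layer = net$nodes$layer,
                   score = as.numeric(scores[net$nodes$id]),
                   stringsAsFactors = FALSE)
  df$rank_in_layer <- stats::ave(
    seq_len(nrow(df)), df$layer,
    FUN = function(idx) {
      o <- order(-df$score[idx], df$node_id[idx])
      r <- integer(length(idx))
      r[o] <- seq_along(idx)
      r
    })
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
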