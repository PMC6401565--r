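#' Rank candidate metabolites by walk score
#'
#' Restricts the score vector to metabolite-layer nodes, excludes any seed
#' metabolites (known disease metabolites are not candidates), sorts by score
#' descending with ties broken by ID ascending, and truncates to the top `k`.
#' Raw walk scores are reported without renormalization.
#'
#' @param scores Named score vector over the network's nodes.
#' @param net The `hetnet` the scores refer to.
#' @param k Number of metabolites to keep (default 50); fewer are returned
#'   when fewer candidates exist.
#' @param exclude Character vector of metabolite IDs to exclude (seed
#'   metabolites).
#' @return A `data.frame` with columns `rank`, `metabolite_id`, `score`.
#' @export
rank_metabolites <- function(scores, net, k = 50L, exclude = character()) {
  stopifnot(inherits(net, "hetnet"), k >= 1)
  mets <- setdiff(layer_nodes(net, "metabolite"), exclude)
  if (!length(mets)) stop("network has no candidate metabolite nodes")
  sc <- as.numeric(scores[mets])
  o <- order(-sc, mets)
  keep <- head(o, min(as.integer(k), length(mets)))
  data.frame(rank = seq_along(keep),
             metabolite_id = mets[keep],
             score = sc[keep],
             stringsAsFactors = FALSE)
}

#' Top co-expressed genes of the ranked metabolites
#'
#' Candidate genes are the gene-layer nodes adjacent, through gene-metabolite
#' edges, to at least one ranked metabolite; they are ordered by their own
#' walk score (descending, ID tiebreak) and truncated to the top `n`. This
#' operationalizes "co-expressed genes interacting with the top metabolites,
#' selected on the score distribution": the walk score is the only score in
#' play, and adjacency is the stated interaction.
#'
#' @param scores Named score vector.
#' @param net The `hetnet`.
#' @param top_mets A ranking from [rank_metabolites()].
#' @param n Number of genes to keep (default 100).
#' @return A `data.frame` with columns `rank`, `gene_id`, `score` (possibly
#'   zero rows, with a warning, when no gene touches a ranked metabolite).
#' @export
top_coexpressed_genes <- function(scores, net, top_mets, n = 100L) {
  stopifnot(inherits(net, "hetnet"), n >= 1)
  gm <- net$edges[net$edges$part == "gm", , drop = FALSE]
  hit <- gm$node_b %in% top_mets$metabolite_id
  cand <- sort(unique(gm$node_a[hit]))
  if (!length(cand)) {
    warning("no genes adjacent to the ranked metabolites")
    return(data.frame(rank = integer(), gene_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  sc <- as.numeric(scores[cand])
  o <- order(-sc, cand)
  keep <- head(o, min(as.integer(n), length(cand)))
  data.frame(rank = seq_along(keep), gene_id = cand[keep], score = sc[keep],
             stringsAsFactors = FALSE)
}

#' Extract the induced subnetwork on a node set
#'
#' @param net A `hetnet`.
#' @param keep Character vector of node IDs, all present in the network
#'   (an unknown ID is an error naming it).
#' @return An object of class `subnetwork`: list with `nodes` (the kept IDs)
#'   and `edges` (induced edge data.frame with `node_a`, `node_b`, `weight`,
#'   `part`).
#' @export
extract_subnetwork <- function(net, keep) {
  stopifnot(inherits(net, "hetnet"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, net$nodes$id)
  if (length(unknown)) {
    stop("unknown node ID in keep set: ", paste(head(unknown, 5),
                                                collapse = ", "))
  }
  sel <- net$edges$node_a %in% keep & net$edges$node_b %in% keep
  structure(list(nodes = keep,
                 edges = net$edges[sel, , drop = FALSE]),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork nodes=%d edges=%d>\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Degree table of a subnetwork
#'
#' Unweighted undirected degree (incident induced edge count) per node,
#' sorted descending with ties broken by ID ascending. Integer degrees are
#' the hub statistic used to nominate central metabolites.
#'
#' @param sub A `subnetwork` from [extract_subnetwork()].
#' @return A `data.frame` with columns `node_id`, `degree`.
#' @export
degree_table <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"))
  deg <- setNames(integer(length(sub$nodes)), sub$nodes)
  if (nrow(sub$edges)) {
    tab <- table(c(sub$edges$node_a, sub$edges$node_b))
    deg[names(tab)] <- as.integer(tab)
  }
  df <- data.frame(node_id = names(deg), degree = unname(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$node_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Metabolites above a score threshold
#'
#' Reports the ranked metabolites whose score strictly exceeds `threshold`.
#' The threshold is an externally chosen reporting parameter.
#'
#' @param ranking A [rank_metabolites()] result.
#' @param threshold Non-negative score threshold.
#' @return List with `count` and `metabolite_ids`.
#' @export
score_threshold_report <- function(ranking, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  sel <- ranking$score > threshold
  list(count = sum(sel), metabolite_ids = ranking$metabolite_id[sel])
}

#' Write a subnetwork edge list as TSV
#' @param sub A `subnetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(sub, path) {
  data.table::fwrite(sub$edges, path, sep = "\t")
  invisible(path)
}
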