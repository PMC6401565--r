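LAYERS <- c("gene", "metabolite", "phenotype")

#' Assemble six EdgeSets into a heterogeneous network
#'
#' Builds the unified node index over the three layers (layer membership
#' inferred from each part tag) and a single symmetric sparse weighted
#' adjacency matrix holding all six blocks. An ID appearing in two different
#' layers is a hard error: the layers form disjoint ID spaces.
#'
#' @param edgesets Named list of [edgeset()]s; names/parts among
#'   `gg, mm, pp, gm, gp, mp`, each part at most once. Empty parts may be
#'   omitted.
#' @param extra_nodes Optional `data.frame` with columns `id`, `layer`
#'   declaring nodes that belong to the universe even without edges (they
#'   become dangling in the transition model).
#' @return An object of class `hetnet`: list with `nodes` (data.frame `id`,
#'   `layer`), `adjacency` (symmetric `dgCMatrix`, weights in `(0, 1]`),
#'   `edges` (data.frame `node_a`, `node_b`, `weight`, `part` with each
#'   undirected edge once) and `n_edges`.
#' @export
assemble_hetnet <- function(edgesets, extra_nodes = NULL) {
  stopifnot(is.list(edgesets), length(edgesets) >= 1L)
  parts <- vapply(edgesets, function(e) e$part, "")
  if (anyDuplicated(parts)) stop("duplicate part in edgesets: ",
                                 parts[duplicated(parts)][1L])
  if (!all(vapply(edgesets, inherits, TRUE, "edgeset"))) {
    stop("all elements must be edgesets")
  }

  # node universe with layer inferred from part tags
  id <- character()
  layer <- character()
  edge_rows <- list()
  for (es in edgesets) {
    lys <- PART_LAYERS[[es$part]]
    id <- c(id, es$edges$node_a, es$edges$node_b)
    layer <- c(layer, rep(lys[1L], nrow(es$edges)),
               rep(lys[2L], nrow(es$edges)))
    if (nrow(es$edges)) {
      edge_rows[[es$part]] <- cbind(es$edges, part = es$part)
    }
  }
  if (!is.null(extra_nodes)) {
    stopifnot(all(c("id", "layer") %in% names(extra_nodes)),
              all(extra_nodes$layer %in% LAYERS))
    id <- c(id, as.character(extra_nodes$id))
    layer <- c(layer, as.character(extra_nodes$layer))
  }
  nodes <- unique(data.frame(id = id, layer = layer,
                             stringsAsFactors = FALSE))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) {
    stop("node ID assigned to two layers: ", dup[1L])
  }
  nodes <- nodes[order(match(nodes$layer, LAYERS), nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- if (length(edge_rows)) {
    do.call(rbind, c(edge_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(node_a = character(), node_b = character(),
               weight = numeric(), part = character(),
               stringsAsFactors = FALSE)
  }

  n <- nrow(nodes)
  ia <- match(edges$node_a, nodes$id)
  ib <- match(edges$node_b, nodes$id)
  adjacency <- Matrix::sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = rep(edges$weight, 2L),
    dims = c(n, n), dimnames = list(nodes$id, nodes$id)
  )
  structure(list(nodes = nodes, adjacency = adjacency, edges = edges,
                 n_edges = nrow(edges)),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  tab <- table(factor(x$nodes$layer, levels = LAYERS))
  cat(sprintf("<hetnet nodes=%d (gene=%d metabolite=%d phenotype=%d) edges=%d>\n",
              nrow(x$nodes), tab[["gene"]], tab[["metabolite"]],
              tab[["phenotype"]], x$n_edges))
  invisible(x)
}

#' Gene/metabolite/phenotype IDs of a network layer
#' @param net A `hetnet`.
#' @param layer One of `"gene"`, `"metabolite"`, `"phenotype"`.
#' @return Character vector of node IDs in that layer.
#' @export
layer_nodes <- function(net, layer = LAYERS) {
  layer <- match.arg(layer)
  net$nodes$id[net$nodes$layer == layer]
}

#' Build the column-stochastic transition model of the walk
#'
#' For a node in layer X, the available moves are its intra-layer neighbors
#' and its neighbors in up to two cross-layer blocks. Probability mass
#' `1 - lambda_jump` goes to intra-layer neighbors proportional to edge
#' weight; `lambda_jump` is split equally among the cross-layer blocks in
#' which the node actually has edges, within each proportional to weight.
#' Nodes with no intra-layer edges send all mass across layers (split equally
#' among available blocks); nodes with no cross-layer edges keep all mass in
#' their own layer; isolated nodes are dangling and get an all-zero column
#' (their probability is teleported to the restart vector during the walk).
#'
#' @param net A `hetnet` from [assemble_hetnet()].
#' @param lambda_jump Cross-layer jump probability in `[0, 1]` (default 0.5).
#' @return An object of class `transition_model`: list with `W` (sparse
#'   column-stochastic matrix), `dangling` (logical vector), `lambda_jump`
#'   and `node_ids`.
#' @export
build_transition <- function(net, lambda_jump = 0.5) {
  stopifnot(inherits(net, "hetnet"))
  if (!is.numeric(lambda_jump) || length(lambda_jump) != 1L ||
      lambda_jump < 0 || lambda_jump > 1) {
    stop("lambda_jump must be a single number in [0, 1]")
  }
  A <- methods::as(net$adjacency, "CsparseMatrix")
  n <- nrow(A)
  layer_idx <- match(net$nodes$layer, LAYERS)

  # weighted degree of each node into each layer (3 x n)
  blockdeg <- rbind(
    Matrix::colSums(A[layer_idx == 1L, , drop = FALSE]),
    Matrix::colSums(A[layer_idx == 2L, , drop = FALSE]),
    Matrix::colSums(A[layer_idx == 3L, , drop = FALSE])
  )

  intra_ind <- cbind(layer_idx, seq_len(n))
  d_intra <- blockdeg[intra_ind]
  avail <- blockdeg > 0
  avail[intra_ind] <- FALSE              # cross-layer availability only
  k <- colSums(avail)

  # per-column mass allocated to each target layer
  coef <- matrix(0, 3L, n)
  cross_mass <- ifelse(k > 0, ifelse(d_intra > 0, lambda_jump, 1) / k, 0)
  coef[avail] <- rep(cross_mass, each = 3L)[avail]
  coef[intra_ind] <- ifelse(d_intra > 0, ifelse(k > 0, 1 - lambda_jump, 1), 0)

  # scale each stored entry A[i, j] by coef[layer(i), j] / blockdeg[layer(i), j]
  ii <- A@i + 1L
  jj <- rep(seq_len(n), diff(A@p))
  li <- layer_idx[ii]
  x <- A@x * coef[cbind(li, jj)] / blockdeg[cbind(li, jj)]
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = c(n, n),
                            dimnames = dimnames(A))
  W <- Matrix::drop0(W)
  dangling <- Matrix::colSums(A) == 0

  structure(list(W = W, dangling = dangling, lambda_jump = lambda_jump,
                 node_ids = net$nodes$id),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model n=%d dangling=%d lambda_jump=%g>\n",
              length(x$node_ids), sum(x$dangling), x$lambda_jump))
  invisible(x)
}

#' Write the node table of a network
#' @param net A `hetnet`.
#' @param path Output TSV path (`id`, `layer`).
#' @return `path`, invisibly.
#' @export
write_node_table <- function(net, path) {
  data.table::fwrite(net$nodes, path, sep = "\t")
  invisible(path)
}
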