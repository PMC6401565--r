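#' @importFrom stats rbinom runif rnorm pt median setNames
#' @importFrom utils head
NULL

# Layer pair declared by each network part. Intra-layer parts are undirected
# within one layer; bipartite parts connect two distinct layers with node_a
# always in the first layer of the pair.
PART_LAYERS <- list(
  gg = c("gene", "gene"),
  mm = c("metabolite", "metabolite"),
  pp = c("phenotype", "phenotype"),
  gm = c("gene", "metabolite"),
  gp = c("gene", "phenotype"),
  mp = c("metabolite", "phenotype")
)

EDGE_PARTS <- names(PART_LAYERS)

is_intra_part <- function(part) part %in% c("gg", "mm", "pp")

#' Construct an EdgeSet
#'
#' An EdgeSet is the universal exchange format for one part of the
#' heterogeneous network: an undirected, weighted node-pair list tagged with
#' its part (`gg`, `mm`, `pp`, `gm`, `gp`, `mp`). Construction canonicalizes
#' the edge list: self-loops are dropped, duplicate unordered pairs collapse
#' to the maximum weight, and intra-layer pairs are stored with endpoints in
#' lexicographic order.
#'
#' @param part One of `"gg"`, `"mm"`, `"pp"`, `"gm"`, `"gp"`, `"mp"`.
#' @param node_a,node_b Character vectors of node IDs. For bipartite parts
#'   `node_a` belongs to the first layer of the part tag and `node_b` to the
#'   second.
#' @param weight Numeric edge weights in `(0, 1]`.
#' @return An object of class `edgeset`: a list with elements `part` and
#'   `edges` (a `data.frame` with columns `node_a`, `node_b`, `weight`).
#' @export
edgeset <- function(part, node_a = character(), node_b = character(),
                    weight = numeric()) {
  part <- match.arg(part, EDGE_PARTS)
  node_a <- as.character(node_a)
  node_b <- as.character(node_b)
  weight <- as.numeric(weight)
  if (length(node_a) != length(node_b) || length(node_a) != length(weight)) {
    stop("node_a, node_b and weight must have equal length")
  }
  if (length(weight) && (any(!is.finite(weight)) ||
                         any(weight <= 0) || any(weight > 1))) {
    stop("edge weights must be finite and in (0, 1]")
  }
  keep <- node_a != node_b
  if (is_intra_part(part)) {
    a <- pmin(node_a[keep], node_b[keep])
    b <- pmax(node_a[keep], node_b[keep])
  } else {
    if (any(!keep)) {
      # shared IDs across two layers would be a layer collision downstream
      stop("bipartite part '", part, "' has an edge with identical endpoints: ",
           node_a[!keep][1])
    }
    a <- node_a
    b <- node_b
  }
  w <- weight[if (is_intra_part(part)) keep else TRUE]
  edges <- collapse_max(a, b, w)
  structure(list(part = part, edges = edges), class = "edgeset")
}

# Collapse duplicate (a, b) pairs keeping the maximum weight; stable order
# by (a, b) so that construction is canonical and deterministic.
collapse_max <- function(a, b, w) {
  if (!length(a)) {
    return(data.frame(node_a = character(), node_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(a, b, sep = "\r")
  w_max <- tapply(w, key, max)
  keys <- sort(names(w_max))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    node_a = vapply(parts, `[[`, "", 1L),
    node_b = vapply(parts, `[[`, "", 2L),
    weight = as.numeric(w_max[keys]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' @export
print.edgeset <- function(x, ...) {
  cat(sprintf("<edgeset part=%s edges=%d nodes=%d>\n", x$part,
              nrow(x$edges), length(edgeset_nodes(x))))
  invisible(x)
}

#' Number of edges in an EdgeSet
#' @param es An `edgeset`.
#' @return Integer edge count.
#' @export
n_edges <- function(es) nrow(es$edges)

#' Node IDs appearing in an EdgeSet
#'
#' @param es An `edgeset`.
#' @param side `"both"` (default), `"a"` or `"b"`; for bipartite parts the
#'   sides correspond to the two layers.
#' @return Sorted character vector of unique node IDs.
#' @export
edgeset_nodes <- function(es, side = c("both", "a", "b")) {
  side <- match.arg(side)
  ids <- switch(side,
    both = c(es$edges$node_a, es$edges$node_b),
    a = es$edges$node_a,
    b = es$edges$node_b
  )
  sort(unique(ids))
}

#' Read a scored edge file (STRING/STITCH dialect)
#'
#' Reads a 3-column tab-separated file of scored node pairs, rescales the
#' score column to `[0, 1]` by `score_scale`, drops edges below `min_score`
#' (strict: an edge is kept iff `score / score_scale >= min_score`, matching
#' the "not less than" convention of STRING combine-scores), removes
#' self-loops and collapses duplicates to the maximum weight.
#'
#' @param path File path. Tab-separated, with a header row; columns are
#'   interpreted positionally as node_a, node_b, score.
#' @param part Part tag for the resulting EdgeSet.
#' @param min_score Retention threshold on the rescaled score (default 0,
#'   i.e. keep all; set 0.8 for STRING-style combine-score filtering).
#' @param score_scale Divisor converting file scores to `[0, 1]` (1000 for
#'   STRING-style integer scores, 1 for already-normalized scores).
#' @return An `edgeset`.
#' @export
read_scored_edges <- function(path, part, min_score = 0, score_scale = 1) {
  stopifnot(is.numeric(min_score), length(min_score) == 1L,
            is.numeric(score_scale), length(score_scale) == 1L,
            score_scale > 0)
  dt <- read_tsv_checked(path, n_cols = 3L)
  score <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(score))
  if (length(bad)) {
    stop("malformed score in ", path, " at data line ", bad[1L],
         ": '", dt[[3L]][bad[1L]], "'")
  }
  out_of_range <- which(score < 0 | score > score_scale)
  if (length(out_of_range)) {
    stop("score outside [0, ", score_scale, "] in ", path,
         " at data line ", out_of_range[1L], ": ", score[out_of_range[1L]])
  }
  w <- score / score_scale
  keep <- w >= min_score & w > 0
  edgeset(part,
          node_a = as.character(dt[[1L]])[keep],
          node_b = as.character(dt[[2L]])[keep],
          weight = w[keep])
}

#' Read an unweighted pair file (OMIM/HMDB dialect)
#'
#' Reads a 2-column tab-separated file of node pairs for the phenotype-gene
#' or phenotype-metabolite association parts and assigns every edge weight
#' exactly 1, the convention for curated association links.
#'
#' @param path File path. Tab-separated with a header row.
#' @param part `"gp"` or `"mp"`.
#' @return An `edgeset` with all weights 1.
#' @export
read_unit_edges <- function(path, part = c("gp", "mp")) {
  part <- match.arg(part)
  dt <- read_tsv_checked(path, n_cols = 2L)
  edgeset(part,
          node_a = as.character(dt[[1L]]),
          node_b = as.character(dt[[2L]]),
          weight = rep(1, nrow(dt)))
}

# Shared strict TSV reader: exactly n_cols columns, header row, errors carry
# the 1-based data line number.
read_tsv_checked <- function(path, n_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty file: ", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(as.data.frame(matrix(character(), 0, n_cols),
                         stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != n_cols)
  if (length(bad)) {
    stop("malformed row in ", path, " at data line ", bad[1L], ": expected ",
         n_cols, " tab-separated fields, found ", nf[bad[1L]])
  }
  cols <- lapply(seq_len(n_cols), function(k) vapply(fields, `[[`, "", k))
  as.data.frame(cols, col.names = paste0("V", seq_len(n_cols)),
                stringsAsFactors = FALSE)
}

#' Translate node IDs of an EdgeSet
#'
#' Applies an ID mapping (e.g. STRING protein identifiers to gene symbols) to
#' both endpoints of every edge. Edges with an unmapped endpoint are dropped
#' and the unmapped IDs are reported; edges whose endpoints become identical
#' after mapping are removed as self-loops; duplicates arising from
#' many-to-one mappings are re-collapsed keeping the maximum weight.
#'
#' @param es An `edgeset`.
#' @param mapping Named character vector: `names(mapping)` are source IDs,
#'   values are target IDs.
#' @param sides Which endpoints to map: `"both"` (default), `"a"` or `"b"`.
#' @return A list with elements `edges` (the translated `edgeset`) and
#'   `unmapped` (character vector of source IDs that had no mapping).
#' @export
map_node_ids <- function(es, mapping, sides = c("both", "a", "b")) {
  sides <- match.arg(sides)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  a <- es$edges$node_a
  b <- es$edges$node_b
  unmapped <- character()
  ok <- rep(TRUE, length(a))
  if (sides %in% c("both", "a")) {
    ma <- mapping[a]
    unmapped <- c(unmapped, a[is.na(ma)])
    ok <- ok & !is.na(ma)
    a <- unname(ifelse(is.na(ma), a, ma))
  }
  if (sides %in% c("both", "b")) {
    mb <- mapping[b]
    unmapped <- c(unmapped, b[is.na(mb)])
    ok <- ok & !is.na(mb)
    b <- unname(ifelse(is.na(mb), b, mb))
  }
  keep <- ok & (a != b)
  list(
    edges = edgeset(es$part, a[keep], b[keep], es$edges$weight[keep]),
    unmapped = sort(unique(unmapped))
  )
}

#' Restrict a gene-gene EdgeSet to a gene set
#'
#' Keeps only edges with both endpoints in `keep`. Used with the DEG set to
#' form the informative gene network from the background interaction network.
#'
#' @param es An `edgeset` with `part == "gg"`.
#' @param keep Character vector of gene IDs to retain.
#' @return The filtered `edgeset`.
#' @export
restrict_to_genes <- function(es, keep) {
  stopifnot(inherits(es, "edgeset"))
  if (es$part != "gg") stop("restrict_to_genes requires a gg edgeset")
  sel <- es$edges$node_a %in% keep & es$edges$node_b %in% keep
  edgeset("gg", es$edges$node_a[sel], es$edges$node_b[sel],
          es$edges$weight[sel])
}

#' Filter a bipartite EdgeSet by layer node sets
#'
#' Keeps only edges whose `node_a` endpoint is in `layer_a_nodes` and whose
#' `node_b` endpoint is in `layer_b_nodes` — e.g. restrict gene-metabolite
#' associations to metabolites present in the metabolite network and genes
#' present in the gene network.
#'
#' @param es A bipartite `edgeset` (`gm`, `gp` or `mp`).
#' @param layer_a_nodes,layer_b_nodes Character ID sets for the two layers.
#' @return The filtered `edgeset`.
#' @export
cross_filter <- function(es, layer_a_nodes, layer_b_nodes) {
  stopifnot(inherits(es, "edgeset"))
  if (is_intra_part(es$part)) stop("cross_filter requires a bipartite part")
  sel <- es$edges$node_a %in% layer_a_nodes &
    es$edges$node_b %in% layer_b_nodes
  edgeset(es$part, es$edges$node_a[sel], es$edges$node_b[sel],
          es$edges$weight[sel])
}

#' Write an EdgeSet to its TSV dialect
#'
#' The on-disk dialect is a `#part=<tag>` comment line followed by a header
#' and tab-separated `node_a`, `node_b`, `weight` columns. `read_edgeset()`
#' round-trips it losslessly.
#'
#' @param es An `edgeset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgeset <- function(es, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#part=%s", es$part), "node_a\tnode_b\tweight"), con)
  if (nrow(es$edges)) {
    writeLines(sprintf("%s\t%s\t%.17g", es$edges$node_a, es$edges$node_b,
                       es$edges$weight), con)
  }
  invisible(path)
}

#' Read an EdgeSet written by [write_edgeset()]
#' @param path File path.
#' @return An `edgeset`.
#' @export
read_edgeset <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!grepl("^#part=", first)) {
    stop("not an edgeset file (missing '#part=' header): ", path)
  }
  part <- sub("^#part=", "", first)
  dt <- read_tsv_checked(path, n_cols = 3L)
  w <- as.numeric(dt[[3L]])
  edgeset(part, dt[[1L]], dt[[2L]], w)
}
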