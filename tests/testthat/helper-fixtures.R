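# Shared fixture builders. Everything is generated in code under fixed seeds.

# Random edgeset over arbitrary prefixed IDs; may contain no edges.
rand_edgeset <- function(part, n_a, n_b = n_a, density = 0.2) {
  pre <- strsplit(part, "")[[1]]
  pref <- c(g = "G", m = "M", p = "P")
  ids_a <- sprintf("%s%04d", pref[pre[1]], seq_len(n_a))
  ids_b <- sprintf("%s%04d", pref[pre[2]], seq_len(n_b))
  pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  if (part %in% c("gg", "mm", "pp")) pairs <- pairs[pairs$a < pairs$b, ]
  keep <- runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  edgeset(part, pairs$a, pairs$b, runif(nrow(pairs), 0.1, 1))
}

# Small random heterogeneous network (always includes all six parts).
rand_hetnet <- function(n_g = 20, n_m = 10, n_p = 5, density = 0.2) {
  assemble_hetnet(list(
    rand_edgeset("gg", n_g, density = density),
    rand_edgeset("mm", n_m, density = density),
    rand_edgeset("pp", n_p, density = density),
    rand_edgeset("gm", n_g, n_m, density = density),
    rand_edgeset("gp", n_g, n_p, density = density),
    rand_edgeset("mp", n_m, n_p, density = density)
  ))
}

# Hand-built two-node, one-edge, single-layer network.
two_node_net <- function() {
  assemble_hetnet(list(edgeset("gg", "G1", "G2", 1)))
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
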