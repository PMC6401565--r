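test_that("edgeset construction canonicalizes: self-loops, duplicates, order", {
  es <- edgeset("gg", c("B", "A", "A"), c("A", "B", "A"), c(0.9, 0.8, 0.5))
  expect_equal(nrow(es$edges), 1L)
  expect_equal(es$edges$node_a, "A")
  expect_equal(es$edges$node_b, "B")
  expect_equal(es$edges$weight, 0.9)  # max-collapse

  expect_error(edgeset("gg", "A", "B", 0), "weights")
  expect_error(edgeset("gg", "A", "B", 1.2), "weights")
  expect_error(edgeset("gm", "X", "X", 0.5), "identical endpoints")
})

test_that("read_scored_edges applies threshold, dedupe and self-loop rules", {
  f <- write_tsv_lines(c("node_a\tnode_b\tscore",
                         "A\tB\t900", "B\tA\t900", "A\tA\t950"))
  es <- read_scored_edges(f, "gg", min_score = 0.8, score_scale = 1000)
  expect_equal(es$edges,
               data.frame(node_a = "A", node_b = "B", weight = 0.9,
                          stringsAsFactors = FALSE))

  # strict "not less than" boundary: 799 excluded, 800 included
  f2 <- write_tsv_lines(c("node_a\tnode_b\tscore", "A\tB\t799"))
  expect_equal(n_edges(read_scored_edges(f2, "gg", 0.8, 1000)), 0L)
  f3 <- write_tsv_lines(c("node_a\tnode_b\tscore", "A\tB\t800"))
  expect_equal(n_edges(read_scored_edges(f3, "gg", 0.8, 1000)), 1L)
})

test_that("read_scored_edges rejects malformed rows and bad scores with line numbers", {
  f <- write_tsv_lines(c("a\tb\ts", "A\tB\t0.5", "A\tB"))
  expect_error(read_scored_edges(f, "gg"), "data line 2")
  f2 <- write_tsv_lines(c("a\tb\ts", "A\tB\tfoo"))
  expect_error(read_scored_edges(f2, "gg"), "malformed score.*line 1")
  f3 <- write_tsv_lines(c("a\tb\ts", "A\tB\t1500"))
  expect_error(read_scored_edges(f3, "gg", score_scale = 1000), "outside")
})

test_that("read_scored_edges matches a brute-force line filter on random files", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- 1000
      a <- sprintf("N%03d", sample(200, n, replace = TRUE))
      b <- sprintf("N%03d", sample(200, n, replace = TRUE))
      s <- sample(0:1000, n, replace = TRUE)
      f <- write_tsv_lines(c("a\tb\ts", paste(a, b, s, sep = "\t")))
      es <- read_scored_edges(f, "gg", min_score = 0.8, score_scale = 1000)
      # oracle: per-line filter, drop loops, dedupe unordered pairs by max
      ok <- s / 1000 >= 0.8 & a != b
      key <- paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
      expect_equal(n_edges(es), length(unique(key)))
      w_oracle <- as.numeric(tapply(s[ok] / 1000, key, max))
      expect_equal(sort(es$edges$weight), sort(w_oracle))
    }
  })
})

test_that("read_unit_edges assigns weight 1 and dedupes", {
  f <- write_tsv_lines(c("g\tp", "G1\tP1", "G2\tP1", "G3\tP2", "G1\tP1"))
  es <- read_unit_edges(f, "gp")
  expect_equal(n_edges(es), 3L)
  expect_true(all(es$edges$weight == 1))
})

test_that("unit-edge counting on a synthetic instance of the curated-association size", {
  # 664 distinct pairs over 388 metabolites and 149 phenotypes
  withr::with_seed(5, {
    m <- sprintf("M%04d", seq_len(388))
    p <- sprintf("P%04d", seq_len(149))
    pairs <- unique(data.frame(a = sample(m, 5000, replace = TRUE),
                               b = sample(p, 5000, replace = TRUE)))
    pairs <- pairs[seq_len(664), ]
    # ensure every node is used at least once
    pairs$a[seq_along(m)] <- m
    pairs$b[664 - seq_along(p) + 1] <- p
    f <- write_tsv_lines(c("m\tp", paste(pairs$a, pairs$b, sep = "\t")))
    es <- read_unit_edges(f, "mp")
    expect_equal(length(edgeset_nodes(es, "a")), 388L)
    expect_equal(length(edgeset_nodes(es, "b")), 149L)
    expect_equal(n_edges(es), nrow(unique(pairs)))
  })
})

test_that("map_node_ids translates, collapses and reports unmapped", {
  es <- edgeset("gg", "p1", "p2", 0.9)
  r <- map_node_ids(es, c(p1 = "GA", p2 = "GB"))
  expect_equal(r$edges$edges$node_a, "GA")
  expect_equal(r$edges$edges$node_b, "GB")
  expect_length(r$unmapped, 0)

  # two proteins to one gene -> collapsed self-loop
  r2 <- map_node_ids(es, c(p1 = "GA", p2 = "GA"))
  expect_equal(n_edges(r2$edges), 0L)

  # two protein pairs mapping onto one gene pair keep the max weight
  es3 <- edgeset("gg", c("p1", "p3"), c("p2", "p4"), c(0.8, 0.9))
  r3 <- map_node_ids(es3, c(p1 = "GA", p2 = "GB", p3 = "GA", p4 = "GB"))
  expect_equal(r3$edges$edges$weight, 0.9)

  # unmapped endpoints drop their edges and are reported
  r4 <- map_node_ids(es3, c(p1 = "GA", p2 = "GB"))
  expect_equal(n_edges(r4$edges), 1L)
  expect_equal(r4$unmapped, c("p3", "p4"))
})

test_that("restrict_to_genes and cross_filter match brute-force membership oracles", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      es <- rand_edgeset("gg", 30, density = 0.3)
      keep <- sample(edgeset_nodes(es), sample(0:20, 1))
      got <- restrict_to_genes(es, keep)
      oracle <- es$edges[es$edges$node_a %in% keep &
                           es$edges$node_b %in% keep, ]
      expect_equal(got$edges, oracle, ignore_attr = TRUE)

      bes <- rand_edgeset("gm", 20, 15, density = 0.3)
      ka <- sample(edgeset_nodes(bes, "a"), sample(0:10, 1))
      kb <- sample(edgeset_nodes(bes, "b"), sample(0:10, 1))
      gotb <- cross_filter(bes, ka, kb)
      oracleb <- bes$edges[bes$edges$node_a %in% ka &
                             bes$edges$node_b %in% kb, ]
      expect_equal(gotb$edges, oracleb, ignore_attr = TRUE)
    }
  })
})

test_that("filters are idempotent and respect identity/empty limits", {
  withr::with_seed(31, {
    es <- rand_edgeset("gg", 20, density = 0.3)
    expect_equal(restrict_to_genes(es, edgeset_nodes(es)), es)
    expect_equal(n_edges(restrict_to_genes(es, character())), 0L)
    keep <- sample(edgeset_nodes(es), 8)
    once <- restrict_to_genes(es, keep)
    expect_equal(restrict_to_genes(once, keep), once)

    bes <- rand_edgeset("gm", 15, 10, density = 0.3)
    expect_equal(cross_filter(bes, edgeset_nodes(bes, "a"),
                              edgeset_nodes(bes, "b")), bes)
    expect_equal(n_edges(cross_filter(bes, character(),
                                      edgeset_nodes(bes, "b"))), 0L)
  })
})

test_that("edgeset TSV round trip is lossless", {
  withr::with_seed(41, {
    for (part in c("gg", "gm", "mp")) {
      es <- rand_edgeset(part, 15, 10, density = 0.4)
      f <- tempfile(fileext = ".tsv")
      write_edgeset(es, f)
      expect_equal(read_edgeset(f), es)
    }
    # empty edgeset round-trips too
    e0 <- edgeset("pp")
    f0 <- tempfile(fileext = ".tsv")
    write_edgeset(e0, f0)
    expect_equal(read_edgeset(f0), e0)
  })
})
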