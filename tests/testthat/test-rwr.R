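test_that("restart vector follows the split and reassignment rules", {
  h <- assemble_hetnet(list(
    edgeset("gg", sprintf("G%d", 1:6), sprintf("G%d", 2:7),
            rep(0.5, 6)),
    edgeset("gp", "G1", "P1", 1),
    edgeset("gm", "G1", "M1", 0.5)
  ))
  # 6 gene seeds + 1 phenotype seed, eta = 0.5
  s <- seed_set(sprintf("G%d", 1:6), "P1", eta_phenotype = 0.5)
  p0 <- build_restart_vector(h, s)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0["P1"]), 0.5)
  expect_equal(unname(p0[sprintf("G%d", 1:6)]), rep(0.5 / 6, 6))

  # single phenotype seed gets everything regardless of eta
  p1 <- build_restart_vector(h, seed_set(seed_phenotypes = "P1",
                                         eta_phenotype = 0.2))
  expect_equal(unname(p1["P1"]), 1)
  # no phenotype seeds: gene/metabolite seeds absorb the phenotype share
  p2 <- build_restart_vector(h, seed_set("G1", seed_metabolites = "M1",
                                         eta_phenotype = 0.8))
  expect_equal(unname(p2[c("G1", "M1")]), c(0.5, 0.5))

  expect_error(seed_set(), "at least one seed")
  expect_error(build_restart_vector(h, seed_set("NOPE")), "NOPE")
})

test_that("beta = 1 returns the restart vector in one iteration", {
  h <- two_node_net()
  tm <- build_transition(h, 0.5)
  p0 <- build_restart_vector(h, seed_set("G1"))
  r <- rwr_power(tm, p0, beta = 1)
  expect_equal(unname(r$scores), unname(p0))
  expect_equal(r$n_iter, 1L)
  expect_equal(unname(rwr_solve_oracle(tm, p0, beta = 1)), unname(p0))
})

test_that("two-node worked example gives (2/3, 1/3)", {
  h <- two_node_net()
  tm <- build_transition(h, 0.5)
  p0 <- build_restart_vector(h, seed_set("G1"))
  r <- rwr_power(tm, p0, beta = 0.5, tol = 1e-14)
  expect_equal(unname(r$scores), c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("beta -> 0 approaches weighted-degree proportions on a connected graph", {
  withr::with_seed(91, {
    repeat {  # draw until connected (checked via a BFS oracle)
      es <- rand_edgeset("gg", 12, density = 0.35)
      ids <- edgeset_nodes(es)
      adj <- split(c(es$edges$node_b, es$edges$node_a),
                   c(es$edges$node_a, es$edges$node_b))
      seen <- ids[1]
      front <- ids[1]
      while (length(front)) {
        nxt <- setdiff(unique(unlist(adj[front])), seen)
        seen <- c(seen, nxt)
        front <- nxt
      }
      if (length(seen) == 12 && length(ids) == 12) break
    }
    h <- assemble_hetnet(list(es))
    tm <- build_transition(h, 0)
    p0 <- rep(1 / 12, 12)
    r <- rwr_power(tm, p0, beta = 1e-6, tol = 1e-14, max_iter = 100000)
    wdeg <- Matrix::colSums(h$adjacency)
    expect_equal(unname(r$scores), unname(wdeg / sum(wdeg)),
                 tolerance = 1e-4)
  })
})

test_that("power iteration matches the dense linear-solve oracle", {
  withr::with_seed(101, {
    for (i in 1:10) {
      h <- rand_hetnet(sample(10:40, 1), sample(5:20, 1), sample(3:8, 1),
                       density = runif(1, 0.1, 0.4))
      tm <- build_transition(h, runif(1))
      seeds <- seed_set(sample(layer_nodes(h, "gene"), 2),
                        sample(layer_nodes(h, "phenotype"), 1))
      p0 <- build_restart_vector(h, seeds)
      beta <- runif(1, 0.1, 0.9)
      r <- rwr_power(tm, p0, beta = beta, tol = 1e-14)
      o <- rwr_solve_oracle(tm, p0, beta = beta)
      expect_lt(max(abs(r$scores - o)), 1e-8)
    }
  })
  expect_error(rwr_solve_oracle(structure(list(node_ids = character(2001)),
                                          class = "transition_model"),
                                numeric(2001), 0.5), "2000")
})

test_that("probability is conserved at every iterate, dangling included", {
  withr::with_seed(111, {
    h <- assemble_hetnet(
      list(rand_edgeset("gg", 10, density = 0.3),
           rand_edgeset("gm", 10, 5, density = 0.3)),
      extra_nodes = data.frame(id = c("M9999", "P9999"),
                               layer = c("metabolite", "phenotype")))
    tm <- build_transition(h, 0.5)
    expect_true(all(c("M9999", "P9999") %in% names(which(tm$dangling))))
    p0 <- build_restart_vector(h, seed_set(seed_metabolites = "M9999"))
    # iterate manually and check sum at every step
    p <- p0
    for (it in 1:50) {
      p <- 0.4 * as.numeric(tm$W %*% p) + 0.6 * p0 +
        0.4 * sum(p[tm$dangling]) * p0
      expect_lt(abs(sum(p) - 1), 1e-12)
    }
    r <- rwr_power(tm, p0, beta = 0.6, tol = 1e-14)
    expect_lt(abs(sum(r$scores) - 1), 1e-10)
    expect_lt(max(abs(r$scores - rwr_solve_oracle(tm, p0, 0.6))), 1e-8)
  })
})

test_that("L1 residuals decrease at a geometric rate of at least (1 - beta)", {
  withr::with_seed(121, {
    h <- rand_hetnet(20, 10, 5, density = 0.25)
    tm <- build_transition(h, 0.5)
    p0 <- build_restart_vector(h, seed_set(layer_nodes(h, "gene")[1:3]))
    for (beta in c(0.3, 0.7)) {
      r <- rwr_power(tm, p0, beta = beta, tol = 1e-12)
      res <- r$residuals
      expect_true(all(diff(res) <= 1e-15))
      ratios <- res[-1] / res[-length(res)]
      expect_true(all(ratios <= (1 - beta) + 1e-10))
    }
  })
})

test_that("unseeded disconnected components score zero in both methods", {
  h <- assemble_hetnet(list(
    edgeset("gg", c("G1", "G3"), c("G2", "G4"), c(0.9, 0.9))))
  tm <- build_transition(h, 0.5)
  p0 <- build_restart_vector(h, seed_set("G1"))
  r <- rwr_power(tm, p0, beta = 0.5, tol = 1e-14)
  o <- rwr_solve_oracle(tm, p0, beta = 0.5)
  expect_equal(unname(r$scores[c("G3", "G4")]), c(0, 0))
  expect_equal(unname(o[c("G3", "G4")]), c(0, 0))
})

test_that("seed scores dominate the median non-seed score on planted networks", {
  withr::with_seed(131, {
    for (i in 1:5) {
      cfg <- synthetic_net_config(n_genes = 120, n_metabolites = 50,
                                  n_phenotypes = 15,
                                  rng_seed = sample.int(1e6, 1))
      net <- generate_hetnet(cfg)
      h <- assemble_hetnet(net$edgesets)
      tm <- build_transition(h, 0.5)
      seeds <- seed_set(net$truth$seed_genes, net$truth$disease_phenotype)
      p0 <- build_restart_vector(h, seeds)
      r <- rwr_power(tm, p0)
      seed_ids <- c(net$truth$seed_genes, net$truth$disease_phenotype)
      non_seed <- setdiff(names(r$scores), seed_ids)
      expect_true(all(r$scores[seed_ids] > median(r$scores[non_seed])))
    }
  })
})

test_that("parameter validation and non-convergence warning behave", {
  h <- two_node_net()
  tm <- build_transition(h, 0.5)
  p0 <- build_restart_vector(h, seed_set("G1"))
  expect_error(rwr_power(tm, p0, beta = 0), "beta")
  expect_error(rwr_power(tm, p0, beta = 1.1), "beta")
  expect_error(rwr_power(tm, p0, tol = -1), "tol")
  expect_error(rwr_power(tm, c(0.5, 0.4)), "sum to 1")
  expect_warning(r <- rwr_power(tm, p0, beta = 0.01, tol = 1e-14,
                                max_iter = 3L), "did not converge")
  expect_false(r$converged)
  expect_equal(r$n_iter, 3L)
})
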