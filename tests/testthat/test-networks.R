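test_that("spearman_assoc matches hand computations and rank invariance", {
  s <- spearman_assoc(1:8, 1:8)
  expect_equal(s$rho, 1)
  # monotone decreasing transform: rho = -1 regardless of shape
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 5.5)
  expect_equal(spearman_assoc(x, -x^3)$rho, -1)
  # classical formula, no ties: d^2 = 4 -> 1 - 24/120 = 0.8
  h <- spearman_assoc(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(h$rho, 0.8)
  expect_equal(h$rho, brute_spearman_noties(c(1, 2, 3, 4, 5),
                                            c(2, 1, 4, 3, 5)))
  # exact permutation p at n = 5: perfect concordance has p = 2/5! = 1/60
  expect_equal(spearman_assoc(1:5, 1:5)$p, 2 / factorial(5))
  # constant vector is reported missing with a reason, not an error
  cs <- spearman_assoc(rep(1, 6), 1:6)
  expect_true(is.na(cs$rho))
  expect_identical(cs$reason, "constant input")
  expect_error(spearman_assoc(1:3, 1:3), "at least 4")
  # t-approximation agrees with cor.test for larger n
  set.seed(201)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  s30 <- spearman_assoc(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s30$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("correlation_matrix is symmetric, group-specific and alignment-invariant", {
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, n_burn = 30, n_control = 20, seed = 31)
  cm <- correlation_matrix(ds, "burn")
  expect_equal(cm$rho, t(cm$rho), tolerance = 1e-12)
  expect_equal(unname(diag(cm$rho)), rep(1, nrow(cm$rho)), tolerance = 1e-12)
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  expect_true(all(cm$n[upper.tri(cm$n)] == 30))
  expect_error(correlation_matrix(ds, "lava"), "unknown group")
  expect_error(correlation_matrix(ds, "burn", features = "NotAFeature"),
               "unknown features")

  # single-feature selection gives the 1x1 identity
  one <- correlation_matrix(ds, "control", features = "Glucose")
  expect_equal(dim(one$rho), c(1L, 1L))
  expect_equal(unname(one$rho[1, 1]), 1)

  # permuting sample order identically across panels leaves the matrix alone
  perm <- sample(nrow(ds$samples))
  ds2 <- ds
  ds2$samples <- ds$samples[perm, ]
  ds2$panels <- lapply(ds$panels, function(m) m[perm, , drop = FALSE])
  cm2 <- correlation_matrix(ds2, "burn")
  expect_equal(cm2$rho, cm$rho, tolerance = 1e-12)
})

test_that("group-specific configured correlations are recovered at n = 200", {
  cfg <- default_cfg()
  pick <- c("GlycB", "TNF-a", "V5PL", "IL-2", "Phenylalanine", "L6PN")
  targ <- list(control = configured_spearman(cfg, "control")[pick, pick],
               burn = configured_spearman(cfg, "burn")[pick, pick])
  est <- list(control = 0, burn = 0)
  for (s in 1:10) {
    ds <- simulate_cohort(cfg, n_burn = 200, n_control = 200, seed = s + 50)
    for (g in c("control", "burn"))
      est[[g]] <- est[[g]] + correlation_matrix(ds, g, features = pick)$rho / 10
  }
  for (g in c("control", "burn"))
    expect_lt(max(abs(est[[g]] - targ[[g]])), 0.1)
})

test_that("build_network applies the edge criteria and degree weights", {
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, n_burn = 25, n_control = 25, seed = 32)
  cm <- correlation_matrix(ds, "burn")

  # alpha = 0 gives zero edges, all weights 0
  empty <- build_network(cm, alpha = 0)
  expect_equal(nrow(empty$edges), 0L)
  expect_true(all(empty$nodes$weight == 0L))

  net <- build_network(cm, alpha = 0.05)
  expect_true(all(net$edges$p < 0.05))
  expect_true(all(net$edges$from != net$edges$to))     # no self-edges
  expect_equal(stats::setNames(net$nodes$weight, net$nodes$name),
               brute_degrees(net))
  # stored sign matches rho
  expect_identical(net$edges$sign, ifelse(net$edges$rho >= 0, "+", "-"))

  # three duplicated columns -> complete triangle with all degrees 2
  tri <- cbind(a = ds$panels$metabolite[, "Glucose"],
               b = ds$panels$metabolite[, "Glucose"],
               c = ds$panels$metabolite[, "Glucose"])
  cmt <- correlation_matrix(tri)
  ntri <- build_network(cmt, alpha = 0.05)
  expect_equal(nrow(ntri$edges), 3L)
  expect_true(all(ntri$nodes$weight == 2L))

  # FDR-corrected edge mode is a subset of the raw-p mode
  fdr <- build_network(cm, alpha = 0.05, correction = "fdr")
  expect_true(all(phenomet:::edge_keys(fdr) %in% phenomet:::edge_keys(net)))
  expect_error(build_network(cm, include_features = character(0)),
               "empty node set")
})

test_that("edge sets are monotone in alpha and the rho floor", {
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, n_burn = 20, n_control = 20, seed = 33)
  cm <- correlation_matrix(ds, "control")
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  keys <- lapply(alphas, function(a)
    phenomet:::edge_keys(build_network(cm, alpha = a)))
  for (i in seq_len(length(alphas) - 1L))
    expect_true(all(keys[[i]] %in% keys[[i + 1L]]))
  # higher |rho| floor only removes edges
  k0 <- phenomet:::edge_keys(build_network(cm, alpha = 0.05, min_abs_rho = 0))
  k5 <- phenomet:::edge_keys(build_network(cm, alpha = 0.05,
                                           min_abs_rho = 0.5))
  expect_true(all(k5 %in% k0))
})

test_that("degree weights equal a brute-force recount on random networks", {
  set.seed(202)
  for (i in 1:200) {
    p <- sample(4:12, 1)
    n <- sample(12:30, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    # plant a few strong correlations
    for (k in seq_len(sample(0:3, 1))) {
      ij <- sample(p, 2)
      X[, ij[2]] <- X[, ij[1]] + rnorm(n, sd = 0.3)
    }
    net <- build_network(correlation_matrix(X), alpha = runif(1, 0.01, 0.2))
    expect_equal(stats::setNames(net$nodes$weight, net$nodes$name),
                 brute_degrees(net))
  }
})

test_that("burn networks are denser than control networks across seeds", {
  cfg <- default_cfg()
  denser <- vapply(1:100, function(s) {
    ds <- simulate_cohort(cfg, n_burn = 36, n_control = 21, seed = s + 2000)
    eb <- nrow(build_network(correlation_matrix(ds, "burn"),
                             alpha = 0.05)$edges)
    ec <- nrow(build_network(correlation_matrix(ds, "control"),
                             alpha = 0.05)$edges)
    eb > ec
  }, logical(1))
  expect_gte(sum(denser), 95L)
})

test_that("compare_networks reports degree differences and unique edges", {
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, n_burn = 30, n_control = 30, seed = 34)
  nb <- build_network(correlation_matrix(ds, "burn"), alpha = 0.05)
  nc <- build_network(correlation_matrix(ds, "control"), alpha = 0.05)
  cmp <- compare_networks(nb, nc)
  expect_equal(cmp$degrees$degree_a - cmp$degrees$degree_b,
               cmp$degrees$difference)

  # identical networks: all differences zero, no unique edges
  same <- compare_networks(nb, nb)
  expect_true(all(same$degrees$difference == 0L))
  expect_equal(nrow(same$unique_to_a), 0L)

  # adding one edge raises exactly two node degrees by one
  nb2 <- nb
  absent <- which(is.na(match(
    phenomet:::edge_keys(build_network(correlation_matrix(ds, "burn"),
                                       alpha = 1)),
    phenomet:::edge_keys(nb))))[1]
  all_edges <- build_network(correlation_matrix(ds, "burn"), alpha = 1)$edges
  extra <- all_edges[absent, ]
  nb2$edges <- rbind(nb2$edges, extra)
  for (v in c(extra$from, extra$to)) {
    i <- nb2$nodes$name == v
    nb2$nodes$weight[i] <- nb2$nodes$weight[i] + 1L
  }
  cmp2 <- compare_networks(nb2, nb)
  expect_equal(sum(cmp2$degrees$difference == 1L), 2L)
  expect_equal(sum(cmp2$degrees$difference), 2L)

  # different node universes are rejected, listing the difference
  nsub <- build_network(correlation_matrix(ds, "control",
                                           features = c("Glucose", "L6CH")),
                        alpha = 0.05)
  expect_error(compare_networks(nb, nsub), "symmetric difference")
})

test_that("a configured hub node ranks first by degree in hub-wired networks", {
  ## star topology: hub H correlated 0.33 with eight spokes in the burn-like
  ## matrix (sum of squared spoke correlations < 1, so the matrix is PSD by
  ## construction); spokes mutually independent; control-like matrix empty
  p <- 12L
  nm <- c("H", paste0("S", 1:8), paste0("I", 1:3))
  feats <- data.frame(name = nm, panel = "metabolite",
                      control_mean = 1, control_sd = 0.2,
                      burn_mean = 1, burn_sd = 0.2, unit = "mmol/L")
  Rb <- diag(p); dimnames(Rb) <- list(nm, nm)
  Rb["H", paste0("S", 1:8)] <- Rb[paste0("S", 1:8), "H"] <- 0.33
  Rc <- diag(p); dimnames(Rc) <- list(nm, nm)
  tpl <- data.frame(feature = "H", center = 1, linewidth = 0.004,
                    amplitude = 1, shape = "sharp",
                    vis_standard = 1, vis_cpmg = 1, vis_jedi = 1)
  cfg <- sim_config(feats, Rc, Rb, tpl, noise_sd = 0.001)
  hub_first <- vapply(1:100, function(s) {
    ds <- simulate_cohort(cfg, n_burn = 100, n_control = 100, seed = s + 3000)
    nb <- build_network(correlation_matrix(ds, "burn"), alpha = 0.05)
    nc <- build_network(correlation_matrix(ds, "control"), alpha = 0.05)
    cmp <- compare_networks(nb, nc)
    unname(cmp$top_node["a"]) == "H"
  }, logical(1))
  expect_gte(sum(hub_first), 90L)
})

test_that("phenylalanine is the best-connected metabolite in the burn group", {
  ## study-configured contrast, in expectation over seeds at large n
  cfg <- default_cfg()
  mets <- cfg$features$name[cfg$features$panel == "metabolite"]
  deg_sum <- stats::setNames(numeric(length(mets)), mets)
  for (s in 1:20) {
    ds <- simulate_cohort(cfg, n_burn = 200, n_control = 21, seed = s + 3000)
    nb <- build_network(correlation_matrix(ds, "burn"), alpha = 0.05)
    deg_sum <- deg_sum + stats::setNames(nb$nodes$weight, nb$nodes$name)[mets]
  }
  expect_identical(names(which.max(deg_sum)), "Phenylalanine")
})

test_that("network export round trips through edge-list CSV and GraphML", {
  cfg <- default_cfg()
  ds <- simulate_cohort(cfg, n_burn = 20, n_control = 20, seed = 35)
  net <- build_network(correlation_matrix(ds, "burn"), alpha = 0.01)
  expect_gt(nrow(net$edges), 0)

  f1 <- withr::local_tempfile(fileext = ".csv")
  export_network(net, f1, "edgelist")
  back <- read_network(f1, "edgelist")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges, tolerance = 1e-15)
  expect_identical(back$group, net$group)
  expect_equal(back$criteria$alpha, net$criteria$alpha)

  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f2, "graphml")
  g <- read_network(f2, "graphml")
  expect_equal(g$nodes[order(g$nodes$name), ],
               net$nodes[order(net$nodes$name), ], ignore_attr = TRUE)
  expect_setequal(phenomet:::edge_keys(g), phenomet:::edge_keys(net))
  expect_equal(sort(g$edges$rho), sort(net$edges$rho), tolerance = 1e-9)

  # empty network still round trips
  empty <- build_network(correlation_matrix(ds, "burn"), alpha = 0)
  f3 <- withr::local_tempfile(fileext = ".csv")
  export_network(empty, f3, "edgelist")
  eb <- read_network(f3, "edgelist")
  expect_equal(nrow(eb$edges), 0L)
  expect_equal(eb$nodes, empty$nodes)

  # triangle network in GraphML: 3 nodes, 3 edges
  tri <- cbind(a = ds$panels$metabolite[, "Glucose"],
               b = ds$panels$metabolite[, "Glucose"],
               c = ds$panels$metabolite[, "Glucose"])
  ntri <- build_network(correlation_matrix(tri), alpha = 0.05)
  f4 <- withr::local_tempfile(fileext = ".graphml")
  export_network(ntri, f4, "graphml")
  doc <- readLines(f4)
  expect_equal(sum(grepl("<node ", doc)), 3L)
  expect_equal(sum(grepl("<edge ", doc)), 3L)
  expect_error(export_network(net, f1, "dot"), "arg")
})
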