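test_that("occurrence filter is strict on 'less than' and re-closes", {
  m <- make_counts(0, 3, 10)
  m[1, 1:2] <- 5    # 2/10 -> removed
  m[2, 1:3] <- 5    # exactly 3/10 -> retained
  m[3, ] <- 100     # everywhere
  tab <- otu_table(m)
  f <- suppressMessages(occurrence_filter(tab, 0.3))
  expect_setequal(f$otu_ids, c("OTU02", "OTU03"))
  expect_equal(unname(colSums(f$rel_abund)), rep(1, 10), tolerance = 1e-9)
  # min_fraction = 0 is the identity
  f0 <- suppressMessages(occurrence_filter(tab, 0))
  expect_equal(f0$counts, tab$counts)
  expect_error(suppressMessages(occurrence_filter(otu_table(m[3, , drop = FALSE]), 0.3)),
               NA)
})

test_that("spearman matrix equals rank-then-Pearson and handles constants", {
  set.seed(61)
  tab <- random_table(6, 5, lambda = 9)
  rho <- spearman_matrix(tab)
  x <- t(tab$rel_abund)
  oracle <- stats::cor(apply(x, 2, rank))
  expect_equal(unname(rho), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(diag(rho)), rep(1, 6))

  # monotone pair -> 1; reversed -> -1
  m <- make_counts(c(1, 5, 9, 2, 6, 8, 3, 7, 7, 4, 8, 6), 3, 4)
  tab2 <- otu_table(m)
  rho2 <- spearman_matrix(tab2)
  expect_equal(rho2["OTU01", "OTU02"], 1)

  # a constant OTU vector yields rho 0 with a warning
  mc <- make_counts(rep(5, 8), 2, 4)   # rel abund 0.5 everywhere
  expect_warning(rc <- spearman_matrix(otu_table(mc)), "constant")
  expect_equal(rc["OTU01", "OTU02"], 0)
  expect_error(spearman_matrix(random_table(4, 3)), ">= 4 samples")
})

test_that("build_network thresholds |rho| and keeps signs", {
  ids <- c("a", "b", "c", "d")
  rho <- diag(4)
  dimnames(rho) <- list(ids, ids)
  rho["a", "b"] <- rho["b", "a"] <- 0.9
  rho["c", "d"] <- rho["d", "c"] <- -0.85
  rho["a", "c"] <- rho["c", "a"] <- 0.5
  net <- build_network(rho, 0.8)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("+", "-"))
  expect_equal(net$n_isolated, 0)
  # edge count equals the brute-force super-threshold pair scan
  set.seed(62)
  corr <- stats::cov2cor(crossprod(matrix(rnorm(25 * 20), 25)))
  dimnames(corr) <- list(sprintf("o%02d", 1:20), sprintf("o%02d", 1:20))
  for (t_i in c(0.3, 0.5, 0.7)) {
    bf <- 0
    for (i in 1:19) for (j in (i + 1):20) if (abs(corr[i, j]) >= t_i) bf <- bf + 1
    expect_equal(nrow(build_network(corr, t_i)$edges), bf)
  }
})

two_clique_net <- function() {
  ids <- sprintf("n%02d", 1:8)
  rho <- diag(8)
  dimnames(rho) <- list(ids, ids)
  for (i in 1:4) for (j in 1:4) if (i != j) rho[i, j] <- 0.9
  for (i in 5:8) for (j in 5:8) if (i != j) rho[i, j] <- 0.9
  build_network(rho, 0.8, make_labels(ids, rep(c("abundant", "rare"), each = 4)))
}

test_that("fast-greedy modules split disconnected cliques; Q bounds hold", {
  net <- greedy_modularity(two_clique_net())
  expect_equal(length(unique(net$nodes$module)), 2)
  expect_true(net$modularity >= -0.5 && net$modularity <= 1)
  # single edge: Q = 0
  rho <- diag(2); dimnames(rho) <- list(c("a", "b"), c("a", "b"))
  rho["a", "b"] <- rho["b", "a"] <- 0.9
  net1 <- greedy_modularity(build_network(rho, 0.8))
  expect_equal(net1$modularity, 0)
  empty <- build_network(diag(2) + 0 * rho, 0.99)
  expect_error(greedy_modularity(empty), "empty network")
})

test_that("rewired nulls preserve node count, link count and degree sequence", {
  set.seed(63)
  corr <- stats::cov2cor(crossprod(matrix(rnorm(30 * 40), 30)))
  dimnames(corr) <- list(sprintf("o%02d", 1:40), sprintf("o%02d", 1:40))
  net <- build_network(corr, stats::quantile(abs(corr[upper.tri(corr)]), 0.95))
  nulls <- rewire_null(net, n_nulls = 20, seed = 64)
  expect_true(all(nulls$null_values[, "nodes"] == nulls$observed["nodes"]))
  expect_true(all(nulls$null_values[, "links"] == nulls$observed["links"]))
  expect_false(nulls$degenerate)
  # explicit degree-sequence check on one rewiring
  g <- as_igraph(net)
  set.seed(65)
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  expect_equal(sort(igraph::degree(gr)), sort(igraph::degree(g)))
  # handshake lemma
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
})

test_that("planted-modular graphs show positive clustering Z against nulls", {
  net <- two_clique_net()
  nulls <- suppressWarnings(rewire_null(net, n_nulls = 30, seed = 66))
  expect_gt(nulls$observed["avg_clustering"], 0.99)
  expect_gte(nulls$z["avg_clustering"], 0)
})

test_that("link signs tally by biosphere category and close to one", {
  ids <- c("a1", "a2", "r1", "r2", "r3")
  rho <- diag(5)
  dimnames(rho) <- list(ids, ids)
  rho["a1", "a2"] <- rho["a2", "a1"] <- 0.9   # AA +
  rho["r1", "r2"] <- rho["r2", "r1"] <- -0.9  # RR -
  rho["r1", "r3"] <- rho["r3", "r1"] <- 0.85  # RR +
  rho["a1", "r1"] <- rho["r1", "a1"] <- 0.95  # AR +
  labels <- make_labels(ids, c("abundant", "abundant", "rare", "rare", "rare"))
  net <- build_network(rho, 0.8, labels)
  s <- link_sign_summary(net)
  ov <- s[s$category == "overall", ]
  expect_equal(ov$n_links, 4)
  expect_equal(ov$prop_negative, 0.25)
  rr <- s[s$category == "RR", ]
  expect_equal(rr$n_negative, 1)
  expect_equal(rr$prop_positive + rr$prop_negative, 1)
  expect_equal(sum(s$n_links[s$category != "overall"]), ov$n_links)
  # unlabeled nodes are an error
  net_nolab <- build_network(rho, 0.8)
  expect_error(link_sign_summary(net_nolab), "label")
})

test_that("degree-by-category reproduces a star graph and quartile oracle", {
  ids <- c("hub", sprintf("leaf%d", 1:5))
  rho <- diag(6)
  dimnames(rho) <- list(ids, ids)
  for (l in ids[-1]) rho["hub", l] <- rho[l, "hub"] <- 0.9
  net <- build_network(rho, 0.8,
                       make_labels(ids, c("abundant", rep("rare", 5))))
  d <- degree_by_category(net)
  expect_equal(d$degrees$abundant, 5)
  expect_equal(d$degrees$rare, rep(1, 5))
  expect_equal(sum(unlist(d$degrees)), 2 * nrow(net$edges))
  q <- stats::quantile(d$degrees$rare, c(0, .25, .5, .75, 1), names = FALSE)
  expect_equal(unlist(d$summary[d$summary$label == "rare",
                                c("min", "q25", "median", "q75", "max")],
                      use.names = FALSE), q)
})
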