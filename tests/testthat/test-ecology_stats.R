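test_that("weighted MPD matches hand values and the brute-force double loop", {
  # two OTUs at patristic distance d: MPD = d regardless of abundances
  tr2 <- ape::read.tree(text = "(OTU01:0.7,OTU02:0.5);")
  tab2 <- make_table(c(90, 10), 2, 1)
  expect_equal(weighted_mpd(tab2, tr2, "s01"), 1.2)

  # star tree, 3 equal-abundance leaves, branch length 1 -> 2.0
  tab3 <- make_table(rep(10, 3), 3, 1)
  expect_equal(weighted_mpd(tab3, star_tree(3), "s01"), 2.0)

  # brute-force oracle on random coalescent trees <= 10 leaves
  set.seed(41)
  for (k in 1:10) {
    nl <- sample(4:10, 1)
    tree <- ape::rcoal(nl, tip.label = sprintf("OTU%02d", seq_len(nl)))
    tab <- random_table(nl, 2, lambda = 4)
    D <- ape::cophenetic.phylo(tree)
    for (sm in tab$sample_ids) {
      p <- tab$rel_abund[, sm]
      if (sum(p > 0) < 2) next
      expect_equal(weighted_mpd(tab, tree, sm), unname(oracle_wmpd(D, p)),
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted MPD agrees with picante's abundance-weighted mpd", {
  skip_if_not_installed("picante")
  set.seed(42)
  tree <- ape::rcoal(8, tip.label = sprintf("OTU%02d", 1:8))
  tab <- random_table(8, 3, lambda = 6)
  for (sm in tab$sample_ids) {
    ours <- weighted_mpd(tab, tree, sm)
    theirs <- picante::mpd(t(tab$rel_abund[, sm, drop = FALSE]),
                           ape::cophenetic.phylo(tree),
                           abundance.weighted = TRUE)
    # picante averages over ordered pairs including self-pairs (distance 0,
    # weight p_i^2); our distinct-pair convention rescales its denominator
    p <- tab$rel_abund[, sm]
    expect_equal(ours, unname(theirs) / (1 - sum(p^2)), tolerance = 1e-10)
  }
})

test_that("weighted MPD is NA with a warning below two detected OTUs", {
  tab <- otu_table(make_counts(c(5, 0, 0, 3), 2, 2))
  expect_warning(v <- weighted_mpd(tab, star_tree(2), "s01"), "MPD undefined")
  expect_true(is.na(v))
})

test_that("weighted UniFrac obeys its closed-form identities", {
  # identical communities -> 0
  tree <- star_tree(3)
  m <- make_counts(c(10, 20, 30, 10, 20, 30), 3, 2)
  tab <- otu_table(m)
  expect_equal(weighted_unifrac(tab, tree, "s01", "s02"), 0)

  # disjoint two-leaf communities with equal branch lengths -> 1
  tree2 <- star_tree(2)
  tabd <- otu_table(make_counts(c(10, 0, 0, 10), 2, 2))
  expect_equal(weighted_unifrac(tabd, tree2, "s01", "s02"), 1)

  # symmetric and bounded on random fixtures
  set.seed(43)
  for (k in 1:8) {
    nl <- sample(4:12, 1)
    tree <- ape::rcoal(nl, tip.label = sprintf("OTU%02d", seq_len(nl)))
    tab <- random_table(nl, 3, lambda = 5)
    u12 <- weighted_unifrac(tab, tree, "s01", "s02")
    expect_equal(u12, weighted_unifrac(tab, tree, "s02", "s01"))
    expect_gte(u12, 0)
    expect_lte(u12, 1)
  }
})

test_that("unifrac_matrix matches the pairwise function and is a metric tag", {
  set.seed(44)
  tree <- ape::rcoal(10, tip.label = sprintf("OTU%02d", 1:10))
  tab <- random_table(10, 4, lambda = 5)
  M <- unifrac_matrix(tab, tree)
  expect_equal(attr(M, "metric"), "weighted_unifrac")
  expect_equal(unname(diag(M)), rep(0, 4))
  expect_equal(M["s01", "s03"], weighted_unifrac(tab, tree, "s01", "s03"),
               tolerance = 1e-12)
  expect_equal(max(abs(M - t(M))), 0)
})

test_that("Pearson trait-env correlation matches the closed-form oracle", {
  env <- env_table(data.frame(sample_id = sprintf("s%02d", 1:15),
                              NH4 = c(1:14, NA),
                              TP = rnorm(15)))
  x <- stats::setNames(2 * c(1:14, 7) + 1, env$sample_id)
  r <- suppressMessages(pearson_trait_env(x, env, "NH4"))
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$n, 14)  # the NA pair is dropped

  y <- stats::setNames(-env$TP, env$sample_id)
  r2 <- pearson_trait_env(y, env, "TP")
  expect_equal(r2$r, -1, tolerance = 1e-12)

  set.seed(45)
  vals <- stats::setNames(rnorm(15), env$sample_id)
  r3 <- pearson_trait_env(vals, env, "TP")
  v <- env$TP
  oracle <- sum((vals - mean(vals)) * (v - mean(v))) /
    sqrt(sum((vals - mean(vals))^2) * sum((v - mean(v))^2))
  expect_equal(r3$r, oracle, tolerance = 1e-12)
  expect_error(pearson_trait_env(stats::setNames(rep(1, 15), env$sample_id),
                                 env, "TP"), "zero variance")
})

make_dist <- function(n, ids, seed) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
  dimnames(m) <- list(ids, ids)
  m
}

test_that("partial Mantel statistic agrees with vegan and permutes correctly", {
  n <- 15
  ids <- sprintf("s%02d", 1:n)
  A <- make_dist(n, ids, 1)
  B <- make_dist(n, ids, 2)
  C <- make_dist(n, ids, 3)
  res <- partial_mantel(A, B, C, permutations = 199, seed = 5)
  expect_true(abs(res$r) <= 1)
  expect_gte(res$p, 1 / 200)

  skip_if_not_installed("vegan")
  vr <- vegan::mantel.partial(stats::as.dist(A), stats::as.dist(B),
                              stats::as.dist(C), permutations = 19)
  expect_equal(res$r, unname(vr$statistic), tolerance = 1e-10)
})

test_that("identical matrices give the minimal one-sided p-value", {
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  A <- make_dist(n, ids, 6)
  C <- make_dist(n, ids, 7)
  res <- partial_mantel(A, A, C, permutations = 999, seed = 8)
  expect_equal(res$p, 1 / 1000)
})

test_that("joint relabeling of all three matrices leaves r unchanged", {
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  A <- make_dist(n, ids, 9); B <- make_dist(n, ids, 10)
  C <- make_dist(n, ids, 11)
  r1 <- partial_mantel(A, B, C, permutations = 99, seed = 1)$r
  set.seed(2)
  p <- sample.int(n)
  r2 <- partial_mantel(A[p, p], B[p, p], C[p, p], permutations = 99, seed = 1)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate control matrices error rather than return NaN", {
  n <- 10
  ids <- sprintf("s%02d", 1:n)
  A <- make_dist(n, ids, 12); B <- make_dist(n, ids, 13)
  C0 <- matrix(1, n, n); diag(C0) <- 0; dimnames(C0) <- list(ids, ids)
  expect_error(partial_mantel(A, B, C0, permutations = 99, seed = 1),
               "degenerate")
  expect_error(partial_mantel(A, B, make_dist(n, rev(ids), 14),
                              permutations = 99, seed = 1), "identical sample")
})

test_that("fixed seeds give bit-identical permutation p-values", {
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  A <- make_dist(n, ids, 15); B <- make_dist(n, ids, 16)
  C <- make_dist(n, ids, 17)
  r1 <- partial_mantel(A, B, C, permutations = 499, seed = 33)
  r2 <- partial_mantel(A, B, C, permutations = 499, seed = 33)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$r_perm, r2$r_perm)
})

test_that("env_distance drops incomplete samples pairwise-complete style", {
  env <- env_table(data.frame(sample_id = c("a", "b", "c"),
                              x = c(1, 2, NA), y = c(3, 1, 2)))
  D <- suppressMessages(env_distance(env, scale = FALSE))
  expect_equal(rownames(D), c("a", "b"))
  expect_equal(D["a", "b"], sqrt(1 + 4))
})
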