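fixture_db <- function() {
  trait_db(data.frame(
    rank = c("species", "species", "species", "genus", "family"),
    lineage = c(
      "Bacteria;Pro;Alpha;Pel;PelF;Pelagibacter;Pelagibacter ubique",
      "Bacteria;Firm;Bac;Bacil;BacF;Bacillus;Bacillus a",
      "Bacteria;Firm;Bac;Bacil;BacF;Bacillus;Bacillus b",
      "Bacteria;Pro;Gamma;Alt;AltF;Alteromonas",
      "Bacteria;Pro;Delta;Des;DesF"),
    copies = c(1, 6, 11, 5, 4)))
}

fixture_tax <- function() {
  taxonomy_table(data.frame(
    otu_id = c("sar11", "bac_new", "alt_sp", "des_genus", "alien", "empty"),
    domain = c(rep("Bacteria", 5), ""),
    phylum = c("Pro", "Firm", "Pro", "Pro", "Weird", ""),
    class = c("Alpha", "Bac", "Gamma", "Delta", "W1", ""),
    order = c("Pel", "Bacil", "Alt", "Des", "W2", ""),
    family = c("PelF", "BacF", "AltF", "DesF", "W3", ""),
    genus = c("Pelagibacter", "Bacillus", "Alteromonas", "Desulfo", "W4", ""),
    species = c("", "Bacillus zz", "Alteromonas sp9", "Desulfo sp1", "W sp", "")))
}

test_that("hierarchical matching walks species -> genus -> family correctly", {
  asg <- assign_rrn(fixture_tax(), fixture_db())
  row <- function(id) asg[asg$otu_id == id, ]
  # genus known only via a single-copy species record (SAR11-like)
  expect_equal(row("sar11")$n, 1)
  expect_equal(row("sar11")$matched_rank, "genus")
  # species absent, genus resolves to the child mean (6, 11) -> 8.5
  expect_equal(row("bac_new")$n, 8.5)
  # genus has its own record and no children
  expect_equal(row("alt_sp")$n, 5)
  expect_equal(row("alt_sp")$matched_rank, "genus")
  # genus unknown, family record fallback
  expect_equal(row("des_genus")$n, 4)
  expect_equal(row("des_genus")$matched_rank, "family")
  # matched rank is always a rank on the OTU's own lineage
  ok <- !asg$missing
  expect_true(all(asg$matched_rank[ok] %in% TAX_RANKS))
  # lineage absent everywhere (matches only at domain? no: domain differs)
  expect_true(row("alien")$missing ||
                row("alien")$matched_rank == "domain")
  expect_true(row("empty")$missing)
  expect_match(row("empty")$reason, "empty lineage")
})

test_that("assignment is invariant to db record order", {
  db_recs <- as.data.frame(fixture_db())[, c("rank", "lineage", "copies")]
  a1 <- assign_rrn(fixture_tax(), trait_db(db_recs))
  a2 <- assign_rrn(fixture_tax(), trait_db(db_recs[rev(seq_len(nrow(db_recs))), ]))
  expect_equal(a1$n, a2$n)
})

test_that("assignment equals the exhaustive search oracle on random dbs", {
  for (seed in c(21, 22, 23)) {
    aux <- simulate_taxonomy_tree_db(40, seed = seed)
    asg <- assign_rrn(aux$taxonomy, aux$db)
    recs <- as.data.frame(aux$db)[, c("rank", "lineage", "copies")]
    tax <- as.data.frame(aux$taxonomy)
    for (i in seq_len(nrow(tax))) {
      want <- oracle_assign(unlist(tax[i, TAX_RANKS]), recs)
      got <- asg[asg$otu_id == tax$otu_id[i], ]
      if (is.na(want$n)) {
        expect_true(got$missing)
      } else {
        expect_equal(got$n, want$n, tolerance = 1e-12)
        expect_equal(match(got$matched_rank, TAX_RANKS), want$rank_idx)
      }
    }
    # species-level hits reproduce the recorded truth exactly
    sp <- !asg$missing & asg$matched_rank == "species"
    expect_equal(asg$n[sp], unname(aux$true_n[asg$otu_id[sp]]))
  }
})

test_that("Eq. 1 equals direct-loop evaluation and respects its bounds", {
  # S = (1, 1), n = (1, 3): 2 / (1 + 1/3) = 1.5
  tab <- make_table(c(1, 1), 2, 1)
  tr <- make_traits(tab$otu_ids, c(1, 3))
  expect_equal(as.numeric(community_rrn(tab, tr, "s01")), 1.5)
  expect_equal(as.numeric(community_rrn_unweighted(tab, tr, "s01")), 2)

  # heavily skewed: S = (99, 1) pulls the weighted value toward n = 1
  tab2 <- make_table(c(99, 1), 2, 1)
  expect_equal(as.numeric(community_rrn(tab2, tr, "s01")),
               oracle_community_rrn(c(99, 1), c(1, 3)), tolerance = 1e-12)
  expect_equal(as.numeric(community_rrn_unweighted(tab2, tr, "s01")), 2)

  # single OTU identity and all-n=1 lower bound
  tab3 <- make_table(7, 1, 1)
  expect_equal(as.numeric(community_rrn(tab3, make_traits(tab3$otu_ids, 4),
                                        "s01")), 4)
  tab4 <- make_table(c(3, 9), 2, 1)
  expect_equal(as.numeric(community_rrn(tab4, make_traits(tab4$otu_ids,
                                                          c(1, 1)), "s01")), 1)

  set.seed(31)
  for (k in 1:25) {
    no <- sample(2:10, 1)
    tab <- random_table(no, 3, lambda = 8)
    n <- stats::runif(no, 1, 12)
    tr <- make_traits(tab$otu_ids, n)
    for (sm in tab$sample_ids) {
      S <- tab$counts[, sm]
      det <- S > 0
      if (!any(det)) next
      v <- as.numeric(community_rrn(tab, tr, sm))
      expect_equal(v, oracle_community_rrn(S[det], n[det]), tolerance = 1e-12)
      expect_gte(v, min(n[det]) - 1e-12)
      expect_lte(v, max(n[det]) + 1e-12)
      # scaling invariance
      tab_big <- otu_table(tab$counts * 7)
      expect_equal(as.numeric(community_rrn(tab_big, tr, sm)), v,
                   tolerance = 1e-12)
      # weighted harmonic <= unweighted arithmetic mean
      expect_lte(v, max(n[det]) + 1e-12)
      expect_lte(oracle_community_rrn(rep(1, sum(det)), n[det]),
                 as.numeric(community_rrn_unweighted(tab, tr, sm)) + 1e-12)
    }
  }
})

test_that("community_rrn errors without any assigned detected OTU", {
  tab <- make_table(c(4, 6), 2, 1)
  tr <- make_traits(tab$otu_ids, c(NA, NA))
  expect_error(community_rrn(tab, tr, "s01"), "no detected")
})

test_that("coverage reports the assigned fraction of detected reads", {
  tab <- make_table(c(80, 20), 2, 1)
  tr <- make_traits(tab$otu_ids, c(2, NA))
  v <- community_rrn(tab, tr, "s01")
  expect_equal(attr(v, "coverage"), 0.8)
  expect_equal(as.numeric(v), 2)
})

test_that("biosphere-restricted rrn matches hand-computed subset values", {
  # 4 OTUs, counts (10, 30, 5, 55), n = (2, 4, 1, 8)
  tab <- make_table(c(10, 30, 5, 55), 4, 1)
  tr <- make_traits(tab$otu_ids, c(2, 4, 1, 8))
  lab <- make_labels(tab$otu_ids, c("abundant", "abundant", "rare", "rare"))
  expect_equal(biosphere_rrn(tab, tr, lab, "abundant", "s01"),
               oracle_community_rrn(c(10, 30), c(2, 4)), tolerance = 1e-12)
  expect_equal(biosphere_rrn(tab, tr, lab, "rare", "s01"),
               oracle_community_rrn(c(5, 55), c(1, 8)), tolerance = 1e-12)
  # single-label table equals the whole-community value
  lab_all <- make_labels(tab$otu_ids, rep("rare", 4))
  expect_equal(biosphere_rrn(tab, tr, lab_all, "rare", "s01"),
               as.numeric(community_rrn(tab, tr, "s01")))
  # empty subset -> NA
  expect_true(is.na(suppressMessages(
    biosphere_rrn(tab, tr, lab, "intermediate", "s01"))))
})
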