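# Synthetic communities with planted ground truth. The generator emulates the
# statistical structure the analysis assumes: a lognormal species-abundance
# distribution with a long rare tail, per-OTU rrn traits conserved within
# genera, nutrient gradients coupled to the community-level trait, and signed
# inter-OTU associations imposed through a Gaussian copula on log expected
# abundances before multinomial read sampling.

softmax_cols <- function(logw) {
  w <- exp(sweep(logw, 2, apply(logw, 2, max)))
  sweep(w, 2, colSums(w), `/`)
}

draw_counts <- function(expected, depth) {
  cnt <- vapply(seq_len(ncol(expected)),
                function(j) stats::rmultinom(1, depth, expected[, j])[, 1],
                numeric(nrow(expected)))
  dimnames(cnt) <- dimnames(expected)
  cnt
}

# planted biosphere design: OTUs whose expected relative abundance is at
# least 2x the abundant cutoff in every sample (constructed-abundant) or
# below half the cutoff in every sample (constructed-rare)
planted_biospheres <- function(expected, a = 0.001) {
  lo <- apply(expected, 1, min)
  hi <- apply(expected, 1, max)
  list(abundant = rownames(expected)[lo >= 2 * a],
       rare = rownames(expected)[hi < a / 2])
}

rebuild_sim <- function(truth) {
  logw <- truth$base + truth$sample_sigma * truth$noise
  if (!is.null(truth$assoc_noise)) {
    ids <- rownames(truth$assoc_noise)
    logw[ids, ] <- truth$base[ids] + truth$sample_sigma * truth$assoc_noise
  }
  if (!is.null(truth$tilt)) logw <- logw + truth$tilt
  expected <- softmax_cols(logw)
  dimnames(expected) <- list(names(truth$base), truth$sample_ids)
  expected
}

#' Simulate an OTU count table with a lognormal abundance distribution
#'
#' Per-OTU log baseline abundances are drawn from Normal(`sad_mu`,
#' `sad_sigma`) (a lognormal species-abundance distribution after
#' exponentiation), perturbed per sample by independent Normal(0,
#' `sample_sigma`) noise, closed to expected proportions, and sampled as one
#' multinomial of `depth` reads per sample. The returned truth records all
#' planted parameters; regeneration from the same arguments is bit-identical.
#'
#' @param n_otus number of OTUs (>= 10)
#' @param n_samples number of samples
#' @param sad_mu,sad_sigma lognormal SAD parameters (defaults 0 and 2)
#' @param depth reads per sample (>= 1000; default 50000)
#' @param sample_sigma sd of per-sample log-abundance noise (default 0.6)
#' @param seed integer RNG seed (required)
#' @return object of class `sim_community`: list with `table` (an
#'   [otu_table]) and `truth` (class `synthetic_truth`) carrying the seed,
#'   SAD parameters, expected proportions and the planted biosphere design
#' @export
simulate_community <- function(n_otus, n_samples, sad_mu = 0, sad_sigma = 2,
                               depth = 50000, sample_sigma = 0.6, seed) {
  if (missing(seed)) abort_input("`seed` is required")
  if (n_otus < 10) abort_input("n_otus must be >= 10")
  if (depth < 1000) abort_input("depth must be >= 1000")
  if (!is.finite(sad_sigma) || sad_sigma < 0)
    abort_input("invalid SAD parameters")
  set.seed(seed)
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  base <- stats::setNames(stats::rnorm(n_otus, sad_mu, sad_sigma), otu_ids)
  noise <- matrix(stats::rnorm(n_otus * n_samples), n_otus, n_samples,
                  dimnames = list(otu_ids, sample_ids))
  truth <- structure(
    list(seed = seed, sad_mu = sad_mu, sad_sigma = sad_sigma, depth = depth,
         sample_sigma = sample_sigma, base = base, noise = noise,
         sample_ids = sample_ids, assoc_noise = NULL, tilt = NULL,
         links = NULL, coupling = NA_real_, gradient = NULL, true_n = NULL),
    class = "synthetic_truth")
  expected <- rebuild_sim(truth)
  truth$expected <- expected
  truth$planted <- planted_biospheres(expected)
  counts <- draw_counts(expected, depth)
  structure(list(table = otu_table(counts), truth = truth),
            class = "sim_community")
}

#' Plant signed pairwise associations into a simulated community
#'
#' Replaces the idiosyncratic per-sample noise of the OTUs involved in
#' `planted_links` with draws from a multivariate normal whose correlation
#' matrix carries the planted signed latent correlations (a Gaussian copula
#' on log expected abundances), then re-draws the counts. The planted matrix
#' must be positive definite; otherwise an error is raised.
#'
#' @param sim a `sim_community`
#' @param planted_links data.frame with columns `otu_a`, `otu_b`, `rho`
#'   (latent correlation, |rho| in (0, 1])
#' @param seed integer RNG seed (required)
#' @return the modified `sim_community`; `truth$links` records the planted
#'   list
#' @export
simulate_associations <- function(sim, planted_links, seed) {
  stopifnot(inherits(sim, "sim_community"))
  if (missing(seed)) abort_input("`seed` is required")
  pl <- planted_links
  need <- c("otu_a", "otu_b", "rho")
  if (!all(need %in% names(pl)))
    abort_input("planted_links needs columns otu_a, otu_b, rho")
  truth <- sim$truth
  if (nrow(pl) == 0) {
    truth$links <- pl
    sim$truth <- truth
    return(sim)
  }
  if (any(abs(pl$rho) <= 0 | abs(pl$rho) > 1))
    abort_input("planted |rho| must lie in (0, 1]")
  ids <- unique(c(pl$otu_a, pl$otu_b))
  unknown <- setdiff(ids, names(truth$base))
  if (length(unknown)) abort_input("unknown OTU in planted_links: ",
                                   paste(unknown, collapse = ", "))
  k <- length(ids)
  Sigma <- diag(k)
  dimnames(Sigma) <- list(ids, ids)
  for (r in seq_len(nrow(pl)))
    Sigma[pl$otu_a[r], pl$otu_b[r]] <- Sigma[pl$otu_b[r], pl$otu_a[r]] <-
      pl$rho[r]
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    abort_input("planted correlation matrix is not positive definite ",
                "(smallest eigenvalue ", format(min(ev)), ")")
  set.seed(seed)
  n_s <- length(truth$sample_ids)
  Z <- matrix(stats::rnorm(n_s * k), n_s, k) %*% chol(Sigma)
  truth$assoc_noise <- t(Z)
  rownames(truth$assoc_noise) <- ids
  colnames(truth$assoc_noise) <- truth$sample_ids
  truth$links <- pl
  expected <- rebuild_sim(truth)
  truth$expected <- expected
  truth$planted <- planted_biospheres(expected)
  counts <- draw_counts(expected, truth$depth)
  sim$table <- otu_table(counts)
  sim$truth <- truth
  sim
}

#' Pick random planted link pairs among moderately abundant OTUs
#'
#' Helper for presets and validation runs: samples disjoint OTU pairs from
#' the abundance ranks 11..`pool_max` (skipping the dominant head so no pair
#' overwhelms the composition, while staying abundant enough to survive the
#' occurrence filter), with latent |rho| uniform in `rho_range` and a fixed
#' fraction of negative signs.
#'
#' @param sim a `sim_community`
#' @param n_links number of pairs
#' @param rho_range magnitude range of the latent correlation
#' @param neg_frac fraction of links planted negative
#' @param seed integer RNG seed
#' @param pool_max largest abundance rank eligible (default 10 + 6*n_links)
#' @return data.frame (otu_a, otu_b, rho) suitable for
#'   [simulate_associations]
#' @export
plant_random_links <- function(sim, n_links, rho_range = c(0.8, 0.95),
                               neg_frac = 0, seed,
                               pool_max = 10 + 6 * n_links) {
  stopifnot(inherits(sim, "sim_community"))
  if (missing(seed)) abort_input("`seed` is required")
  set.seed(seed)
  ord <- order(sim$truth$base, decreasing = TRUE)
  pool <- names(sim$truth$base)[ord[11:min(pool_max, length(ord))]]
  if (length(pool) < 2 * n_links)
    abort_input("not enough OTUs in the eligible abundance pool")
  picked <- sample(pool, 2 * n_links)
  n_neg <- round(neg_frac * n_links)
  sgn <- c(rep(-1, n_neg), rep(1, n_links - n_neg))
  data.frame(otu_a = picked[seq_len(n_links)],
             otu_b = picked[n_links + seq_len(n_links)],
             rho = sgn * stats::runif(n_links, rho_range[1], rho_range[2]),
             stringsAsFactors = FALSE)
}

#' Couple a nutrient gradient to the community-level trait
#'
#' Draws a latent nutrient gradient per sample and tilts the log expected
#' abundance of high-copy-number OTUs up-gradient, so that the realized
#' Pearson correlation between the community-level rrn copy number and the
#' first nutrient approaches the planted `coupling` as depth and sample count
#' grow. The first nutrient (NH4-N) is a linear transform of the gradient
#' itself; the remaining covariates are noisy correlates, including a
#' strongly correlated NH4-N/TN pair so a control matrix has structure to
#' work against. Counts are re-drawn from the tilted expectations.
#'
#' @param sim a `sim_community`
#' @param true_traits named per-OTU rrn copy numbers (>= 2 distinct values)
#' @param coupling planted trait-nutrient correlation, |coupling| <= 1
#' @param n_nutrients number of covariate columns (default 4)
#' @param seed integer RNG seed (required)
#' @param tau tilt strength on the log scale per unit gradient (default 0.1)
#' @return the modified `sim_community` with an `env` element (an
#'   `env_table`); `truth$coupling`, `truth$gradient` and `truth$true_n`
#'   record the planted values
#' @export
simulate_trait_env_coupling <- function(sim, true_traits, coupling,
                                        n_nutrients = 4, seed, tau = 0.1) {
  stopifnot(inherits(sim, "sim_community"))
  if (missing(seed)) abort_input("`seed` is required")
  if (abs(coupling) > 1) abort_input("|coupling| must be <= 1")
  truth <- sim$truth
  tt <- true_traits[names(truth$base)]
  if (anyNA(tt)) abort_input("true_traits must cover every OTU")
  if (length(unique(tt)) < 2)
    abort_input("coupling is unidentifiable with < 2 distinct trait values")
  set.seed(seed)
  n_s <- length(truth$sample_ids)
  x <- stats::rnorm(n_s)                      # latent nutrient gradient
  u <- stats::rnorm(n_s)                      # trait variation off-gradient
  eta <- coupling * x + sqrt(1 - coupling^2) * u
  tstd <- as.numeric(scale(tt))
  truth$tilt <- tau * outer(tstd, eta)
  dimnames(truth$tilt) <- list(names(truth$base), truth$sample_ids)
  truth$coupling <- coupling
  truth$gradient <- stats::setNames(x, truth$sample_ids)
  truth$true_n <- tt
  expected <- rebuild_sim(truth)
  truth$expected <- expected
  truth$planted <- planted_biospheres(expected)
  counts <- draw_counts(expected, truth$depth)
  sim$table <- otu_table(counts)
  sim$truth <- truth
  nut_names <- c("NH4_N_mgL", "TN_mgL", "TP_mgL", "NO3_N_mgL")
  if (n_nutrients > length(nut_names))
    nut_names <- c(nut_names, sprintf("nutrient_%02d",
                                      seq_len(n_nutrients - length(nut_names))))
  env <- data.frame(sample_id = truth$sample_ids, stringsAsFactors = FALSE)
  env[[nut_names[1]]] <- 5 + 2 * x
  if (n_nutrients >= 2)                       # TN tracks NH4-N closely
    env[[nut_names[2]]] <- 8 + 3 * (0.95 * x + sqrt(1 - 0.95^2) * stats::rnorm(n_s))
  if (n_nutrients >= 3)
    env[[nut_names[3]]] <- 0.6 + 0.2 * (0.8 * x + 0.6 * stats::rnorm(n_s))
  if (n_nutrients >= 4)
    for (j in 4:n_nutrients)
      env[[nut_names[j]]] <- 1 + 0.5 * (0.7 * x + sqrt(1 - 0.7^2) * stats::rnorm(n_s))
  sim$env <- env_table(env)
  sim
}

#' Simulate a taxonomy, tree and rrnDB-style trait database with known truth
#'
#' Builds a random seven-rank taxonomy over `n_otus` OTUs, a coalescent tree
#' with OTU tips, genus-conserved true rrn copy numbers, and a trait database
#' populated at mixed ranks so that hierarchical assignment must exercise the
#' species-hit, sibling child-mean, genus-record, family-fallback and
#' no-match paths. The per-genus path class and the true per-OTU copy number
#' are recorded.
#'
#' @param n_otus number of OTUs
#' @param seed integer RNG seed (required)
#' @return list with `taxonomy` (a `taxonomy_table`), `tree` (`phylo`),
#'   `db` (a `trait_db`), `true_n` (named per-OTU copy number),
#'   `path_class` (named per-OTU db-path class)
#' @export
simulate_taxonomy_tree_db <- function(n_otus, seed) {
  if (missing(seed)) abort_input("`seed` is required")
  set.seed(seed)
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  n_gen <- max(4L, round(n_otus / 3))
  n_fam <- max(3L, round(n_gen / 3))
  n_ord <- max(2L, round(n_fam / 2))
  n_cls <- max(2L, round(n_ord / 2))
  n_phy <- max(2L, round(n_cls / 2))
  gen_fam <- sample.int(n_fam, n_gen, replace = TRUE)
  fam_ord <- sample.int(n_ord, n_fam, replace = TRUE)
  ord_cls <- sample.int(n_cls, n_ord, replace = TRUE)
  cls_phy <- sample.int(n_phy, n_cls, replace = TRUE)
  gname <- sprintf("Genus%03d", seq_len(n_gen))
  fname <- sprintf("Family%03d", seq_len(n_fam))
  oname <- sprintf("Order%02d", seq_len(n_ord))
  cname <- sprintf("Class%02d", seq_len(n_cls))
  pname <- sprintf("Phylum%02d", seq_len(n_phy))
  otu_gen <- sample.int(n_gen, n_otus, replace = TRUE)
  # genus-conserved base trait; species jitter in whole copies, floor 1
  gen_n <- pmax(1, round(exp(stats::rnorm(n_gen, log(3), 0.6))))
  sp_jit <- sample(c(-1, 0, 0, 1), n_otus, replace = TRUE)
  true_n <- pmax(1, gen_n[otu_gen] + sp_jit)
  names(true_n) <- otu_ids
  sp_name <- paste0(gname[otu_gen], "_sp", seq_len(n_otus))
  # db path class per genus
  classes <- c("species", "sibling", "genus_record", "family_record", "alien")
  gen_class <- sample(classes, n_gen, replace = TRUE,
                      prob = c(0.40, 0.15, 0.20, 0.15, 0.10))
  lineage_of <- function(g) {
    f <- gen_fam[g]; o <- fam_ord[f]; cl <- ord_cls[o]; ph <- cls_phy[cl]
    c("Bacteria", pname[ph], cname[cl], oname[o], fname[f], gname[g])
  }
  tax <- data.frame(otu_id = otu_ids, stringsAsFactors = FALSE)
  linm <- t(vapply(otu_gen, lineage_of, character(6)))
  tax$domain <- linm[, 1]; tax$phylum <- linm[, 2]; tax$class <- linm[, 3]
  tax$order <- linm[, 4]; tax$family <- linm[, 5]; tax$genus <- linm[, 6]
  tax$species <- sp_name
  # alien genera live in a lineage the db never sees
  alien <- gen_class[otu_gen] == "alien"
  tax$domain[alien] <- "DomainAlien"
  tax$phylum[alien] <- "PhylumAlien"
  tax$class[alien] <- "ClassAlien"
  tax$order[alien] <- "OrderAlien"
  tax$family[alien] <- "FamilyAlien"
  tax$genus[alien] <- paste0(tax$genus[alien], "x")
  recs <- list()
  add_rec <- function(rank, lineage_vec, copies)
    recs[[length(recs) + 1L]] <<- data.frame(
      rank = rank, lineage = paste(lineage_vec, collapse = ";"),
      copies = copies, stringsAsFactors = FALSE)
  path_class <- stats::setNames(gen_class[otu_gen], otu_ids)
  fam_has_record <- logical(n_fam)
  for (g in seq_len(n_gen)) {
    members <- which(otu_gen == g)
    if (length(members) == 0) next
    lv <- lineage_of(g)
    cls <- gen_class[g]
    if (cls == "species") {
      for (i in members)
        add_rec("species", c(lv, sp_name[i]), true_n[i])
    } else if (cls == "sibling") {
      # record some members' species; the rest must resolve via the genus
      # child mean of their recorded siblings
      rec <- members[seq_len(max(1L, length(members) - 1L))]
      for (i in rec) add_rec("species", c(lv, sp_name[i]), true_n[i])
      path_class[otu_ids[rec]] <- "species"
    } else if (cls == "genus_record") {
      add_rec("genus", lv, gen_n[g])
    } else if (cls == "family_record") {
      f <- gen_fam[g]
      if (!fam_has_record[f]) {
        add_rec("family", lineage_of(g)[1:5], max(1, round(mean(gen_n[gen_fam == f]))))
        fam_has_record[f] <- TRUE
      }
    } # alien: no records anywhere on its (rewritten) lineage
  }
  db <- trait_db(do.call(rbind, recs))
  tree <- validate_phylo(ape::rcoal(n_otus, tip.label = otu_ids))
  list(taxonomy = taxonomy_table(tax), tree = tree, db = db,
       true_n = true_n, path_class = path_class)
}

#' Simulate a full synthetic dataset under a named preset
#'
#' `"sediment"` emulates a nutrient-rich community: strong trait-nutrient
#' coupling (0.7) and many planted links with a substantial negative
#' fraction. `"ocean"` emulates the nutrient-scarce pelagic community: weak
#' coupling (0.2), fewer planted links, none negative. Both share the
#' lognormal SAD and read depth; every stage seed is derived from the master
#' `seed` by fixed small offsets.
#'
#' @param preset `"sediment"` or `"ocean"`
#' @param n_otus,n_samples community size (defaults 1500 and 60)
#' @param depth reads per sample (default 50000)
#' @param seed master integer seed (required)
#' @return list of class `sim_dataset`: `table`, `env`, `taxonomy`, `tree`,
#'   `db`, `truth`
#' @export
simulate_preset <- function(preset = c("sediment", "ocean"), n_otus = 1500,
                            n_samples = 60, depth = 50000, seed) {
  preset <- match.arg(preset)
  if (missing(seed)) abort_input("`seed` is required")
  cfg <- switch(preset,
    sediment = list(coupling = 0.7, n_links = 30, neg_frac = 0.4),
    ocean    = list(coupling = 0.2, n_links = 15, neg_frac = 0))
  aux <- simulate_taxonomy_tree_db(n_otus, seed = seed + 1L)
  sim <- simulate_community(n_otus, n_samples, depth = depth, seed = seed + 2L)
  links <- plant_random_links(sim, cfg$n_links, neg_frac = cfg$neg_frac,
                              seed = seed + 3L)
  sim <- simulate_associations(sim, links, seed = seed + 4L)
  sim <- simulate_trait_env_coupling(sim, aux$true_n, cfg$coupling,
                                     seed = seed + 5L)
  structure(list(table = sim$table, env = sim$env, taxonomy = aux$taxonomy,
                 tree = aux$tree, db = aux$db, truth = sim$truth,
                 preset = preset, path_class = aux$path_class),
            class = "sim_dataset")
}
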