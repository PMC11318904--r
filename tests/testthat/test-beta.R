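test_that("phylosor decomposition matches edge-set enumeration on the 4-tip tree", {
  tr <- toy_tree()
  p <- phylosor_pair(c("A", "B"), c("A", "C"), tr)
  expect_equal(p$a, 2)
  expect_equal(p$b, 1)
  expect_equal(p$c, 2)
  expect_equal(p$beta_sor, 3 / 7, tolerance = 1e-12)
  expect_equal(p$beta_sim, 1 / 3, tolerance = 1e-12)
  expect_equal(p$beta_sne, 2 / 21, tolerance = 1e-12)
  expect_equal(p$phylosor, 4 / 7, tolerance = 1e-12)

  ident <- phylosor_pair(c("A", "B"), c("A", "B"), tr)
  expect_equal(ident$beta_sor, 0)
  expect_equal(ident$phylosor, 1)

  # symmetric unique branch lengths (b == c) mean pure turnover
  symm <- phylosor_pair(c("A", "C"), c("B", "D"), tr)
  expect_equal(symm$b, symm$c)
  expect_equal(symm$beta_sne, 0, tolerance = 1e-12)
})

test_that("phylosor components satisfy a + b = PD1 and a + c = PD2", {
  tr <- random_tree(25, 13)
  for (seed in 1:5) {
    taxa <- withr::with_seed(seed, list(
      sample(tr$tip.label, 6), sample(tr$tip.label, 9)))
    p <- phylosor_pair(taxa[[1]], taxa[[2]], tr)
    expect_equal(p$a + p$b, faith_pd(tr, taxa[[1]]), tolerance = 1e-10)
    expect_equal(p$a + p$c, faith_pd(tr, taxa[[2]]), tolerance = 1e-10)
  }
})

test_that("species sorensen handles shared, disjoint and nested sets", {
  p <- sorensen_pair(c("A", "B"), c("A", "C"))
  expect_equal(p$beta_sor, 0.5)
  expect_equal(p$beta_sim, 0.5)
  expect_equal(p$beta_sne, 0)

  disj <- sorensen_pair(c("A", "B"), c("C", "D"))
  expect_equal(disj$beta_sor, 1)

  nest <- sorensen_pair(c("A", "B", "C"), c("A", "B"))
  expect_equal(nest$beta_sim, 0)
  expect_equal(nest$beta_sne, 1 / 5, tolerance = 1e-12)
})

test_that("phylogenetic beta on a unit star tree degenerates to species beta", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  sets <- list(c("A", "B", "C"), c("B", "C", "D", "E"))
  ph <- phylosor_pair(sets[[1]], sets[[2]], star)
  sp <- sorensen_pair(sets[[1]], sets[[2]])
  expect_equal(ph$beta_sor, sp$beta_sor, tolerance = 1e-12)
  expect_equal(ph$beta_sim, sp$beta_sim, tolerance = 1e-12)
})

test_that("beta_matrices are symmetric, zero-diagonal and additive", {
  tr <- random_tree(30, 17)
  comm <- sim_communities(tr, richness = rep(8, 8), mode = "random", seed = 2)
  bm <- beta_matrices(comm, tr)
  for (nm in names(bm)) {
    expect_true(isSymmetric(bm[[nm]]))
    expect_equal(unname(diag(bm[[nm]])), rep(0, 8))
  }
  expect_equal(bm$phylo_sor, bm$phylo_sim + bm$phylo_sne, tolerance = 1e-12)
  expect_equal(bm$species_sor, bm$species_sim + bm$species_sne, tolerance = 1e-12)
})

test_that("nested gradients put the signal in nestedness, turnover gradients in turnover", {
  tr <- random_tree(80, 19)
  nested <- sim_communities(tr, mode = "nested-attrition",
    richness = c(60, 45, 35, 25, 18, 12, 8, 5), seed = 3)
  bn <- beta_pairs(nested)
  sp <- bn[bn$variant == "species", ]
  adj <- sp[match(paste0(nested$site[-8], nested$site[-1]),
                  paste0(sp$site1, sp$site2)), ]
  expect_true(all(adj$beta_sim == 0))
  expect_true(all(adj$beta_sne > 0))

  turn <- sim_communities(tr, mode = "range-turnover", seed = 3)
  bt <- beta_pairs(turn, tr)
  pt <- bt[bt$variant == "phylogenetic", ]
  adj_t <- pt[match(paste0(turn$site[-8], turn$site[-1]),
                    paste0(pt$site1, pt$site2)), ]
  expect_gt(mean(adj_t$beta_sim), mean(adj_t$beta_sne))
})

test_that("comdist matches hand computation, its oracle, and is symmetric", {
  tr <- toy_tree()
  d <- cophenetic_distances(tr)
  expect_equal(comdist_pair(c("A", "B"), c("C", "D"), d), 4)
  expect_equal(comdist_pair("A", "A", d), 0)

  tr2 <- random_tree(20, 23)
  d2 <- cophenetic_distances(tr2)
  for (seed in 1:5) {
    sets <- withr::with_seed(seed, list(
      sample(tr2$tip.label, 5), sample(tr2$tip.label, 7)))
    expect_equal(comdist_pair(sets[[1]], sets[[2]], d2),
      comdist_brute(sets[[1]], sets[[2]], d2), tolerance = 1e-12)
    expect_equal(comdist_pair(sets[[1]], sets[[2]], d2),
      comdist_pair(sets[[2]], sets[[1]], d2), tolerance = 1e-12)
  }
})

test_that("comdist_matrix agrees with the reference implementation", {
  skip_if_not_installed("picante")
  tr <- random_tree(25, 29)
  comm <- sim_communities(tr, richness = rep(6, 8), mode = "random", seed = 5)
  cd <- comdist_matrix(comm, tr)
  ref <- as.matrix(picante::comdist(community_matrix(comm),
    ape::cophenetic.phylo(tr), abundance.weighted = FALSE))
  off <- row(cd) != col(cd)
  expect_equal(cd[rownames(ref), colnames(ref)][off], ref[off], tolerance = 1e-10)
})

test_that("clustering recovers forced topologies and matches the textbook oracle", {
  d <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
    dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  hc <- cluster_communities(d)
  expect_equal(hc$height[1], 1) # raw merge distance convention
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "\\((s1:[^,]*,s2:|s2:[^,]*,s1:)")

  for (seed in 1:5) {
    dm <- withr::with_seed(seed, random_distance_matrix(6))
    for (linkage in c("average", "complete", "single")) {
      hc <- cluster_communities(dm, linkage)
      expect_equal(hc$height, agglom_brute(dm, linkage), tolerance = 1e-10)
    }
  }
})

test_that("clustering rejects asymmetric input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(cluster_communities(m), class = "phylograd_validation_error")
})
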