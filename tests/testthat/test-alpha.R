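test_that("mpd and mntd match hand arithmetic on the 4-tip tree", {
  d <- cophenetic_distances(toy_tree())
  expect_equal(mpd_community(c("A", "B", "C"), d), (2 + 4 + 4) / 3)
  expect_equal(mntd_community(c("A", "B", "C"), d), (2 + 2 + 4) / 3)
  expect_equal(mpd_community(c("A", "B"), d), 2)
  expect_equal(mntd_community(c("A", "B"), d), mpd_community(c("A", "B"), d))
  expect_warning(out <- mpd_community("A", d), "fewer than 2")
  expect_true(is.na(out))
})

test_that("mpd and mntd equal their brute-force oracles on random instances", {
  for (seed in 1:8) {
    tr <- random_tree(sample(6:12, 1), seed)
    d <- cophenetic_distances(tr)
    taxa <- sample(tr$tip.label, sample(3:5, 1))
    expect_equal(mpd_community(taxa, d), mpd_brute(taxa, d), tolerance = 1e-12)
    expect_equal(mntd_community(taxa, d), mntd_brute(taxa, d), tolerance = 1e-12)
  }
})

test_that("observed per-site metrics agree with the reference implementation", {
  skip_if_not_installed("picante")
  tr <- random_tree(30, 21)
  comm <- sim_communities(tr, elevations = seq(200, 3700, 500),
    richness = rep(8, 8), mode = "random", seed = 4)
  X <- community_matrix(comm)
  ses <- ses_indices(comm, tr, n_iter = 5, seed = 1)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(ses$mpd, unname(picante::mpd(X, d)), tolerance = 1e-10)
  expect_equal(ses$mntd, unname(picante::mntd(X, d)), tolerance = 1e-10)
  expect_equal(ses$pd, picante::pd(X, tr, include.root = TRUE)$PD, tolerance = 1e-10)
})

test_that("label shuffling leaves a full-pool community invariant", {
  tr <- toy_tree()
  comm <- tibble::tibble(site = "all", A = 1, B = 1, C = 1, D = 1)
  ens <- shuffle_null(comm, tr, "mpd", n_iter = 25, seed = 3)
  expect_equal(ens$null_mean, ens$observed, tolerance = 1e-12)
  expect_equal(ens$null_sd, 0)
})

test_that("exhaustive null on the 4-tip pair reproduces the enumerated ensemble", {
  tr <- toy_tree()
  comm <- tibble::tibble(site = "s1", A = 1, B = 1)
  ens <- shuffle_null(comm, tr, "mpd", mode = "exhaustive", keep_values = TRUE)
  # all C(4,2)=6 pair identities: distances {2,4,4,4,4,2}
  expect_equal(sort(ens$values[[1]]), c(2, 2, 4, 4, 4, 4))
  expect_equal(ens$null_mean, 10 / 3, tolerance = 1e-12)
  expect_equal(ens$null_sd, sd(c(2, 2, 4, 4, 4, 4)), tolerance = 1e-12)
  expect_equal(ens$n_null, 6L)
})

test_that("null ensembles are reproducible from the seed", {
  tr <- random_tree(20, 5)
  comm <- sim_communities(tr, richness = rep(5, 8), mode = "random", seed = 9)
  a <- shuffle_null(comm, tr, "mntd", n_iter = 49, seed = 123, keep_values = TRUE)
  b <- shuffle_null(comm, tr, "mntd", n_iter = 49, seed = 123, keep_values = TRUE)
  expect_identical(a, b)
  c <- shuffle_null(comm, tr, "mntd", n_iter = 49, seed = 124)
  expect_false(identical(a$null_mean, c$null_mean))
})

test_that("ses_indices reproduces the exhaustively derived NRI and SES.PD", {
  tr <- toy_tree()
  comm <- tibble::tibble(site = "s1", A = 1, B = 1)
  s <- ses_indices(comm, tr, mode = "exhaustive")
  expect_equal(s$nri, -(2 - 10 / 3) / 1.0327956, tolerance = 1e-6)
  expect_equal(s$nri, 1.29099, tolerance = 1e-5)
  expect_equal(s$ses_pd, -1.29099, tolerance = 1e-5)
  expect_equal(s$pd, 3)
  expect_equal(s$pd_null_mean, 11 / 3, tolerance = 1e-12)
  # two-taxon community: MPD = MNTD so NRI = NTI exactly
  expect_equal(s$nri, s$nti, tolerance = 1e-12)
})

test_that("exhaustive and Monte-Carlo nulls agree on a small tree", {
  tr <- random_tree(7, 11)
  comm <- tibble::tibble(site = "s1",
    !!!setNames(as.list(c(1, 1, 1, 0, 0, 0, 0)), tr$tip.label))
  ex <- suppressWarnings(shuffle_null(comm, tr, "mpd", mode = "exhaustive"))
  mc <- suppressWarnings(shuffle_null(comm, tr, "mpd", n_iter = 10000, seed = 2))
  se <- ex$null_sd / sqrt(10000)
  expect_lt(abs(mc$null_mean - ex$null_mean), 3 * se)
  expect_equal(mc$null_sd, ex$null_sd, tolerance = 0.05)
})

test_that("clade-restricted communities are flagged as clustered", {
  tr <- random_tree(60, 31)
  clade <- phylograd:::pick_clade(tr, min_frac = 0.15)
  comm <- tibble::tibble(site = "filtered",
    !!!setNames(as.list(as.numeric(tr$tip.label %in% clade[1:8])), tr$tip.label))
  s <- suppressWarnings(ses_indices(comm, tr, n_iter = 199, seed = 8))
  expect_gt(s$nri, 1.96)
  expect_true(s$nri_sig)
})

test_that("degenerate sites yield NA indices, never infinities", {
  # non-ultrametric tree: tip depths differ, so even a single-taxon site has
  # a non-degenerate PD null
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  comm <- tibble::tibble(site = c("single", "pair"),
    A = c(1, 1), B = c(0, 1), C = c(0, 0), D = c(0, 0))
  s <- suppressWarnings(ses_indices(comm, tr, n_iter = 30, seed = 1))
  expect_true(is.na(s$nri[s$site == "single"]))
  expect_true(is.na(s$nti[s$site == "single"]))
  expect_false(is.na(s$ses_pd[s$site == "single"]))
  expect_true(all(is.finite(s$ses_pd)))

  # a truly degenerate null (every permutation identical) is NA, not Inf
  full <- tibble::tibble(site = "all", A = 1, B = 1, C = 1, D = 1)
  sf <- suppressWarnings(ses_indices(full, tr, n_iter = 20, seed = 2))
  expect_true(is.na(sf$nri))
  expect_false(any(is.infinite(c(sf$nri, sf$nti, sf$ses_pd))))
})

test_that("species missing from the tree are reported by name", {
  comm <- tibble::tibble(site = "s1", A = 1, Z = 1)
  expect_error(ses_indices(comm, toy_tree(), n_iter = 5, seed = 1),
    class = "phylograd_lookup_error", regexp = "Z")
})
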