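tree3 <- parse_newick("((A:1,B:1):1,C:2);")
dist3 <- pairwise_distances(tree3)

test_that("MPD is the unweighted mean over distinct species pairs", {
  expect_equal(mpd(c("A", "B"), dist3), 2)
  expect_equal(mpd(c("A", "B", "C"), dist3), (2 + 4 + 4) / 3)
  # presence/absence: duplicated species change nothing
  expect_equal(mpd(c("A", "A", "B", "C", "C"), dist3),
               mpd(c("A", "B", "C"), dist3))
  expect_true(is.na(mpd("A", dist3)))
  expect_error(mpd(c("A", "Z"), dist3), "Z")
})

test_that("MPD matches the picante reference implementation", {
  skip_if_not_installed("picante")
  tr <- random_test_tree(25, 8)
  d <- pairwise_distances(tr)
  comm <- simulate_dataset(sim_config(n_plots = 6, pool_size = 25,
                                      scenario = "neutral",
                                      stems_range = c(30, 60),
                                      seed = 2))$community
  colnames(comm) <- tr$tip.label[seq_len(ncol(comm))]
  ours <- vapply(seq_len(nrow(comm)), function(i)
    mpd(colnames(comm)[comm[i, ] > 0], d), numeric(1))
  theirs <- picante::mpd(comm, d[colnames(comm), colnames(comm)])
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("exhaustive taxa-labels null reproduces the worked 3-species example", {
  r <- ses_mpd(c("A", "B"), dist3, exhaustive = TRUE)
  expect_equal(r$null_mean, mean(c(2, 4, 4)))
  expect_equal(r$null_sd, sd(c(2, 4, 4)))
  expect_equal(r$ses, (2 - 10 / 3) / sd(c(2, 4, 4)))
  expect_equal(r$ses, -2 / sqrt(3), tolerance = 1e-12)
  expect_equal(r$nri, -r$ses)
})

test_that("exhaustive null equals brute-force enumeration of relabelings on small pools", {
  for (n_tips in 5:7) {
    tr <- random_test_tree(n_tips, n_tips * 3)
    d <- pairwise_distances(tr)
    for (k in 2:(n_tips - 1)) {
      sp <- with_seed(k, sample(tr$tip.label, k))
      r <- ses_mpd(sp, d, exhaustive = TRUE)
      vals <- oracle_exhaustive_null(sp, d)
      expect_equal(r$null_mean, mean(vals), tolerance = 1e-12)
      expect_equal(r$null_sd, sd(vals), tolerance = 1e-12)
      expect_equal(r$ses, (r$mpd_obs - mean(vals)) / sd(vals),
                   tolerance = 1e-12)
    }
  }
})

test_that("a plot holding the entire pool has undefined SES (zero null sd)", {
  r <- ses_mpd(c("A", "B", "C"), dist3, exhaustive = TRUE)
  expect_equal(r$null_sd, 0)
  expect_true(is.na(r$ses))
  expect_true(is.na(r$nri))
})

test_that("SES null mean/sd agree with picante's taxa.labels null", {
  skip_if_not_installed("picante")
  tr <- random_test_tree(30, 5)
  d <- pairwise_distances(tr)
  sp <- with_seed(31, sample(tr$tip.label, 10))
  ours <- ses_mpd(sp, d, n_rand = 2000, seed = 1)
  samp <- rbind(p1 = as.integer(tr$tip.label %in% sp),
                p2 = as.integer(tr$tip.label %in% tr$tip.label[1:5]))
  colnames(samp) <- tr$tip.label
  theirs <- with_seed(2, picante::ses.mpd(samp, d, null.model = "taxa.labels",
                                          runs = 2000))
  # two independent Monte-Carlo estimates of the same null distribution
  expect_equal(ours$null_mean, theirs$mpd.rand.mean[1], tolerance = 0.02)
  expect_equal(ours$null_sd, theirs$mpd.rand.sd[1], tolerance = 0.1)
  expect_equal(ours$mpd_obs, theirs$mpd.obs[1], tolerance = 1e-10)
})

test_that("NRI = -SES exactly for every plot, and seeding makes results reproducible", {
  sim <- simulate_dataset(sim_config(n_plots = 8, pool_size = 40,
                                     scenario = "neutral", seed = 6))
  d <- pairwise_distances(sim$tree)
  t1 <- ses_mpd_table(sim$community, d, n_rand = 99, seed = 123)
  t2 <- ses_mpd_table(sim$community, d, n_rand = 99, seed = 123)
  expect_identical(t1, t2)
  expect_equal(t1$nri, -t1$ses)
  t3 <- ses_mpd_table(sim$community, d, n_rand = 99, seed = 124)
  expect_false(identical(t1$null_mean, t3$null_mean))
})

test_that("under random assembly the SES distribution is centred near zero", {
  tr <- random_test_tree(40, 17)
  d <- pairwise_distances(tr)
  plots <- with_seed(99, t(vapply(1:200, function(i)
    sample(tr$tip.label, 8), character(8))))
  ses <- vapply(seq_len(nrow(plots)), function(i)
    ses_mpd(plots[i, ], d, n_rand = 99, seed = 1000 + i)$ses, numeric(1))
  expect_lt(abs(mean(ses)), 3 * sd(ses) / sqrt(length(ses)))
  expect_gt(sd(ses), 0.8)
  expect_lt(sd(ses), 1.2)
})

test_that("clade-restricted plots are clustered and clade-spanning plots overdispersed", {
  # balanced two-clade tree: 8 + 8 tips
  nw <- paste0("((((a1:1,a2:1):1,(a3:1,a4:1):1):1,((a5:1,a6:1):1,(a7:1,a8:1):1):1):1,",
               "(((b1:1,b2:1):1,(b3:1,b4:1):1):1,((b5:1,b6:1):1,(b7:1,b8:1):1):1):1);")
  tr <- parse_newick(nw)
  d <- pairwise_distances(tr)
  one_clade <- vapply(1:30, function(i)
    ses_mpd(with_seed(i, sample(paste0("a", 1:8), 5)), d,
            n_rand = 99, seed = i)$nri, numeric(1))
  # one tip from each of the deepest subclades: maximally spread
  spread <- vapply(1:30, function(i)
    ses_mpd(with_seed(i, c(sample(paste0("a", 1:4), 1),
                           sample(paste0("a", 5:8), 1),
                           sample(paste0("b", 1:4), 1),
                           sample(paste0("b", 5:8), 1))), d,
            n_rand = 99, seed = 60 + i)$nri, numeric(1))
  expect_gt(mean(one_clade), 0)   # clustering: positive NRI
  expect_lt(mean(spread), 0)      # overdispersion: negative NRI
})

test_that("rarefied PD matches the worked example and exhaustive enumeration", {
  expect_equal(rarefied_pd(c(A = 2, B = 1, C = 0), tree3, 2), 8 / 3)
  for (seed in 1:3) {
    tr <- random_test_tree(6, seed + 40)
    counts <- with_seed(seed, setNames(rpois(6, 1.2), tr$tip.label))
    if (sum(counts) < 2) counts[1] <- counts[1] + 2
    for (n in seq_len(min(sum(counts), 6))) {
      expect_equal(rarefied_pd(counts, tr, n),
                   oracle_enum_rarefaction(counts, n, function(ind)
                     total_branch_length(tr, tr$tip.label[unique(ind)])),
                   tolerance = 1e-10)
    }
  }
})

test_that("rarefied PD limits: n = N recovers Faith's PD; monotone in n", {
  tr <- random_test_tree(15, 77)
  counts <- with_seed(8, setNames(rpois(15, 3), tr$tip.label))
  counts[counts == 0][1] <- 1
  N <- sum(counts)
  expect_equal(rarefied_pd(counts, tr, N),
               faith_pd(names(counts)[counts > 0], tr), tolerance = 1e-9)
  grid <- vapply(seq_len(N), function(n) rarefied_pd(counts, tr, n),
                 numeric(1))
  expect_true(all(diff(grid) >= -1e-9))
})

test_that("analytic rarefied PD agrees with seeded Monte-Carlo subsampling", {
  for (i in 1:3) {
    tr <- random_test_tree(20, i + 60)
    counts <- with_seed(i, setNames(rpois(20, 4) + 1, tr$tip.label))
    n <- floor(sum(counts) / 3)
    mc <- rarefied_pd_mc(counts, tr, n, n_draws = 3000, seed = 7 + i)
    expect_lt(abs(rarefied_pd(counts, tr, n) - mc$mean), 3 * mc$se + 1e-9)
  }
})

test_that("rooted Faith PD agrees with picante on multi-species plots", {
  skip_if_not_installed("picante")
  tr <- random_test_tree(18, 21)
  comm <- with_seed(3, t(vapply(1:5, function(i) {
    x <- integer(18); x[sample(18, sample(3:10, 1))] <- 1L; x
  }, integer(18))))
  dimnames(comm) <- list(paste0("P", 1:5), tr$tip.label)
  ours <- vapply(seq_len(nrow(comm)), function(i)
    faith_pd(colnames(comm)[comm[i, ] > 0], tr), numeric(1))
  theirs <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("Hill phylogenetic diversity: closed forms and worked example", {
  # single species: diversity 1
  expect_equal(hill_pd(c(A = 5, B = 0, C = 0), tree3), 1)
  # hand-evaluated branch sum on the 3-tip tree
  expect_equal(hill_pd(c(A = 1, B = 1, C = 1), tree3), 2.381102,
               tolerance = 1e-6)
  # star tree with equal depths: reduces to the effective number of species
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  x <- c(A = 8, B = 4, C = 2, D = 1)
  expect_equal(hill_pd(x, star),
               shannon_effective(x)$effective_species, tolerance = 1e-9)
})

test_that("Hill-PD q = 1 equals the general-q formula in the limit", {
  tr <- random_test_tree(12, 31)
  counts <- with_seed(4, setNames(rpois(12, 3) + 1, tr$tip.label))
  q1 <- hill_pd(counts, tr, q = 1)
  expect_equal(hill_pd(counts, tr, q = 1 - 1e-6), q1, tolerance = 1e-4)
  expect_equal(hill_pd(counts, tr, q = 1 + 1e-6), q1, tolerance = 1e-4)
})

test_that("Hill-PD is replication-invariant", {
  tr <- random_test_tree(10, 55)
  counts <- with_seed(5, setNames(rpois(10, 2) + 1, tr$tip.label))
  expect_equal(hill_pd(counts, tr), hill_pd(counts * 7, tr),
               tolerance = 1e-12)
  expect_gte(hill_pd(counts, tr), 1)
})

test_that("phylostructure_table combines SES, rarefied PD and Hill-PD per plot", {
  sim <- simulate_dataset(sim_config(n_plots = 6, pool_size = 30,
                                     scenario = "neutral", seed = 13))
  tab <- phylostructure_table(sim$community, sim$tree, n_rand = 49, seed = 5)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$nri, -tab$ses)
  expect_true(all(tab$pd_rarefied > 0))
  expect_true(all(tab$hill_pd_q1 >= 1))
  full_pd <- vapply(seq_len(6), function(i)
    faith_pd(colnames(sim$community)[sim$community[i, ] > 0], sim$tree),
    numeric(1))
  expect_true(all(tab$pd_rarefied <= full_pd + 1e-9))
})
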