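test_that("simulated trees are unit-height, ultrametric and deterministic", {
  tr <- simulate_tree(156, seed = 5)
  expect_length(tr$tip.label, 156)
  expect_equal(tree_height(tr), 1, tolerance = 1e-9)
  expect_s3_class(validate_ultrametric_tree(tr), "phylo")
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(156, seed = 5)))
  expect_false(identical(ape::write.tree(tr), ape::write.tree(simulate_tree(156, seed = 6))))
  # two tips: a cherry with both depths 1
  ch <- simulate_tree(2, seed = 1)
  expect_equal(unname(pairwise_distances(ch)[1, 2]), 2, tolerance = 1e-9)
  expect_error(simulate_tree(1), ">= 2")
})

test_that("cherry counts match the Yule expectation n/3", {
  n <- 64
  cherries <- vapply(1:150, function(s) {
    tr <- simulate_tree(n, seed = s)
    # a cherry = an internal node whose two children are both tips
    tab <- table(tr$edge[, 1][tr$edge[, 2] <= n])
    sum(tab == 2)
  }, numeric(1))
  se <- sd(cherries) / sqrt(length(cherries))
  expect_lt(abs(mean(cherries) - n / 3), 3 * se)
})

test_that("soil draws respect the configured windows and are reproducible", {
  cfg <- sim_config(n_plots = 50, scenario = "neutral", seed = 21)
  s1 <- simulate_soil(cfg)
  s2 <- simulate_soil(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$soil$value > 0))
  tr <- s1$truth
  for (nut in c("AN", "EP")) {
    mr <- if (nut == "AN") cfg$an_mean_range else cfg$ep_mean_range
    cr <- if (nut == "AN") cfg$an_cv_range else cfg$ep_cv_range
    sub <- tr[tr$nutrient == nut, ]
    expect_true(all(sub$mean_true >= mr[1] & sub$mean_true <= mr[2]))
    expect_true(all(sub$cv_true >= cr[1] & sub$cv_true <= cr[2]))
  }
  # replicate moments target the latent values: pooled over many plots the
  # attenuated sample CV still increases in CV* (see soil metrics tests)
  expect_equal(sort(unique(s1$soil$replicate)), 1:4)
})

test_that("optional EP mean-CV coupling induces the documented correlation", {
  cfg0 <- sim_config(n_plots = 400, scenario = "neutral", seed = 31)
  cfg1 <- sim_config(n_plots = 400, scenario = "neutral", seed = 31,
                     couple_ep_mean_cv = TRUE)
  t0 <- simulate_soil(cfg0)$truth
  t1 <- simulate_soil(cfg1)$truth
  ep0 <- t0[t0$nutrient == "EP", ]
  ep1 <- t1[t1$nutrient == "EP", ]
  expect_lt(abs(cor(ep0$mean_true, ep0$cv_true)), 0.15)  # off by default
  expect_gt(cor(ep1$mean_true, log(ep1$cv_true)), 0.3)
})

test_that("communities cover only tree tips and hit the stem windows", {
  for (scen in c("niche_coupled", "unimodal", "neutral")) {
    sim <- simulate_dataset(sim_config(n_plots = 8, pool_size = 60,
                                       scenario = scen, seed = 3))
    expect_true(all(colnames(sim$community) %in% sim$tree$tip.label))
    totals <- rowSums(sim$community)
    expect_true(all(totals >= sim$truth$config$stems_range[1]))
    expect_true(all(totals <= sim$truth$config$stems_range[2]))
    expect_true(all(sim$community >= 0))
    expect_identical(sim$truth$scenario, scen)
  }
})

test_that("datasets are reproducible bit-for-bit and written files identical", {
  cfg <- sim_config(n_plots = 6, pool_size = 30, scenario = "niche_coupled",
                    seed = 14)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$community, s2$community)
  expect_identical(s1$soil, s2$soil)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in c("tree.nwk", "community.csv", "soil.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the neutral scenario decouples soil heterogeneity from diversity", {
  n_sig <- 0L
  for (s in 1:6) {
    sim <- simulate_dataset(sim_config(scenario = "neutral", seed = s))
    rich <- rowSums(sim$community > 0)
    cvt <- sim$truth$soil
    cv_ep <- cvt$cv_true[cvt$nutrient == "EP"][
      match(rownames(sim$community),
            cvt$plot_id[cvt$nutrient == "EP"])]
    n_sig <- n_sig + (pearson_cor(cv_ep, rich)$p < 0.05)
  }
  expect_lte(n_sig, 2)
})

test_that("the niche-coupled scenario links heterogeneity to rarefied richness", {
  for (s in 1:3) {
    sim <- simulate_dataset(sim_config(scenario = "niche_coupled", seed = s))
    n <- smallest_sample_size(sim$community)
    rtr <- vapply(seq_len(nrow(sim$community)), function(i)
      rarefied_richness(sim$community[i, ], n), numeric(1))
    u <- sim$truth$plots$u
    r <- pearson_cor(u, rtr)
    expect_gt(r$r, 0)
    expect_lt(r$p, 0.05)
  }
})

test_that("repulsion and clade filtering set the direction of phylogenetic structure", {
  # strong repulsion, no clade filter (a fully homogeneous plot): NRI < 0;
  # full clade filtering (a maximally heterogeneous plot): NRI > 0
  sim <- simulate_dataset(sim_config(n_plots = 10, pool_size = 80,
                                     scenario = "niche_coupled", seed = 42))
  d <- pairwise_distances(sim$tree)
  u <- sim$truth$plots$u
  tab <- ses_mpd_table(sim$community, d, n_rand = 199, seed = 7)
  lo <- u <= sort(u)[3]
  hi <- u >= sort(u, decreasing = TRUE)[3]
  expect_lt(mean(tab$nri[lo]), mean(tab$nri[hi]))
})

test_that("the unimodal scenario produces a humped heterogeneity-richness relation", {
  rich_t <- matrix(0, 6, 3)
  for (s in 1:6) {
    sim <- simulate_dataset(sim_config(scenario = "unimodal", seed = s))
    u <- sim$truth$plots$u
    rich <- rowSums(sim$community > 0)
    terc <- cut(u, quantile(u, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                labels = FALSE)
    rich_t[s, ] <- tapply(rich, terc, mean)
  }
  m <- colMeans(rich_t)
  expect_gt(m[2], m[1])       # rising limb
  expect_gt(m[2], m[3] - 1)   # declining/saturating limb beyond the peak
})
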