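# Synthetic communities, phylogenies and soil samples under three assembly
# regimes (niche_coupled, unimodal, neutral), emulating the statistical
# structure the analysis assumes: 39 plots of 20 x 20 m, four soil samples
# per plot, a pool of ~156 species on an ultrametric tree, per-plot stem
# totals >= 84 and nutrient means/CVs inside the study windows.

#' Simulation configuration
#'
#' Defaults emulate the study system: 39 plots, 4 soil replicates per
#' plot, a 156-species pool on a unit-height pure-birth tree, 84-300
#' recorded stems per plot, alkali-hydrolysable nitrogen (AN) means
#' 123.25-240.25 mg/kg with CV 0.02-0.35 and extractable phosphorus (EP)
#' means 2.43-23.4 mg/kg with CV 0.16-1.13. The scenario parameters
#' (niche breadth, micro-niche count, phylogenetic repulsion) are the
#' calibrated values committed with the package; the calibration sweep is
#' in `scripts/calibrate_scenarios.R`.
#'
#' Scenario semantics: under `niche_coupled`, species nutrient-niche
#' optima evolve by Brownian motion on the tree (phylogenetic niche
#' conservatism); each plot offers micro-niches whose number and spread
#' grow with its latent EP heterogeneity CV*, and co-occurring close
#' relatives suffer a repulsion penalty that weakens as CV* grows —
#' richness and NRI both increase with CV*. `neutral` draws stems
#' multinomially from a pool-wide abundance distribution, ignoring soil.
#' `unimodal` is niche_coupled plus an effective-area thinning that
#' removes species at high CV*, producing a humped
#' heterogeneity-diversity relation.
#'
#' @param n_plots number of plots.
#' @param n_soil_replicates soil samples per plot (study design: four
#'   corners).
#' @param pool_size species-pool size.
#' @param stems_range range of recorded (DBH > 1 cm) stems per plot.
#' @param scenario `"niche_coupled"`, `"unimodal"` or `"neutral"`.
#' @param ep_mean_range,ep_cv_range,an_mean_range,an_cv_range uniform
#'   ranges (mg/kg; CV dimensionless) for the latent per-plot nutrient
#'   mean M* and heterogeneity CV*.
#' @param couple_ep_mean_cv draw EP M* and CV* with a Gaussian-copula
#'   correlation of `ep_mean_cv_rho` instead of independently (off by
#'   default).
#' @param ep_mean_cv_rho copula correlation used when coupling is on.
#' @param niche_breadth sd of a species' suitability kernel around a
#'   micro-niche centre, on the standardized trait scale.
#' @param clade_filter_strength,clade_filter_scale each micro-niche is
#'   anchored on a focal species (drawn by trait suitability at the
#'   niche centre); suitability for that niche blends the trait kernel
#'   with a conserved clade kernel exp(-d / scale) in phylogenetic
#'   distance d to the anchor, with blend weight min(1, strength * u).
#'   Habitat specialization is phylogenetically conserved, so in
#'   heterogeneous plots (large u) distinct micro-niches recruit
#'   distinct clades; in homogeneous plots (u -> 0) the filter vanishes.
#' @param env_center_sd sd of the plot-level environmental offset added
#'   to every expressed habitat centre.
#' @param habitat_spread trait-scale spread of the landscape's habitat
#'   centres (normal quantiles scaled by this value).
#' @param n_microniches_max number of distinct micro-habitat types in the
#'   landscape. Habitats are ordered from the central (common) to the
#'   extreme (rare) trait positions and expressed nestedly: a plot with
#'   normalized heterogeneity u offers the first 1 + round(u * (max - 1))
#'   of them, so both the number and the spread of offered micro-niches
#'   grow with CV*.
#' @param repulsion_strength,repulsion_scale penalty on species at
#'   phylogenetic distance d from an established close relative:
#'   1 - strength * (1 - u) * exp(-d / scale).
#' @param dominance_sd sd (log scale) of species' competitive
#'   abilities; the hierarchy acts with exponent (1 - u), so fitness
#'   differences concentrate dominance in homogeneous plots and are
#'   equalized as heterogeneity partitions the plot into micro-niches.
#' @param extinction_strength unimodal thinning: species availability
#'   probability 1 - strength * u.
#' @param sad_sd lognormal sd of the neutral pool abundance distribution.
#' @param dbh_meanlog,dbh_sdlog lognormal DBH (cm) attached to each stem;
#'   stems with DBH <= 1 cm are discarded before counting.
#' @param seed top-level integer seed.
#' @return a list of class `"phet_config"`.
#' @export
sim_config <- function(n_plots = 39,
                       n_soil_replicates = 4,
                       pool_size = 156,
                       stems_range = c(84, 300),
                       scenario = c("niche_coupled", "unimodal", "neutral"),
                       ep_mean_range = c(2.43, 23.4),
                       ep_cv_range = c(0.16, 1.13),
                       an_mean_range = c(123.25, 240.25),
                       an_cv_range = c(0.02, 0.35),
                       couple_ep_mean_cv = FALSE,
                       ep_mean_cv_rho = 0.5,
                       niche_breadth = 0.7,
                       clade_filter_strength = 2,
                       clade_filter_scale = 0.15,
                       env_center_sd = 0.3,
                       habitat_spread = 1.2,
                       n_microniches_max = 22,
                       repulsion_strength = 0.98,
                       repulsion_scale = 1.2,
                       dominance_sd = 2.8,
                       extinction_strength = 0.95,
                       sad_sd = 1.5,
                       dbh_meanlog = log(6),
                       dbh_sdlog = 0.8,
                       seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- list(n_plots = assert_scalar_count(n_plots, "n_plots", min = 3L),
              n_soil_replicates = assert_scalar_count(n_soil_replicates,
                                                      "n_soil_replicates",
                                                      min = 2L),
              pool_size = assert_scalar_count(pool_size, "pool_size",
                                              min = 2L),
              stems_range = stems_range, scenario = scenario,
              ep_mean_range = ep_mean_range, ep_cv_range = ep_cv_range,
              an_mean_range = an_mean_range, an_cv_range = an_cv_range,
              couple_ep_mean_cv = isTRUE(couple_ep_mean_cv),
              ep_mean_cv_rho = ep_mean_cv_rho,
              niche_breadth = niche_breadth,
              clade_filter_strength = clade_filter_strength,
              clade_filter_scale = clade_filter_scale,
              env_center_sd = env_center_sd,
              habitat_spread = habitat_spread,
              n_microniches_max = assert_scalar_count(n_microniches_max,
                                                      "n_microniches_max"),
              repulsion_strength = repulsion_strength,
              repulsion_scale = repulsion_scale,
              dominance_sd = dominance_sd,
              extinction_strength = extinction_strength,
              sad_sd = sad_sd,
              dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
              seed = assert_scalar_count(seed, "seed", min = 0L))
  for (rg in c("stems_range", "ep_mean_range", "ep_cv_range",
               "an_mean_range", "an_cv_range")) {
    v <- cfg[[rg]]
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0) || v[1] > v[2])
      stop(sprintf("`%s` must be a positive increasing length-2 range", rg),
           call. = FALSE)
  }
  class(cfg) <- "phet_config"
  cfg
}

#' Simulate an ultrametric species-pool phylogeny
#'
#' Pure-birth (Yule) tree rescaled to unit height, with tips relabelled
#' `sp001`, `sp002`, ... Deterministic given the seed.
#'
#' @param pool_size number of tips (>= 2).
#' @param seed integer seed.
#' @return a validated `"phylo"` object of height 1.
#' @export
simulate_tree <- function(pool_size, seed = 1) {
  pool_size <- assert_scalar_count(pool_size, "pool_size", min = 2L)
  tr <- with_seed(seed, ape::rphylo(pool_size, birth = 1, death = 0))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr$tip.label <- sprintf("sp%03d", seq_len(pool_size))
  validate_ultrametric_tree(tr)
}

# lognormal replicates with exact latent mean M and CV (moment inversion)
.soil_replicates <- function(M, cv, n_rep) {
  if (cv <= 0) return(rep(M, n_rep))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n_rep, meanlog = log(M) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate replicated soil nutrient samples
#'
#' Per plot and nutrient, a latent availability M* and heterogeneity CV*
#' are drawn from the configured ranges (the mean uniformly, the CV --
#' a scale parameter -- log-uniformly); replicates are
#' lognormal with mean exactly M* and coefficient of variation exactly
#' CV* (moment inversion), keeping CV* the controlled quantity. With
#' `couple_ep_mean_cv` the EP M* and CV* share a Gaussian copula.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default: derived from `config$seed`).
#' @return list with `soil` (long table: `plot_id`, `nutrient`,
#'   `replicate`, `value`) and `truth` (`plot_id`, `nutrient`,
#'   `mean_true`, `cv_true`).
#' @export
simulate_soil <- function(config, seed = derive_seed(config$seed, 3)) {
  stopifnot(inherits(config, "phet_config"))
  np <- config$n_plots
  plot_ids <- sprintf("P%02d", seq_len(np))
  with_seed(seed, {
    draw_nut <- function(nutrient, mean_range, cv_range, couple, rho) {
      if (couple) {
        z1 <- stats::rnorm(np)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(np)
        M <- mean_range[1] + stats::pnorm(z1) * diff(mean_range)
        cv <- exp(log(cv_range[1]) +
                    stats::pnorm(z2) * (log(cv_range[2]) - log(cv_range[1])))
      } else {
        M <- stats::runif(np, mean_range[1], mean_range[2])
        cv <- exp(stats::runif(np, log(cv_range[1]), log(cv_range[2])))
      }
      vals <- lapply(seq_len(np), function(i)
        .soil_replicates(M[i], cv[i], config$n_soil_replicates))
      list(soil = data.frame(
             plot_id = rep(plot_ids, each = config$n_soil_replicates),
             nutrient = nutrient,
             replicate = rep(seq_len(config$n_soil_replicates), np),
             value = unlist(vals), stringsAsFactors = FALSE),
           truth = data.frame(plot_id = plot_ids, nutrient = nutrient,
                              mean_true = M, cv_true = cv,
                              stringsAsFactors = FALSE))
    }
    an <- draw_nut("AN", config$an_mean_range, config$an_cv_range,
                   FALSE, 0)
    ep <- draw_nut("EP", config$ep_mean_range, config$ep_cv_range,
                   config$couple_ep_mean_cv, config$ep_mean_cv_rho)
    list(soil = rbind(an$soil, ep$soil),
         truth = rbind(an$truth, ep$truth))
  })
}

# landscape-level habitat anchors: trait targets at normal quantiles
# scaled by habitat_spread, ordered central-to-extreme, each anchored on
# the species whose optimum is nearest the target
.habitat_anchors <- function(z, cfg) {
  m_max <- cfg$n_microniches_max
  tq <- stats::qnorm(seq_len(m_max) / (m_max + 1)) * cfg$habitat_spread
  tq <- tq[order(abs(tq))]
  anchors <- vapply(tq, function(t) which.min(abs(z - t)), integer(1))
  list(targets = tq, anchors = anchors)
}

# one plot's stem-by-stem lottery assembly (niche_coupled / unimodal)
.assemble_plot <- function(z, comp, phylo_d, hab, n_stems, u, u_lin, cfg) {
  S <- length(z)
  e_p <- stats::rnorm(1, 0, cfg$env_center_sd)
  alpha <- cfg$repulsion_strength * max(0, 1 - u_lin)
  m <- 1L + as.integer(round(u * (cfg$n_microniches_max - 1)))
  centers <- z[hab$anchors[seq_len(m)]] + e_p
  sb2 <- 2 * cfg$niche_breadth^2
  # micro-niche suitability: trait kernel blended with a conserved clade
  # kernel around the habitat's anchor species, expressed as u grows
  lam <- min(1, cfg$clade_filter_strength * u)
  suit <- vapply(seq_len(m), function(j) {
    kern <- exp(-(z - centers[[j]])^2 / sb2)
    (1 - lam) * kern +
      lam * exp(-phylo_d[, hab$anchors[[j]]] / cfg$clade_filter_scale)
  }, numeric(S))
  # competitive hierarchy, expressed at exponent (1 - u_lin)
  dom <- exp(cfg$dominance_sd * (1 - u_lin) * comp)
  avail <- rep(1, S)
  if (cfg$scenario == "unimodal") {
    avail <- stats::rbinom(S, 1, max(0.05, 1 - cfg$extinction_strength * u))
    if (sum(avail) < 2) avail[sample.int(S, 2)] <- 1
  }
  pen <- rep(1, S)
  counts <- integer(S)
  present <- logical(S)
  accepted <- 0L
  while (accepted < n_stems) {
    j <- sample.int(m, 1L)
    w <- suit[, j] * dom * pen * avail
    sw <- sum(w)
    if (!is.finite(sw) || sw <= 0) { w <- pen * avail; sw <- sum(w) }
    sp <- sample.int(S, 1L, prob = w)
    dbh <- stats::rlnorm(1, cfg$dbh_meanlog, cfg$dbh_sdlog)
    if (dbh <= 1) next  # below the census threshold
    accepted <- accepted + 1L
    counts[sp] <- counts[sp] + 1L
    if (!present[sp]) {
      present[sp] <- TRUE
      if (alpha > 0) {
        f <- 1 - alpha * exp(-phylo_d[, sp] / cfg$repulsion_scale)
        f[sp] <- 1  # repulsion is interspecific
        pen <- pen * f
      }
    }
  }
  counts
}

#' Simulate a plot-by-species community matrix
#'
#' Species niche optima evolve by Brownian motion on the tree and are
#' standardized; each plot's normalized EP heterogeneity u (its latent
#' CV* rescaled to \[0, 1\] over the configured range) sets the number
#' and spread of micro-niche centres, and the strength of the repulsion
#' penalty between co-occurring close relatives (strong at u = 0, absent
#' at u = 1). Stems are recruited one at a time by lottery; each carries
#' a lognormal DBH and only stems with DBH > 1 cm are counted. The
#' neutral scenario instead draws stems multinomially from a pool-wide
#' lognormal abundance distribution (DBH thinning is
#' species-independent, so recorded neutral stems are exactly
#' multinomial).
#'
#' @param tree species-pool tree from [simulate_tree()].
#' @param soil_truth the `truth` element of [simulate_soil()].
#' @param config a [sim_config()].
#' @param seed integer seed (default: derived from `config$seed`).
#' @return list with `community` (plot-by-species count matrix),
#'   `plot_truth` (`plot_id`, `u`, `n_stems`, `scenario`) and `optima`
#'   (named standardized niche optima).
#' @export
simulate_community <- function(tree, soil_truth, config,
                               seed = derive_seed(config$seed, 2)) {
  stopifnot(inherits(config, "phet_config"))
  validate_ultrametric_tree(tree)
  S <- length(tree$tip.label)
  ept <- soil_truth[soil_truth$nutrient == "EP", , drop = FALSE]
  ept <- ept[order(ept$plot_id), , drop = FALSE]
  np <- nrow(ept)
  if (np < 1L) stop("soil truth contains no EP rows", call. = FALSE)
  z <- with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = 1))
  z <- (z - mean(z)) / stats::sd(z)
  comp <- with_seed(derive_seed(seed, 2), stats::rnorm(S))
  hab <- NULL
  rng <- config$ep_cv_range
  # heterogeneity driver on the relative (log) scale: CVs span nearly an
  # order of magnitude, so a doubling of CV* is treated the same anywhere
  # in the range
  u <- pmin(1, pmax(0, (log(ept$cv_true) - log(rng[1])) /
                      (log(rng[2]) - log(rng[1]))))
  # competition strength declines on the linear CV scale instead, so the
  # hierarchy and repulsion stay strong only in genuinely homogeneous plots
  u_lin <- pmin(1, pmax(0, (ept$cv_true - rng[1]) / (rng[2] - rng[1])))
  phylo_d <- if (config$scenario == "neutral") NULL else
    pairwise_distances(tree)
  if (config$scenario != "neutral") hab <- .habitat_anchors(z, config)
  sad <- with_seed(derive_seed(seed, 1),
                   exp(stats::rnorm(S, 0, config$sad_sd)))
  counts <- matrix(0L, nrow = np, ncol = S,
                   dimnames = list(ept$plot_id, tree$tip.label))
  n_stems <- integer(np)
  for (i in seq_len(np)) {
    res <- with_seed(derive_seed(seed, 100 + i), {
      ns <- as.integer(round(stats::runif(1, config$stems_range[1],
                                          config$stems_range[2])))
      ci <- if (config$scenario == "neutral") {
        as.integer(stats::rmultinom(1, ns, sad))
      } else {
        .assemble_plot(z, comp, phylo_d, hab, ns, u[i], u_lin[i], config)
      }
      list(ns = ns, counts = ci)
    })
    n_stems[i] <- res$ns
    counts[i, ] <- res$counts
  }
  list(community = counts,
       plot_truth = data.frame(plot_id = ept$plot_id, u = u,
                               n_stems = n_stems,
                               scenario = config$scenario,
                               stringsAsFactors = FALSE),
       optima = z)
}

#' Simulate a complete synthetic dataset
#'
#' Tree, soil samples and community under one configuration and seed;
#' all stages use sub-seeds derived from `config$seed`, so the whole
#' dataset is reproducible bit-for-bit.
#'
#' @param config a [sim_config()].
#' @return a list of class `"phet_sim"`: `tree`, `community`, `soil`,
#'   `truth` (latent soil means/CVs, per-plot u, niche optima, config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "phet_config"))
  tree <- simulate_tree(config$pool_size, seed = derive_seed(config$seed, 1))
  soil <- simulate_soil(config)
  comm <- simulate_community(tree, soil$truth, config)
  structure(list(tree = tree,
                 community = comm$community,
                 soil = soil$soil,
                 truth = list(soil = soil$truth,
                              plots = comm$plot_truth,
                              optima = comm$optima,
                              scenario = config$scenario,
                              config = unclass(config))),
            class = "phet_sim")
}

#' @export
print.phet_sim <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d plots x %d species pool (scenario: %s)\n",
              nrow(x$community), ncol(x$community), x$truth$scenario))
  cat(sprintf("  stems/plot: %d-%d; tree height %.3f\n",
              min(rowSums(x$community)), max(rowSums(x$community)),
              tree_height(x$tree)))
  invisible(x)
}

#' Write a synthetic dataset to standard input files
#'
#' Writes `tree.nwk` (Newick), `community.csv`, `soil.csv` and
#' `truth.json` into a directory; the three data files are exactly the
#' inputs [run_pipeline()] accepts.
#'
#' @param x a `"phet_sim"` dataset.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "phet_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             community = file.path(dir, "community.csv"),
             soil = file.path(dir, "soil.csv"),
             truth = file.path(dir, "truth.json"))
  ape::write.tree(x$tree, file = paths[["tree"]])
  write_community_csv(x$community, paths[["community"]])
  write_soil_csv(x$soil, paths[["soil"]])
  truth <- x$truth
  truth$optima <- as.list(truth$optima)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(paths)
}
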