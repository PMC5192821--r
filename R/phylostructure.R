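# Community phylogenetic structure per plot: MPD, the taxa-labels
# permutation null with SES/NRI, rooted Faith PD with analytic
# individual-based rarefaction, and Hill-number phylogenetic diversity.

#' Mean pairwise phylogenetic distance of a species set
#'
#' Unweighted (presence/absence) mean of the tip-to-tip distances over all
#' unordered pairs of distinct species present in a plot. Abundances play
#' no role, so duplicating stems leaves the value unchanged.
#'
#' @param species character vector of species present (>= 2 for a defined
#'   value; with fewer the metric is undefined and `NA` is returned).
#' @param dist symmetric distance matrix from [pairwise_distances()].
#' @return the mean pairwise distance, or `NA_real_` when fewer than two
#'   species are present.
#' @export
mpd <- function(species, dist) {
  species <- unique(as.character(species))
  labs <- colnames(dist)
  miss <- setdiff(species, labs)
  if (length(miss))
    stop("species not in distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  k <- length(species)
  if (k < 2L) return(NA_real_)
  sub <- dist[species, species]
  # zero diagonal + symmetry: mean over unordered pairs = sum / (k (k-1))
  sum(sub) / (k * (k - 1))
}

#' Standardized effect size of MPD under the taxa-labels null
#'
#' Builds the null distribution of MPD by shuffling the species labels of
#' the pool's distance matrix while holding plot richness fixed. For the
#' unweighted MPD each relabeling is equivalent to evaluating MPD on a
#' same-size species set drawn from the pool, which is how the null is
#' computed: by Monte-Carlo sampling of label permutations
#' (`exhaustive = FALSE`, the default) or by enumerating every distinct
#' relabeled species set once (`exhaustive = TRUE`, feasible for small
#' pools).
#'
#' SES = (observed MPD - null mean) / null sd, with the sample (n - 1)
#' standard deviation; NRI = -SES, so positive NRI indicates phylogenetic
#' clustering and negative NRI overdispersion. When the null sd is zero
#' (e.g. the plot holds the entire pool, or a star tree with equal
#' distances) SES is undefined and returned as `NA`.
#'
#' @inheritParams mpd
#' @param n_rand number of randomizations (default 9999).
#' @param seed integer seed for the randomizations (ignored when
#'   `exhaustive`).
#' @param exhaustive enumerate all `choose(pool, k)` relabeled sets
#'   instead of sampling.
#' @return a list with `mpd_obs`, `null_mean`, `null_sd`, `ses`, `nri`,
#'   `n_randomizations` and `richness`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' d <- pairwise_distances(tr)
#' ses_mpd(c("A", "B"), d, exhaustive = TRUE)  # SES = -sqrt(4/3)
#' @export
ses_mpd <- function(species, dist, n_rand = 9999, seed = NULL,
                    exhaustive = FALSE) {
  obs <- mpd(species, dist)
  k <- length(unique(as.character(species)))
  npool <- ncol(dist)
  empty <- list(mpd_obs = obs, null_mean = NA_real_, null_sd = NA_real_,
                ses = NA_real_, nri = NA_real_,
                n_randomizations = NA_integer_, richness = k)
  if (is.na(obs)) return(empty)
  d <- unname(dist)
  if (exhaustive) {
    n_sets <- choose(npool, k)
    if (n_sets > 2e5)
      stop("exhaustive null infeasible: ", n_sets, " relabeled sets",
           call. = FALSE)
    sets <- utils::combn(npool, k)
    nulls <- apply(sets, 2L, function(s) sum(d[s, s]) / (k * (k - 1)))
  } else {
    n_rand <- assert_scalar_count(n_rand, "n_rand")
    nulls <- with_seed(seed, vapply(seq_len(n_rand), function(i) {
      s <- sample.int(npool, k)
      sum(d[s, s]) / (k * (k - 1))
    }, numeric(1)))
  }
  nm <- mean(nulls)
  nsd <- if (length(nulls) >= 2L) stats::sd(nulls) else 0

  ses <- if (nsd > 0) (obs - nm) / nsd else NA_real_
  list(mpd_obs = obs, null_mean = nm, null_sd = nsd,
       ses = ses, nri = -ses, n_randomizations = length(nulls),
       richness = k)
}

#' Per-plot SES/NRI table for a community matrix
#'
#' Applies [ses_mpd()] to every plot of a community matrix. Each plot uses
#' its own sub-seed derived from `seed` and the plot index, so results do
#' not depend on evaluation order. Plots with fewer than two species get
#' `NA` for MPD/SES/NRI.
#'
#' @param community plot-by-species count matrix.
#' @param dist distance matrix over the full species pool (its columns
#'   define the pool for the null).
#' @param n_rand randomizations per plot.
#' @param seed top-level integer seed.
#' @return data.frame with one row per plot: `plot_id`, `richness`,
#'   `mpd_obs`, `null_mean`, `null_sd`, `ses`, `nri`,
#'   `n_randomizations`.
#' @export
ses_mpd_table <- function(community, dist, n_rand = 9999, seed = 1) {
  community <- as_community_matrix(community)
  miss <- setdiff(colnames(community), colnames(dist))
  if (length(miss))
    stop("community species missing from distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  # canonical label order so null draws are invariant to how the tree or
  # matrix happened to be ordered on input
  ord <- order(colnames(dist))
  dist <- dist[ord, ord]
  rows <- lapply(seq_len(nrow(community)), function(i) {
    pres <- colnames(community)[community[i, ] > 0]
    r <- ses_mpd(pres, dist, n_rand = n_rand,
                 seed = derive_seed(seed, 1000 + i))
    data.frame(plot_id = rownames(community)[i],
               richness = r$richness, mpd_obs = r$mpd_obs,
               null_mean = r$null_mean, null_sd = r$null_sd,
               ses = r$ses, nri = r$nri,
               n_randomizations = r$n_randomizations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Faith's phylogenetic diversity (rooted convention)
#'
#' @param species character vector of tip labels present.
#' @param tree a `"phylo"` object.
#' @return the branch-length sum of the minimal rooted subtree spanning
#'   the species; see [total_branch_length()].
#' @export
faith_pd <- function(species, tree) {
  total_branch_length(tree, species)
}

#' Analytically rarefied Faith's PD
#'
#' Expected rooted PD of a without-replacement subsample of `n`
#' individuals: each branch contributes its length times the probability
#' that at least one of the individuals below it is drawn,
#' E\[PD_n\] = sum_b L_b * (1 - choose(N - N_b, n) / choose(N, n)),
#' where N_b is the number of individuals descending from branch b.
#'
#' @param counts named nonnegative integer vector of stems per species
#'   (names are tip labels of `tree`).
#' @param tree a `"phylo"` object.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return the expected PD.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' rarefied_pd(c(A = 2, B = 1, C = 0), tr, 2)  # 8/3
#' @export
rarefied_pd <- function(counts, tree, n) {
  .check_counts(counts)
  N <- sum(counts)
  n <- assert_scalar_count(n, "n")
  if (n > N)
    stop(sprintf("n (%d) exceeds the total count N (%d)", n, N),
         call. = FALSE)
  bc <- branch_counts(tree, counts)
  bc <- bc[bc$n_below > 0, , drop = FALSE]
  sum(bc$length * (1 - exp(lchoose(N - bc$n_below, n) - lchoose(N, n))))
}

#' Monte-Carlo rarefied PD
#'
#' Seeded subsampling companion to [rarefied_pd()], used as an independent
#' check in tests.
#'
#' @inheritParams rarefied_pd
#' @param n_draws number of random subsamples.
#' @param seed integer seed.
#' @return list with mean PD over draws and its standard error.
#' @export
rarefied_pd_mc <- function(counts, tree, n, n_draws = 10000, seed = 1) {
  .check_counts(counts)
  n <- assert_scalar_count(n, "n")
  sp <- rep.int(names(counts), counts)
  if (n > length(sp)) stop("n exceeds the total count", call. = FALSE)
  with_seed(seed, {
    v <- vapply(seq_len(n_draws), function(i) {
      total_branch_length(tree, unique(sp[sample.int(length(sp), n)]))
    }, numeric(1))
    list(mean = mean(v), se = stats::sd(v) / sqrt(n_draws))
  })
}

#' Phylogenetic diversity based on Hill numbers
#'
#' Abundance-weighted phylogenetic Hill number of order `q`, reported as an
#' effective number of species at the temporal scale of the
#' abundance-weighted mean tip depth T = sum_b L_b a_b, where a_b is the
#' relative abundance passing through branch b. At q = 1 (the default and
#' the order used throughout the pipeline) this is
#' exp(-sum_b (L_b / T) a_b ln a_b), the q -> 1 limit of the general
#' formula (sum_b (L_b / T) a_b^q)^(1/(1-q)). Replication-invariant in the
#' counts; on a star tree with equal tip depths it reduces to the
#' effective number of species exp(H').
#'
#' @param counts named nonnegative integer vector of stems per tip.
#' @param tree a `"phylo"` object.
#' @param q diversity order; `1` in the pipeline (other orders exposed for
#'   the limit checks).
#' @return the effective-number diversity (>= 1).
#' @export
hill_pd <- function(counts, tree, q = 1) {
  .check_counts(counts)
  bc <- branch_counts(tree, counts)
  bc <- bc[bc$n_below > 0 & bc$length > 0, , drop = FALSE]
  a <- bc$n_below / sum(counts)
  Tbar <- sum(bc$length * a)
  if (Tbar <= 0) stop("tree has no positive-length branches above the sampled tips",
                      call. = FALSE)
  w <- bc$length / Tbar
  if (q == 1) {
    exp(-sum(w * a * log(a)))
  } else {
    sum(w * a^q)^(1 / (1 - q))
  }
}

#' Per-plot phylogenetic structure and diversity table
#'
#' Runs [ses_mpd_table()], [rarefied_pd()] and [hill_pd()] over all plots
#' of a community matrix.
#'
#' @param community plot-by-species count matrix.
#' @param tree `"phylo"` object whose tips cover the community species.
#' @param rarefy_n rarefaction depth for PD; `"auto"` = smallest plot
#'   total.
#' @param n_rand randomizations for the SES null.
#' @param seed top-level seed.
#' @return data.frame: `plot_id`, `richness`, `mpd_obs`, `null_mean`,
#'   `null_sd`, `ses`, `nri`, `n_randomizations`, `pd_rarefied`,
#'   `hill_pd_q1`.
#' @export
phylostructure_table <- function(community, tree, rarefy_n = "auto",
                                 n_rand = 9999, seed = 1) {
  community <- as_community_matrix(community)
  miss <- setdiff(colnames(community), tree$tip.label)
  if (length(miss))
    stop("community species missing from tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- resolve_rarefy_n(community, rarefy_n)
  d <- pairwise_distances(tree)
  tab <- ses_mpd_table(community, d, n_rand = n_rand, seed = seed)
  tab$pd_rarefied <- vapply(seq_len(nrow(community)), function(i) {
    x <- community[i, ]
    rarefied_pd(stats::setNames(as.numeric(x), colnames(community)), tree, n)
  }, numeric(1))
  tab$hill_pd_q1 <- vapply(seq_len(nrow(community)), function(i) {
    x <- community[i, ]
    hill_pd(stats::setNames(as.numeric(x), colnames(community)), tree, q = 1)
  }, numeric(1))
  tab
}
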