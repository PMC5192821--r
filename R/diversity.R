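# Per-plot taxonomic diversity: richness, Shannon entropy, effective number
# of species, and individual-based analytic rarefaction.

.check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 1L)
    stop("`counts` must be a numeric abundance vector", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative and non-missing", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers (stems)", call. = FALSE)
  if (sum(counts) < 1)
    stop("at least one positive count is required", call. = FALSE)
  as.numeric(counts)
}

#' Shannon entropy and effective number of species
#'
#' Shannon's index H' = -sum(f_i * ln f_i) over species with positive
#' proportion f_i (stems of species i / total stems), and the effective
#' number of species exp(H') — the Hill number of order 1. Natural
#' logarithms throughout.
#'
#' @param counts nonnegative integer abundance vector (one plot).
#' @return a list with elements `shannon_H` and `effective_species`.
#' @examples
#' shannon_effective(c(10, 10))   # H' = log(2), e^H' = 2
#' shannon_effective(c(4, 2, 2))  # H' = 1.5 * log(2)
#' @export
shannon_effective <- function(counts) {
  counts <- .check_counts(counts)
  f <- counts[counts > 0] / sum(counts)
  H <- -sum(f * log(f))
  list(shannon_H = H, effective_species = exp(H))
}

#' Expected species richness in a subsample (individual-based rarefaction)
#'
#' Analytic hypergeometric expectation of the number of species observed in
#' a without-replacement subsample of `n` individuals:
#' E\[S_n\] = sum_i (1 - choose(N - N_i, n) / choose(N, n)).
#' Deterministic; see [rarefy_mc()] for the Monte-Carlo check used in
#' tests.
#'
#' @param counts nonnegative integer abundance vector.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return the expected richness (a real number).
#' @examples
#' rarefied_richness(c(2, 1), 2)  # 5/3
#' @export
rarefied_richness <- function(counts, n) {
  counts <- .check_counts(counts)
  N <- sum(counts)
  n <- assert_scalar_count(n, "n")
  if (n > N)
    stop(sprintf("n (%d) exceeds the total count N (%d)", n, N),
         call. = FALSE)
  ni <- counts[counts > 0]
  # lchoose(a, n) = -Inf when a < n, giving absence probability 0
  sum(1 - exp(lchoose(N - ni, n) - lchoose(N, n)))
}

#' Monte-Carlo rarefied richness
#'
#' Seeded random subsampling companion to [rarefied_richness()]; used to
#' cross-validate the analytic expectation, not in the pipeline itself.
#'
#' @inheritParams rarefied_richness
#' @param n_draws number of random subsamples.
#' @param seed integer seed.
#' @return list with the mean richness over draws and its standard error.
#' @export
rarefy_mc <- function(counts, n, n_draws = 10000, seed = 1) {
  counts <- .check_counts(counts)
  n <- assert_scalar_count(n, "n")
  pool <- rep.int(seq_along(counts), counts)
  if (n > length(pool)) stop("n exceeds the total count", call. = FALSE)
  with_seed(seed, {
    s <- vapply(seq_len(n_draws), function(i) {
      length(unique(pool[sample.int(length(pool), n)]))
    }, numeric(1))
    list(mean = mean(s), se = stats::sd(s) / sqrt(n_draws))
  })
}

#' Smallest per-plot stem total of a community matrix
#'
#' The default rarefaction depth: diversity and PD are rarefied to the
#' smallest sample size across plots so that plots of unequal abundance
#' are comparable.
#'
#' @param community a plot-by-species count matrix (see
#'   [read_community_csv()]).
#' @return integer minimum of the plot totals.
#' @export
smallest_sample_size <- function(community) {
  community <- as_community_matrix(community)
  as.integer(min(rowSums(community)))
}

#' Per-plot diversity table
#'
#' @param community plot-by-species count matrix.
#' @param rarefy_n rarefaction depth; `"auto"` (default) uses
#'   [smallest_sample_size()].
#' @return data.frame with columns `plot_id`, `richness`, `shannon_H`,
#'   `e_H` (effective number of species) and `R_TR` (rarefied richness).
#' @export
diversity_table <- function(community, rarefy_n = "auto") {
  community <- as_community_matrix(community)
  n <- resolve_rarefy_n(community, rarefy_n)
  rows <- lapply(rownames(community), function(p) {
    x <- community[p, ]
    se <- shannon_effective(x)
    data.frame(plot_id = p,
               richness = sum(x > 0),
               shannon_H = se$shannon_H,
               e_H = se$effective_species,
               R_TR = rarefied_richness(x, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# shared: validate a community matrix (plots x species, integer counts)
as_community_matrix <- function(community) {
  m <- as.matrix(community)
  if (!is.numeric(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("community must be a nonempty numeric plot-by-species matrix",
         call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix needs plot rownames and species colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate species ids in community matrix", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate plot ids in community matrix", call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("community counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(m) < 1))
    stop("every plot must contain at least one stem", call. = FALSE)
  m
}

resolve_rarefy_n <- function(community, rarefy_n) {
  if (identical(rarefy_n, "auto"))
    return(smallest_sample_size(community))
  n <- assert_scalar_count(rarefy_n, "rarefy_n")
  if (n > min(rowSums(community)))
    stop("rarefy_n exceeds the smallest plot total", call. = FALSE)
  n
}
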