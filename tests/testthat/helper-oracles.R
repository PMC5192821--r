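# Independent oracles used to cross-check the package's metric
# implementations. These deliberately use naive algorithms (root-path
# comparisons, exhaustive enumeration, Monte-Carlo subsampling) and never
# call the code paths they verify.

# root-path edge index set of a tip
.oracle_root_path <- function(tree, tip_idx) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of <- integer(length(parent))
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  path <- integer(0)
  node <- tip_idx
  while (edge_of[node] != 0L) {
    path <- c(path, edge_of[node])
    node <- parent[node]
  }
  path
}

# tip-to-tip distance as the symmetric difference of root paths
oracle_pairwise_distances <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(i) .oracle_root_path(tree, i))
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sym <- c(setdiff(paths[[i]], paths[[j]]),
               setdiff(paths[[j]], paths[[i]]))
      d[i, j] <- d[j, i] <- sum(tree$edge.length[sym])
    }
  }
  d
}

# rooted PD as the union of root-path edge sets
oracle_rooted_pd <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  edges <- unique(unlist(lapply(idx, function(i) .oracle_root_path(tree, i))))
  sum(tree$edge.length[edges])
}

# all permutations of 1..n (recursive, for small n)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force taxa-labels null: every relabeling of the distance matrix,
# collapsed to the distinct relabeled species sets (each exactly once),
# MPD computed by an explicit double loop
oracle_exhaustive_null <- function(species, dist) {
  labs <- colnames(dist)
  k <- length(species)
  sp_idx <- match(species, labs)
  perms <- oracle_perms(length(labs))
  seen <- character(0)
  vals <- numeric(0)
  for (r in seq_len(nrow(perms))) {
    image <- sort(perms[r, sp_idx])
    key <- paste(image, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    tot <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) tot <- tot + dist[image[a], image[b]]
    }
    vals <- c(vals, tot / choose(k, 2))
  }
  vals
}

# exhaustive individual-based rarefaction: every without-replacement
# subsample of n individuals, metric averaged over all of them
oracle_enum_rarefaction <- function(counts, n, fun) {
  individuals <- rep.int(seq_along(counts), counts)
  subs <- utils::combn(length(individuals), n)
  mean(apply(subs, 2L, function(s) fun(individuals[s])))
}

# all abundance vectors (integer partitions) summing to N
oracle_partitions <- function(N, max_part = N) {
  if (N == 0L) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(N, max_part))) {
    for (rest in oracle_partitions(N - p, p)) out <- c(out, list(c(p, rest)))
  }
  out
}

# random ultrametric test tree (coalescent; independent of the package's
# pure-birth simulator)
random_test_tree <- function(n, seed) {
  with_seed(seed, ape::rcoal(n))
}
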