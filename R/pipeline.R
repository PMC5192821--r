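# End-to-end orchestration: read/validate the three inputs, build the
# per-plot metrics table, run the correlation layer, record a manifest.

#' Read a plot-by-species community matrix from CSV
#'
#' Expected layout: first column `plot_id`, remaining columns one species
#' each (header row = species ids), cells = stem counts.
#'
#' @param path CSV path.
#' @return validated integer plot-by-species matrix.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "plot_id")
    stop("community CSV must start with a `plot_id` column", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$plot_id)
  as_community_matrix(m)
}

#' Write a community matrix to CSV
#'
#' @param community plot-by-species matrix.
#' @param path output path.
#' @export
write_community_csv <- function(community, path) {
  community <- as_community_matrix(community)
  df <- data.frame(plot_id = rownames(community), community,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format soil sample table from CSV
#'
#' Expected columns: `plot_id`, `nutrient`, `replicate_index`,
#' `value_mg_per_kg` (the on-disk schema), or already the internal names
#' `replicate`/`value`.
#'
#' @param path CSV path.
#' @return data.frame with columns `plot_id`, `nutrient`, `replicate`,
#'   `value`.
#' @export
read_soil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("replicate_index" %in% names(df))
    names(df)[names(df) == "replicate_index"] <- "replicate"
  if ("value_mg_per_kg" %in% names(df))
    names(df)[names(df) == "value_mg_per_kg"] <- "value"
  as_soil_table(df)
}

#' Write a soil sample table to CSV
#'
#' Uses the on-disk schema `plot_id`, `nutrient`, `replicate_index`,
#' `value_mg_per_kg`.
#'
#' @param soil soil table (internal column names).
#' @param path output path.
#' @export
write_soil_csv <- function(soil, path) {
  soil <- as_soil_table(soil)
  out <- data.frame(plot_id = soil$plot_id, nutrient = soil$nutrient,
                    replicate_index = soil$replicate,
                    value_mg_per_kg = soil$value,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate the three pipeline inputs
#'
#' Checks that community species are covered by the tree tips, that soil
#' and community share the same plots, that the tree is ultrametric with
#' nonnegative branch lengths, and that soil values are positive (the
#' log transform must be defined). An empty report means the pipeline
#' may run.
#'
#' @param tree `"phylo"` object.
#' @param community plot-by-species matrix.
#' @param soil long-format soil table.
#' @return data.frame with columns `check` and `detail`, zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(tree, community, soil) {
  problems <- list()
  add <- function(check, detail)
    problems[[length(problems) + 1L]] <<- data.frame(
      check = check, detail = detail, stringsAsFactors = FALSE)
  tr_ok <- tryCatch({validate_ultrametric_tree(tree); TRUE},
                    error = function(e) {add("tree", conditionMessage(e)); FALSE})
  comm <- tryCatch(as_community_matrix(community),
                   error = function(e) {add("community", conditionMessage(e)); NULL})
  soil_t <- tryCatch(as_soil_table(soil),
                     error = function(e) {add("soil", conditionMessage(e)); NULL})
  if (tr_ok && !is.null(comm)) {
    miss <- setdiff(colnames(comm), tree$tip.label)
    if (length(miss))
      add("species_coverage", paste("community species not in tree:",
                                    paste(miss, collapse = ", ")))
  }
  if (!is.null(comm) && !is.null(soil_t)) {
    only_c <- setdiff(rownames(comm), unique(soil_t$plot_id))
    only_s <- setdiff(unique(soil_t$plot_id), rownames(comm))
    if (length(only_c))
      add("plot_match", paste("plots without soil samples:",
                              paste(only_c, collapse = ", ")))
    if (length(only_s))
      add("plot_match", paste("soil plots without community data:",
                              paste(only_s, collapse = ", ")))
  }
  if (!is.null(soil_t) && any(soil_t$value <= 0)) {
    bad <- unique(soil_t$plot_id[soil_t$value <= 0])
    add("soil_positive",
        paste("nonpositive soil values (log transform undefined) in plots:",
              paste(bad, collapse = ", ")))
  }
  if (length(problems)) do.call(rbind, problems) else
    data.frame(check = character(), detail = character(),
               stringsAsFactors = FALSE)
}

# soil summary reshaped to one row per plot with per-nutrient columns
.soil_wide <- function(soil) {
  ss <- soil_summary(soil)
  plots <- sort(unique(ss$plot_id))
  out <- data.frame(plot_id = plots, stringsAsFactors = FALSE)
  for (nut in sort(unique(ss$nutrient))) {
    sub <- ss[ss$nutrient == nut, , drop = FALSE]
    idx <- match(plots, sub$plot_id)
    out[[paste0(nut, "_mean")]] <- sub$mean_M[idx]
    out[[paste0(nut, "_cv")]] <- sub$cv[idx]
    out[[paste0(nut, "_log_mean")]] <- sub$log_mean[idx]
    out[[paste0(nut, "_log_cv")]] <- sub$log_cv[idx]
  }
  out
}

# the study's correlation grid: availability and CV of each nutrient
# (log scale) against R_TR, e^H' and NRI; NRI vs richness; mean vs CV per
# nutrient; CV vs the two phylogenetic-diversity metrics.
standard_pairs <- function(nutrients = c("AN", "EP")) {
  pairs <- list()
  for (nut in nutrients) {
    lm <- paste0(nut, "_log_mean"); lc <- paste0(nut, "_log_cv")
    pairs <- c(pairs, list(c(lm, "R_TR"), c(lm, "e_H"), c(lm, "nri"),
                           c(lc, "R_TR"), c(lc, "e_H"), c(lc, "nri"),
                           c(lm, lc),
                           c(lc, "pd_rarefied"), c(lc, "hill_pd_q1")))
  }
  c(pairs, list(c("nri", "richness")))
}

.safe_shapiro <- function(metrics, vars, alpha) {
  rows <- lapply(vars, function(v)
    tryCatch(shapiro_screen(metrics, v, alpha = alpha),
             error = function(e) NULL))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(), n = integer(),
                      W = numeric(), p = numeric(), normal = logical(),
                      stringsAsFactors = FALSE)
  out
}

#' Run the full heterogeneity-diversity pipeline
#'
#' From an ultrametric tree, a plot-by-species community matrix and a
#' replicated soil table (objects or file paths), computes the per-plot
#' metrics table (richness, H', e^H', rarefied richness, MPD, SES, NRI,
#' rarefied Faith PD, Hill-PD q = 1, soil means/CVs raw and log), the
#' Shapiro-Wilk normality screen, and the Pearson correlation grid the
#' study tests. Plots with undefined SES/NRI (fewer than two species, or
#' a degenerate null) are excluded pairwise from NRI correlations only.
#'
#' @param tree `"phylo"` object or Newick file path.
#' @param community plot-by-species matrix or CSV path (see
#'   [read_community_csv()]).
#' @param soil soil table or CSV path (see [read_soil_csv()]).
#' @param rarefy_n rarefaction depth for richness and PD; `"auto"`
#'   (default) = smallest plot stem total.
#' @param n_rand randomizations for the SES null (study value: 9999).
#' @param seed top-level seed governing all randomizations.
#' @param alpha significance level for the correlation flags.
#' @return a list of class `"phet_run"`: `metrics` (per-plot table),
#'   `correlations`, `normality`, `manifest`.
#' @export
run_pipeline <- function(tree, community, soil, rarefy_n = "auto",
                         n_rand = 9999, seed = 1, alpha = 0.05) {
  checksums <- c(tree = NA_character_, community = NA_character_,
                 soil = NA_character_)
  if (is.character(tree)) {
    checksums[["tree"]] <- unname(tools::md5sum(tree))
    tree <- read_ultrametric_tree(tree)
  }
  if (is.character(community)) {
    checksums[["community"]] <- unname(tools::md5sum(community))
    community <- read_community_csv(community)
  }
  if (is.character(soil)) {
    checksums[["soil"]] <- unname(tools::md5sum(soil))
    soil <- read_soil_csv(soil)
  }
  report <- validate_inputs(tree, community, soil)
  if (nrow(report))
    stop("invalid inputs:\n",
         paste(sprintf("- [%s] %s", report$check, report$detail),
               collapse = "\n"), call. = FALSE)
  community <- as_community_matrix(community)
  community <- community[order(rownames(community)),
                         order(colnames(community)), drop = FALSE]
  n <- resolve_rarefy_n(community, rarefy_n)
  div <- diversity_table(community, rarefy_n = n)
  phy <- phylostructure_table(community, tree, rarefy_n = n,
                              n_rand = n_rand, seed = seed)
  soil_w <- .soil_wide(soil)
  metrics <- merge(div, phy[, setdiff(names(phy), "richness")],
                   by = "plot_id", sort = TRUE)
  metrics <- merge(metrics, soil_w, by = "plot_id", sort = TRUE)
  nutrients <- sort(unique(soil$nutrient))
  soil_vars <- as.vector(outer(nutrients,
                               c("_mean", "_cv", "_log_mean", "_log_cv"),
                               paste0))
  normality <- .safe_shapiro(metrics,
                             c(soil_vars, "richness", "R_TR", "e_H",
                               "nri", "pd_rarefied", "hill_pd_q1"),
                             alpha)
  correlations <- correlation_table(metrics, standard_pairs(nutrients),
                                    alpha = alpha)
  manifest <- list(package = "phet",
                   version = as.character(utils::packageVersion("phet")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed, n_randomizations = n_rand,
                   rarefaction_n = n, alpha = alpha,
                   n_plots = nrow(community),
                   n_species = ncol(community),
                   n_plots_nri_defined = sum(is.finite(metrics$nri)),
                   input_checksums = as.list(checksums))
  structure(list(metrics = metrics, correlations = correlations,
                 normality = normality, manifest = manifest),
            class = "phet_run")
}

#' @export
print.phet_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("phet pipeline run: %d plots, %d species, rarefied to n = %d, %d randomizations (seed %s)\n",
              m$n_plots, m$n_species, m$rarefaction_n,
              m$n_randomizations, m$seed))
  sig <- x$correlations[x$correlations$significant, , drop = FALSE]
  cat(sprintf("significant correlations at alpha = %.2f: %d of %d\n",
              m$alpha, nrow(sig), nrow(x$correlations)))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s ~ %s: r = %.3f, p = %.3g (n = %d)\n",
                  sig$var_x[i], sig$var_y[i], sig$r[i], sig$p[i],
                  sig$n[i]))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `metrics.csv`, `correlations.csv`, `normality.csv` and
#' `manifest.json`. All numbers are written at full precision; rounding
#' is a display concern.
#'
#' @param run a `"phet_run"` result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "phet_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             correlations = file.path(dir, "correlations.csv"),
             normality = file.path(dir, "normality.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(run$metrics, paths[["metrics"]], row.names = FALSE)
  utils::write.csv(run$correlations, paths[["correlations"]],
                   row.names = FALSE)
  utils::write.csv(run$normality, paths[["normality"]],
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
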