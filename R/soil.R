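# Per-plot soil nutrient availability (mean) and heterogeneity (CV) from
# replicate samples, plus the log transform applied before correlation.

#' Summarize replicate soil measurements for one plot
#'
#' Availability is the arithmetic mean M of the replicates; heterogeneity
#' is the coefficient of variation CV = SD / M with the sample (n - 1)
#' standard deviation. Both are also returned on the natural-log scale,
#' the scale used by the correlation layer (`log_cv` is `NA` when CV = 0,
#' i.e. constant replicates).
#'
#' @param values numeric vector of >= 2 positive replicate measurements
#'   (mg/kg).
#' @return a list: `mean_M`, `sd_SD`, `cv`, `log_mean`, `log_cv`, `n`.
#' @examples
#' summarize_soil_plot(c(5, 10, 15, 10))  # CV = sqrt(50/3)/10
#' @export
summarize_soil_plot <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop("need at least 2 non-missing replicate values", call. = FALSE)
  if (any(values <= 0))
    stop("replicate values must be positive (log transform required)",
         call. = FALSE)
  M <- mean(values)
  SD <- stats::sd(values)
  cv <- SD / M
  list(mean_M = M, sd_SD = SD, cv = cv,
       log_mean = log(M),
       log_cv = if (cv > 0) log(cv) else NA_real_,
       n = length(values))
}

#' Natural-log transform with validation
#'
#' @param x numeric vector of positive values.
#' @param labels optional names used in the error message for nonpositive
#'   entries.
#' @return `log(x)`.
#' @export
log_transform <- function(x, labels = names(x)) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    who <- if (!is.null(labels)) labels[bad] else bad
    stop("nonpositive values cannot be log-transformed: ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  log(x)
}

#' Per-plot, per-nutrient soil summary table
#'
#' @param soil a long-format soil sample table with columns `plot_id`,
#'   `nutrient`, `replicate` and `value` (see [read_soil_csv()]).
#' @return data.frame with one row per plot x nutrient: `plot_id`,
#'   `nutrient`, `mean_M`, `sd_SD`, `cv`, `log_mean`, `log_cv`,
#'   `n_replicates`.
#' @export
soil_summary <- function(soil) {
  soil <- as_soil_table(soil)
  key <- interaction(soil$plot_id, soil$nutrient, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- soil[key == k, , drop = FALSE]
    s <- summarize_soil_plot(sub$value)
    data.frame(plot_id = sub$plot_id[1L], nutrient = sub$nutrient[1L],
               mean_M = s$mean_M, sd_SD = s$sd_SD, cv = s$cv,
               log_mean = s$log_mean, log_cv = s$log_cv,
               n_replicates = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$nutrient, out$plot_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_soil_table <- function(soil) {
  soil <- as.data.frame(soil)
  need <- c("plot_id", "nutrient", "replicate", "value")
  miss <- setdiff(need, names(soil))
  if (length(miss))
    stop("soil table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(soil$value) || anyNA(soil$value))
    stop("soil `value` column must be numeric and non-missing",
         call. = FALSE)
  n_rep <- table(interaction(soil$plot_id, soil$nutrient, drop = TRUE))
  if (any(n_rep < 2))
    stop("every plot x nutrient needs >= 2 replicates", call. = FALSE)
  soil
}
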