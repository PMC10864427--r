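#' Percent cancer-cell lysis from optical densities
#'
#' `100 - (OD of co-culture / OD of target cells alone) * 100`: the drop in
#' viable target signal relative to targets cultured without effectors.
#' Values below 0 (co-culture outgrowing the target-alone wells) or above
#' 100 are returned as-is — clipping would hide assay problems — and
#' negatives are flagged via the `flagged` attribute.
#'
#' @param odCocult OD490 of the effector/target co-culture (>= 0),
#'   vectorized.
#' @param odTarget OD490 of target cells alone (> 0).
#' @return Percent lysis; attribute `flagged` marks negative values.
#' @examples
#' percentLysis(0.5, 1.0)  # 50
#' @export
percentLysis <- function(odCocult, odTarget) {
  if (any(!is.finite(odTarget)) || any(odTarget <= 0))
    stop("odTarget must be positive (target-alone wells define the scale)", call. = FALSE)
  if (any(!is.finite(odCocult)) || any(odCocult < 0))
    stop("odCocult must be non-negative", call. = FALSE)
  out <- 100 - (odCocult / odTarget) * 100
  attr(out, "flagged") <- out < 0
  out
}

#' Replicate summary: mean and standard error
#'
#' `SEM = sd / sqrt(n)` with the sample standard deviation. A single
#' replicate returns its value with `sem = NA` and `sem_defined = FALSE`
#' rather than an error, so incomplete wells still summarize.
#'
#' @param replicates numeric replicate readings (at least one).
#' @return List with `mean`, `sem`, `n`, `sem_defined`.
#' @examples
#' summarizeReplicates(c(1, 2, 3))  # mean 2, SEM 0.5774
#' @export
summarizeReplicates <- function(replicates) {
  if (length(replicates) < 1L) stop("at least one replicate is required", call. = FALSE)
  if (any(!is.finite(replicates))) stop("replicates must be finite", call. = FALSE)
  n <- length(replicates)
  list(mean = mean(replicates),
       sem = if (n >= 2L) stats::sd(replicates) / sqrt(n) else NA_real_,
       n = n, sem_defined = n >= 2L)
}

#' Compare assay groups
#'
#' Two groups: two-sided Student's t test (pooled variance). More than two:
#' one-way ANOVA with Tukey's HSD post hoc pairwise comparisons
#' (Tukey--Kramer under unbalanced group sizes). Pairs are flagged
#' significant at `alpha`.
#'
#' @param groups named list of at least two numeric vectors, each with at
#'   least two observations.
#' @param alpha significance level for the per-pair flags.
#' @return List with `method` ("t.test" or "anova_tukey"), `statistic`
#'   (t or F), `p_value` (overall test), and `pairs` — a `data.frame` of
#'   pairwise comparisons with adjusted p-values and significance flags.
#' @examples
#' compareGroups(list(MT = c(50, 60, 55), WT = c(10, 12, 15)))
#' @export
compareGroups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least two replicate vectors", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop(sprintf("every group needs n >= 2 (violated by: %s)",
                 paste(names(groups)[ns < 2L], collapse = ", ")), call. = FALSE)
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    pairs <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                        diff = mean(groups[[1]]) - mean(groups[[2]]),
                        p_adj = tt$p.value, significant = tt$p.value < alpha)
    return(list(method = "t.test", statistic = unname(tt$statistic),
                p_value = tt$p.value, pairs = pairs))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(
    group1 = vapply(nm, `[`, character(1), 1L),
    group2 = vapply(nm, `[`, character(1), 2L),
    diff = tk[, "diff"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha, row.names = NULL)
  list(method = "anova_tukey", statistic = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1], pairs = pairs)
}

#' Read a plate of assay measurements
#'
#' Tab-separated with header `donor`, `condition`, `et_ratio`, `replicate`,
#' `value`.
#'
#' @param file path to the TSV.
#' @return `data.frame` of measurements.
#' @export
readPlate <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("donor", "condition", "et_ratio", "replicate", "value")
  if (!all(need %in% names(df)))
    stop("plate table needs columns donor, condition, et_ratio, replicate, value",
         call. = FALSE)
  if (any(!is.finite(df$value)) || any(df$value < 0))
    stop("plate values must be finite and non-negative", call. = FALSE)
  df[need]
}
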