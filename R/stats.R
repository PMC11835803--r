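#' Long-form entropy table
#'
#' The package's tidy exchange format for entropy results: one row per
#' (subject, group, state, measure, condition, electrode) with the entropy
#' `value` (NA marks undefined estimates). Constructed by the pipeline
#' runners; any data frame with these columns is accepted by the statistics
#' layer.
#'
#' @param df Data frame with columns `subject`, `group`, `state`, `measure`,
#'   `condition`, `electrode`, `value`.
#' @return The data frame, validated, with class `entropy_table`.
#' @export
entropy_table <- function(df) {
  need <- c("subject", "group", "state", "measure", "condition",
            "electrode", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- df[setdiff(need, "value")]
  if (anyDuplicated(key)) stop("duplicate key rows in entropy table")
  class(df) <- unique(c("entropy_table", class(df)))
  df
}

#' Average electrode values into scalp regions
#'
#' Per (subject, group, state, measure, condition), replaces electrode-level
#' values by the mean over each region's electrodes, skipping undefined (NA)
#' values. Electrodes outside every region are dropped.
#'
#' @param table An [entropy_table()] (electrode-level).
#' @param map Region map (named list of label vectors).
#' @return An `entropy_table` whose `electrode` column holds region names.
#' @export
region_average <- function(table, map = default_region_map()) {
  present <- lapply(map, intersect, unique(table$electrode))
  empty <- names(present)[vapply(present, length, 1L) == 0L]
  if (length(empty))
    stop("region(s) with no measured electrode: ",
         paste(empty, collapse = ", "))
  region <- region_of(table$electrode, map)
  keep <- !is.na(region)
  df <- table[keep, , drop = FALSE]
  df$electrode <- region[keep]
  out <- stats::aggregate(
    value ~ subject + group + state + measure + condition + electrode,
    data = df, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  out$value[is.nan(out$value)] <- NA_real_
  entropy_table(out)
}

stat_result <- function(effect, statistic, df1, df2 = NA_real_, p,
                        effect_size = NA_real_, es_type = NA_character_,
                        p_adjusted = FALSE) {
  data.frame(effect = effect, statistic = statistic, df1 = df1, df2 = df2,
             p = p, effect_size = effect_size, es_type = es_type,
             p_adjusted = p_adjusted)
}

as_group_list <- function(values, groups = NULL) {
  gl <- if (is.list(values)) values else split(values, groups)
  if (is.null(names(gl))) names(gl) <- paste0("g", seq_along(gl))
  gl
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group mean (mean-centered Levene statistic). When the deviations carry no
#' variance at all (e.g. every group is a two-point symmetric set), the
#' statistic is defined as 0 with p = 1.
#'
#' @param values Numeric vector of observations, or a list of per-group
#'   vectors (then `groups` is ignored).
#' @param groups Grouping vector parallel to `values`.
#' @return A one-row `data.frame` (statistic, df, p).
#' @export
levene_check <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  if (length(gl) < 2L || any(lengths(gl) < 2L))
    stop("need at least 2 groups with at least 2 observations each")
  dev <- lapply(gl, function(v) abs(v - mean(v)))
  y <- unlist(dev, use.names = FALSE)
  g <- factor(rep(names(dev), lengths(dev)))
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2))
    return(stat_result("levene", 0, length(gl) - 1L,
                       length(y) - length(gl), 1))
  fit <- stats::anova(stats::lm(y ~ g))
  stat_result("levene", fit$`F value`[1], fit$Df[1], fit$Df[2],
              fit$`Pr(>F)`[1])
}

#' One-way between-subjects ANOVA with partial eta squared
#'
#' @param values Numeric vector, or list of per-group vectors.
#' @param groups Grouping vector parallel to `values`.
#' @return A one-row `data.frame` with F, degrees of freedom, p and
#'   `effect_size` = partial eta squared (SS_between / (SS_between +
#'   SS_within)).
#' @export
one_way_anova <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  if (length(gl) < 2L || any(lengths(gl) < 2L))
    stop("need at least 2 groups with at least 2 observations each")
  y <- unlist(gl, use.names = FALSE)
  if (stats::var(y) == 0)
    stop("degenerate input: all observations identical")
  g <- factor(rep(seq_along(gl), lengths(gl)))
  fit <- stats::anova(stats::lm(y ~ g))
  ss_b <- fit$`Sum Sq`[1]; ss_w <- fit$`Sum Sq`[2]
  stat_result("group", fit$`F value`[1], fit$Df[1], fit$Df[2],
              fit$`Pr(>F)`[1], effect_size = ss_b / (ss_b + ss_w),
              es_type = "eta2p")
}

#' Cohen's d with pooled SD
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled`, pooling the
#' two group variances with their degrees of freedom (handles unequal n).
#'
#' @param x,y Numeric vectors.
#' @return Scalar d.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Bonferroni-adjusted pairwise t-tests
#'
#' Two-sided pooled-variance two-sample t-tests for every group pair, with
#' p-values multiplied by the number of pairs (capped at 1) and Cohen's d
#' (pooled SD) as the effect size.
#'
#' @param values Numeric vector, or list of per-group vectors.
#' @param groups Grouping vector parallel to `values`.
#' @return Data frame, one row per pair; `effect` is `"A vs B"`.
#' @export
bonferroni_pairwise <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  if (is.null(names(gl))) names(gl) <- seq_along(gl)
  pairs <- utils::combn(names(gl), 2L, simplify = FALSE)
  k <- length(pairs)
  out <- lapply(pairs, function(pr) {
    tt <- stats::t.test(gl[[pr[1]]], gl[[pr[2]]], var.equal = TRUE)
    stat_result(paste(pr[1], "vs", pr[2]), unname(tt$statistic),
                unname(tt$parameter), p = min(1, tt$p.value * k),
                effect_size = cohens_d(gl[[pr[1]]], gl[[pr[2]]]),
                es_type = "cohens_d", p_adjusted = TRUE)
  })
  do.call(rbind, out)
}

#' Split-plot (mixed-design) two-way ANOVA
#'
#' Between-subjects factor `group`, within-subjects factor `condition`
#' (complete, two measurements per subject), split-plot error strata: the
#' group effect is tested against between-subject variation, condition and
#' group x condition against the subject-by-condition residual. Partial eta
#' squared is reported per effect against its own error stratum. With only
#' two within-subject levels no sphericity correction is needed.
#'
#' @param data Data frame with columns `subject`, `group`, `condition`, and
#'   the response named by `response`.
#' @param response Name of the response column.
#' @return Data frame with one row per effect (`group`, `condition`,
#'   `group:condition`).
#' @export
mixed_two_way_anova <- function(data, response = "value") {
  need <- c("subject", "group", "condition", response)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- table(data$subject, data$condition)
  if (any(tab != 1L))
    stop("every subject needs exactly one measurement per condition")
  if (length(unique(data$group)) < 2L) stop("need at least 2 groups")
  d <- data.frame(y = data[[response]],
                  subject = factor(data$subject),
                  group = factor(data$group),
                  condition = factor(data$condition))
  fit <- stats::aov(y ~ group * condition + Error(subject), data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  pick <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    er <- which(trimws(rownames(tab)) == "Residuals")
    ss <- tab$`Sum Sq`[i]; ss_e <- tab$`Sum Sq`[er]
    stat_result(name, tab$`F value`[i], tab$Df[i], tab$Df[er],
                tab$`Pr(>F)`[i], effect_size = ss / (ss + ss_e),
                es_type = "eta2p")
  }
  rbind(pick(between, "group"),
        pick(within, "condition"),
        pick(within, "group:condition"))
}

#' Pearson correlation between entropy and behavior
#'
#' Joins an [entropy_table()] with per-condition behavioral records by
#' subject and condition, then computes the Pearson correlation (with the
#' two-sided t-test p-value) between entropy and `performance`, separately
#' for each (group, measure, condition, electrode) cell when
#' `scope = "electrode"`, or pooling electrodes by their mean per subject
#' when `scope = "summary"` (the headline per-group values). Undefined
#' entropy values are dropped pairwise; cells with fewer than 4 complete
#' pairs or zero variance yield `NA` with a flag.
#'
#' @param table An [entropy_table()] (task-state band entropy rows).
#' @param behavior Data frame with columns `subject`, `group`, `condition`,
#'   `performance` (see [generate_subject()] for the synthetic source).
#' @param scope `"summary"` or `"electrode"`.
#' @return Data frame with columns `group`, `measure`, `condition`
#'   (and `electrode` for electrode scope), `r`, `n`, `p`, `flag`.
#' @export
entropy_behavior_correlation <- function(table, behavior,
                                         scope = c("summary", "electrode")) {
  scope <- match.arg(scope)
  if (scope == "summary") {
    agg <- stats::aggregate(
      value ~ subject + group + measure + condition, data = table,
      FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
    agg$electrode <- "all"
  } else {
    agg <- table[, c("subject", "group", "measure", "condition",
                     "electrode", "value")]
  }
  agg$value[is.nan(agg$value)] <- NA_real_
  m <- merge(agg, behavior[, c("subject", "condition", "performance")],
             by = c("subject", "condition"))
  cells <- unique(m[, c("group", "measure", "condition", "electrode")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sub <- merge(m, cl)
    ok <- stats::complete.cases(sub$value, sub$performance)
    x <- sub$value[ok]; y <- sub$performance[ok]
    res <- data.frame(cl, r = NA_real_, n = length(x), p = NA_real_,
                      flag = "", row.names = NULL)
    if (length(x) < 4L) { res$flag <- "too_few"; return(res) }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      res$flag <- "zero_variance"; return(res)
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    res$r <- unname(ct$estimate); res$p <- ct$p.value
    res
  })
  out <- do.call(rbind, out)
  if (scope == "summary") out$electrode <- NULL
  out
}
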