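# Per-condition aggregation and the cohort statistics: one-way ANOVA with
# post hoc Tukey HSD, significance stars at 0.05 / 0.01 / 0.001 / 0.0001.

#' Per-condition fractions and summaries
#'
#' For each condition, the pooled fraction of invaginated and wrinkled
#' nuclei is computed over all records, and additionally the mean +- SD of
#' the per-replicate fractions (the two coincide when replicates are
#' equal-sized and identical). Numeric measurement columns are summarised
#' as mean +- SD.
#'
#' @param records data.frame with at least \code{condition} and
#'   \code{replicate} columns, logical \code{invaginated} / \code{wrinkled}
#'   columns when present, and any numeric measurement columns.
#' @return data.frame, one row per condition, with columns \code{condition},
#'   \code{n}, \code{fractionInvaginated} (pooled),
#'   \code{fractionInvaginatedRepMean}, \code{fractionInvaginatedRepSd},
#'   the analogous wrinkle columns, and \code{<var>Mean} / \code{<var>Sd}
#'   for each numeric measurement.
#' @export
conditionFractions <- function(records) {
  .assert(is.data.frame(records) && nrow(records) > 0, "no records")
  .assert(all(c("condition", "replicate") %in% names(records)),
          "records must carry condition and replicate labels")
  .assert(!anyNA(records$condition) && !anyNA(records$replicate),
          "missing condition/replicate labels")
  numCols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                     c("replicate", "label"))
  out <- lapply(split(records, records$condition), function(g) {
    row <- data.frame(condition = g$condition[1], n = nrow(g))
    for (fld in c("invaginated", "wrinkled")) {
      if (!fld %in% names(g)) next
      v <- as.logical(g[[fld]])
      perRep <- tapply(v, g$replicate, mean)
      nice <- paste0("fraction", toupper(substring(fld, 1, 1)), substring(fld, 2))
      row[[nice]] <- mean(v)
      row[[paste0(nice, "RepMean")]] <- mean(perRep)
      row[[paste0(nice, "RepSd")]] <- if (length(perRep) > 1) sd(perRep) else NA_real_
    }
    for (v in numCols) {
      row[[paste0(v, "Mean")]] <- mean(g[[v]])
      row[[paste0(v, "Sd")]] <- sd(g[[v]])
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Significance stars at the conventional thresholds
#'
#' @param p numeric p-value(s).
#' @return character: \code{"****"} p < 0.0001, \code{"***"} p < 0.001,
#'   \code{"**"} p < 0.01, \code{"*"} p < 0.05, \code{"ns"} otherwise.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' One-way ANOVA with post hoc Tukey HSD
#'
#' Wraps \code{stats::aov} and \code{stats::TukeyHSD}. The degenerate case
#' of all groups identical and constant (zero between- and within-group
#' variance) is reported as F = 0, p = 1, all pairwise p = 1.
#'
#' @param values numeric vector of per-nucleus (or per-cell) measurements.
#' @param groups factor/character of condition labels, same length.
#' @param alpha family-wise level for the Tukey intervals (default 0.05).
#' @return list with \code{F}, \code{p}, \code{df} (c(between, within)),
#'   \code{tukey} (data.frame: pair, diff, lwr, upr, pAdj, stars) and
#'   \code{stars} for the omnibus p.
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  .assert(nlevels(groups) >= 2, "need at least 2 groups")
  ns <- table(groups)
  .assert(all(ns >= 2), "every group needs n >= 2")
  .assert(length(values) == length(groups), "values/groups length mismatch")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an["groups", "F value"]; pv <- an["groups", "Pr(>F)"]
  dfB <- an["groups", "Df"]; dfW <- an["Residuals", "Df"]
  ssB <- an["groups", "Sum Sq"]; ssW <- an["Residuals", "Sum Sq"]
  # degenerate cases, handled relative to the data scale (aov's own F is
  # numerical noise when both sums of squares underflow)
  scale2 <- max(mean(values)^2, 1) * length(values) * 1e-12
  allConstant <- ssB <= scale2 && ssW <= scale2
  if (allConstant) { Fv <- 0; pv <- 1 }
  else if (ssW <= scale2) { Fv <- Inf; pv <- 0 }      # perfect separation
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tk <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   pAdj = tk[, "p adj"], row.names = NULL)
  if (allConstant) {
    tk$pAdj <- 1
    tk$diff <- 0
  }
  tk$stars <- significanceStars(tk$pAdj)
  list(F = unname(Fv), p = unname(pv), df = c(between = dfB, within = dfW),
       tukey = tk, stars = significanceStars(pv))
}
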