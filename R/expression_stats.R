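#' Efficiency-corrected relative qPCR quantification
#'
#' Computes per-sample relative expression of a target gene against a
#' reference gene, calibrated to a control group, using the
#' efficiency-corrected ratio method:
#' \deqn{ratio = E_t^{\bar{Ct}_{cal,t} - Ct_{s,t}} / E_{ref}^{\bar{Ct}_{cal,ref} - Ct_{s,ref}}}
#' where the calibrator Ct is the mean over the calibrator group and `E` is
#' the per-gene amplification factor from a dilution standard curve
#' (typically 1.8-2.2, i.e. 90-110% efficiency). Technical replicates are
#' averaged at the Ct level first. A `"ddct"` mode forces `E = 2` for both
#' genes (classical delta-delta-Ct).
#'
#' By construction the geometric mean ratio of the calibrator group is 1.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct` (Ct > 0).
#' @param target_gene,ref_gene Gene names present for every sample.
#' @param calibrator_group Group label used as calibrator (e.g. the saline
#'   control).
#' @param efficiencies Named numeric vector of per-gene `E` values in
#'   (1, 3), or a single value recycled; ignored under `method = "ddct"`.
#' @param method `"pfaffl"` (default) or `"ddct"`.
#' @return Data frame `sample_id`, `group`, `gene`, `ratio`.
#' @export
relative_expression <- function(ct, target_gene, ref_gene, calibrator_group,
                                efficiencies = 2, method = c("pfaffl", "ddct")) {
  method <- match.arg(method)
  need <- c("sample_id", "group", "gene", "ct")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!calibrator_group %in% ct$group) {
    stop("calibrator group '", calibrator_group, "' absent from Ct table")
  }
  eff_of <- function(gene) {
    if (method == "ddct") return(2)
    e <- if (length(efficiencies) == 1L && is.null(names(efficiencies))) {
      efficiencies
    } else {
      if (!gene %in% names(efficiencies)) {
        stop("no amplification efficiency given for gene '", gene, "'")
      }
      efficiencies[[gene]]
    }
    if (!is.finite(e) || e <= 1 || e >= 3) {
      stop("amplification factor for '", gene, "' must be in (1, 3), got ", e)
    }
    e
  }
  # average technical replicates at the Ct level
  avg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct, FUN = mean)
  per_gene <- function(gene) {
    sub <- avg[avg$gene == gene, ]
    if (!nrow(sub)) stop("gene '", gene, "' absent from Ct table")
    sub
  }
  tg <- per_gene(target_gene); rg <- per_gene(ref_gene)
  samples <- unique(avg$sample_id)
  missing_ref <- setdiff(samples, rg$sample_id)
  if (length(missing_ref)) {
    stop("missing reference-gene rows for sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  tg <- tg[tg$sample_id %in% samples, ]
  cal_t <- mean(tg$ct[tg$group == calibrator_group])
  cal_r <- mean(rg$ct[rg$group == calibrator_group])
  if (is.nan(cal_t) || is.nan(cal_r)) {
    stop("calibrator group has no Ct values for both genes")
  }
  e_t <- eff_of(target_gene); e_r <- eff_of(ref_gene)
  idx <- match(tg$sample_id, rg$sample_id)
  ratio <- e_t^(cal_t - tg$ct) / e_r^(cal_r - rg$ct[idx])
  data.frame(sample_id = tg$sample_id, group = tg$group,
             gene = target_gene, ratio = ratio, stringsAsFactors = FALSE)
}

#' ANOVA assumption checks with transform recommendation
#'
#' Normality of residuals (Shapiro-Wilk, after centering on group means)
#' and homoscedasticity (Levene's test, mean-centered). When either check
#' fails at `alpha` the function recommends a log10 transform and, if all
#' values are positive, re-runs both checks on the transformed data.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; at least 3 values per group.
#' @param alpha Check threshold, default 0.05.
#' @return List with `shapiro_p`, `levene_p`, `pass`,
#'   `transform_recommended`, `after_log` (the same checks on log10 data,
#'   or `NULL`), and `flagged` (character notes, e.g. constant groups).
#' @export
assumption_checks <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  ns <- table(groups)
  if (any(ns < 3L)) stop("assumption checks need >= 3 values per group")
  flagged <- character(0)
  const <- tapply(values, groups, function(v) stats::var(v) == 0)
  if (any(const)) {
    flagged <- c(flagged, paste0("constant group: ",
                                 paste(names(const)[const], collapse = ", ")))
  }
  resid <- values - stats::ave(values, groups)
  shapiro_p <- if (stats::var(resid) == 0) {
    flagged <- c(flagged, "normality undefined (zero residual variance)")
    NA_real_
  } else {
    stats::shapiro.test(resid)$p.value
  }
  levene_p <- car::leveneTest(values ~ groups, center = mean)[1, "Pr(>F)"]
  pass <- isTRUE(shapiro_p >= alpha) && isTRUE(levene_p >= alpha)
  out <- list(shapiro_p = shapiro_p, levene_p = levene_p, pass = pass,
              transform_recommended = !pass, after_log = NULL,
              flagged = flagged)
  if (!pass && all(values > 0)) {
    lg <- log10(values)
    lresid <- lg - stats::ave(lg, groups)
    out$after_log <- list(
      shapiro_p = if (stats::var(lresid) == 0) NA_real_ else
        stats::shapiro.test(lresid)$p.value,
      levene_p = car::leveneTest(lg ~ groups, center = mean)[1, "Pr(>F)"])
    out$after_log$pass <- isTRUE(out$after_log$shapiro_p >= alpha) &&
      isTRUE(out$after_log$levene_p >= alpha)
  }
  out
}

#' One-way (univariate) ANOVA
#'
#' Classical between/within sum-of-squares decomposition via `stats::aov`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; at least 2 groups with n >= 2.
#' @return List of class `anova_result`: `df_between` (k-1), `df_within`
#'   (N-k), `F`, `p`, `ms_within`, `ss_between`, `ss_within`,
#'   `group_means`, `group_n`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  k <- nlevels(droplevels(groups))
  if (k < 2L) stop("one_way_anova requires >= 2 groups")
  if (any(table(droplevels(groups)) < 2L)) {
    stop("one_way_anova requires n >= 2 per group")
  }
  if (stats::var(values) == 0) stop("degenerate data: zero total variance")
  groups <- droplevels(groups)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  structure(list(df_between = tab$Df[1], df_within = tab$Df[2],
                 F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                 ms_within = tab$`Mean Sq`[2],
                 ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
                 group_means = tapply(values, groups, mean),
                 group_n = as.integer(table(groups))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Student-Newman-Keuls post-hoc test with compact letters
#'
#' Stepwise studentized-range procedure on ordered group means: the range
#' spanning `r` ordered means is tested against `qtukey(1 - alpha, r, df)`,
#' working from the full range inward; any range found non-significant
#' shields all ranges inside it from further testing. The within-group mean
#' square and df come from the one-way ANOVA on the same data. Standard
#' errors use the Tukey-Kramer form `sqrt(ms_w/2 (1/ni + 1/nj))` so
#' moderately unbalanced groups are handled.
#'
#' The compact letter display assigns letters over descending means; two
#' groups share a letter iff the SNK procedure does not separate them.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param alpha Significance level, default 0.05.
#' @return List of class `snk_grouping`: `groups` (data frame `group`, `n`,
#'   `mean`, `letters`, sorted by descending mean), `different` (logical
#'   matrix of separated pairs), `anova` (the underlying `anova_result`).
#' @export
snk_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("snk_posthoc requires >= 2 groups")
  aov_res <- one_way_anova(values, groups)
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; n <- as.integer(ns[ord]); labs <- names(means)[ord]
  df <- aov_res$df_within; msw <- aov_res$ms_within
  # decision[i,j] over ordered means: TRUE = declared different
  different <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  shielded <- matrix(FALSE, k, k)  # inside an accepted range
  for (r in k:2) {
    for (lo in seq_len(k - r + 1L)) {
      hi <- lo + r - 1L
      if (shielded[lo, hi]) next
      se <- sqrt(msw / 2 * (1 / n[lo] + 1 / n[hi]))
      q_obs <- if (se == 0) Inf else (m[lo] - m[hi]) / se
      crit <- stats::qtukey(1 - alpha, nmeans = r, df = df)
      if (q_obs > crit) {
        different[lo, hi] <- different[hi, lo] <- TRUE
      } else {
        # accepted: shield (and accept) every pair within
        for (a in lo:hi) for (b in lo:hi) shielded[a, b] <- TRUE
      }
    }
  }
  # compact letters: maximal runs of ordered groups with no separated pair
  reach <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(different[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    reach[i] <- j
  }
  runs <- unique(lapply(seq_len(k), function(i) c(i, reach[i])))
  runs <- Filter(function(rn) {
    !any(vapply(runs, function(o) o[1] <= rn[1] && o[2] >= rn[2] &&
                  !identical(o, rn), logical(1)))
  }, runs)
  runs <- runs[order(vapply(runs, `[`, 0, 1))]
  letters_vec <- rep("", k)
  for (li in seq_along(runs)) {
    span <- runs[[li]][1]:runs[[li]][2]
    letters_vec[span] <- paste0(letters_vec[span], letters[li])
  }
  structure(list(groups = data.frame(group = labs, n = n, mean = unname(m),
                                     letters = letters_vec,
                                     stringsAsFactors = FALSE),
                 different = different, alpha = alpha, anova = aov_res),
            class = "snk_grouping")
}

#' @export
print.snk_grouping <- function(x, ...) {
  cat(sprintf("SNK grouping at alpha = %g (groups sharing a letter do not differ):\n",
              x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
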