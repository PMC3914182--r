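#' Mann-Whitney U test between set members and background
#'
#' Two-sided rank-sum comparison of a gene set's scores against a
#' background distribution — the statistic behind sub-network enrichment
#' scoring. The p-value is exact (full enumeration of labelings) when
#' `n1 + n2 <= 12` and the data carry no ties; otherwise a tie-corrected
#' normal approximation with continuity correction is used. `U` is reported
#' for the member group.
#'
#' @param member_scores,background_scores Nonempty numeric vectors.
#' @return List with `U`, `p`, `n1`, `n2`, `exact` (logical).
#' @examples
#' mwu_test(c(4, 5, 6), c(1, 2, 3))  # U = 9, p = 0.1
#' @export
mwu_test <- function(member_scores, background_scores) {
  if (!length(member_scores) || !length(background_scores)) {
    stop("mwu_test: both groups must be nonempty")
  }
  stopifnot(all(is.finite(member_scores)), all(is.finite(background_scores)))
  n1 <- length(member_scores); n2 <- length(background_scores)
  pooled <- c(member_scores, background_scores)
  if (length(unique(pooled)) == 1L) {
    return(list(U = n1 * n2 / 2, p = 1, n1 = n1, n2 = n2, exact = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  w <- suppressWarnings(stats::wilcox.test(member_scores, background_scores,
                                           exact = exact, correct = TRUE))
  p <- w$p.value
  if (is.nan(p)) p <- 1  # degenerate normal approximation (zero variance)
  list(U = unname(w$statistic), p = min(p, 1), n1 = n1, n2 = n2,
       exact = exact)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of observing at least `k` targets in
#' a set of size `set_size` when `n_targets` of `universe_size` genes are
#' targets, under sampling without replacement. The companion
#' over-representation score for binary membership universes.
#'
#' @param k_overlap Observed overlap count.
#' @param set_size Gene-set size (within the universe).
#' @param n_targets Number of target genes in the universe.
#' @param universe_size Universe size.
#' @return Upper-tail p-value.
#' @examples
#' hypergeom_test(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_test <- function(k_overlap, set_size, n_targets, universe_size) {
  stopifnot(length(k_overlap) == 1L, length(set_size) == 1L,
            length(n_targets) == 1L, length(universe_size) == 1L)
  if (k_overlap < 0 || set_size < 0 || n_targets < 0 ||
      k_overlap > min(set_size, n_targets) ||
      set_size > universe_size || n_targets > universe_size) {
    stop("hypergeom_test: inconsistent counts")
  }
  stats::phyper(k_overlap - 1, n_targets, universe_size - n_targets,
                set_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (capped at 1). Offered alongside
#' raw p-value filtering so multiple gene sets can be screened with FDR
#' control.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id <TAB> description <TAB>
#' member...`. Parsing is delegated to `fgsea::gmtPathways`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (member ids per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (!length(readLines(path, warn = FALSE))) return(stats::setNames(list(), character(0)))
  fgsea::gmtPathways(path)
}

#' Read a gene universe TSV
#'
#' Columns `gene_id`, `score`. The score is typically binary target
#' membership (0/1) from a UTR scan, or a continuous per-gene statistic.
#'
#' @param path Path to the TSV.
#' @return Data frame with `gene_id`, `score`.
#' @export
read_universe <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score") %in% names(df))) {
    stop("universe table must have columns gene_id, score")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in universe")
  stopifnot(all(is.finite(df$score)))
  df[, c("gene_id", "score")]
}

#' Sub-network enrichment analysis over a gene-set collection
#'
#' Scores each gene set against the rest of the universe with a two-sided
#' Mann-Whitney U test on the per-gene scores (background = universe minus
#' set members, the standard competitive construction), plus a
#' hypergeometric over-representation p-value when scores are binary.
#' Gene id matching is case-insensitive after trimming. Sets with fewer
#' than `min_set_size` members in the universe are excluded (and reported).
#' Results are sorted by the U-test p-value ascending, ties broken by set
#' id; the `significant` flag uses the raw U-test p-value against `alpha`,
#' with BH-adjusted values reported alongside.
#'
#' @param universe Data frame with `gene_id`, `score` (see
#'   [read_universe()]).
#' @param sets Named list of member-id character vectors (see
#'   [read_gmt()]).
#' @param alpha Significance threshold on the raw `p_mwu`, default 0.05.
#' @param min_set_size Minimum members-in-universe, default 3.
#' @return Object of class `snea_result`: list with `results` (data frame:
#'   `set_id`, `n1`, `n2`, `U`, `p_mwu`, `p_hyper`, `q`, `significant`) and
#'   `excluded` (set ids below the size threshold).
#' @export
snea <- function(universe, sets, alpha = 0.05, min_set_size = 3L) {
  stopifnot(is.data.frame(universe),
            all(c("gene_id", "score") %in% names(universe)))
  if (!nrow(universe)) stop("snea: empty universe")
  key <- tolower(trimws(universe$gene_id))
  score <- universe$score
  binary <- all(score %in% c(0, 1))
  n_targets <- if (binary) sum(score == 1) else NA_integer_
  rows <- list(); excluded <- character(0)
  for (sid in names(sets)) {
    memb <- unique(tolower(trimws(sets[[sid]])))
    inu <- key %in% memb
    n1 <- sum(inu)
    if (n1 < min_set_size) {
      excluded <- c(excluded, sid)
      next
    }
    mw <- mwu_test(score[inu], score[!inu])
    ph <- if (binary) {
      hypergeom_test(sum(score[inu] == 1), n1, n_targets, length(score))
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = sid, n1 = n1, n2 = mw$n2, U = mw$U, p_mwu = mw$p,
      p_hyper = ph, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("snea: no set has >= ", min_set_size, " members in the universe")
  }
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p_mwu)
  res$significant <- res$p_mwu < alpha
  res <- res[order(res$p_mwu, res$set_id), ]
  rownames(res) <- NULL
  structure(list(results = res, excluded = excluded, alpha = alpha,
                 min_set_size = min_set_size, binary_scores = binary),
            class = "snea_result")
}

#' @export
print.snea_result <- function(x, ...) {
  cat(sprintf("<snea_result> %d sets tested (%d excluded below size %d), %d significant at alpha = %g\n",
              nrow(x$results), length(x$excluded), x$min_set_size,
              sum(x$results$significant), x$alpha))
  print(utils::head(x$results, 10))
  invisible(x)
}
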