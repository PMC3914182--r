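#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment of two nucleotide sequences under a simple
#' match/mismatch/linear-gap scheme. This is the pairwise core of the
#' progressive multiple aligner used for pre-miRNA hairpin families
#' (70-90 nt, up to a few dozen species), where a heavyweight external
#' aligner adds nothing.
#'
#' Traceback ties are broken deterministically: diagonal first, then a gap
#' in the second sequence, then a gap in the first.
#'
#' @param a,b `nuc_sequence` objects or bare strings; both nonempty.
#' @param match,mismatch,gap Finite scores (defaults +1, -1, -2).
#' @return A list with `a_aln`, `b_aln` (aligned strings with `-` gaps) and
#'   `score`.
#' @examples
#' pairwise_align("GATTACA", "GCATGCT", match = 1, mismatch = -1, gap = -1)
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as_nuc(a, "a"); b <- as_nuc(b, "b")
  if (!nchar(a$residues) || !nchar(b$residues)) {
    stop("pairwise_align requires nonempty sequences")
  }
  stopifnot(is.finite(match), is.finite(mismatch), is.finite(gap))
  x <- strsplit(a$residues, "")[[1]]
  y <- strsplit(b$residues, "")[[1]]
  m <- length(x); n <- length(y)
  F <- matrix(0, m + 1L, n + 1L)
  F[, 1L] <- gap * (0:m)
  F[1L, ] <- gap * (0:n)
  # pointers: 1 = diag, 2 = up (consume x, gap in y), 3 = left (gap in x)
  P <- matrix(0L, m + 1L, n + 1L)
  P[2:(m + 1L), 1L] <- 2L
  P[1L, 2:(n + 1L)] <- 3L
  for (i in seq_len(m)) {
    sub <- ifelse(y == x[i], match, mismatch)
    for (j in seq_len(n)) {
      d <- F[i, j] + sub[j]
      u <- F[i, j + 1L] + gap
      l <- F[i + 1L, j] + gap
      best <- max(d, u, l)
      F[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  # traceback
  ai <- character(0); bi <- character(0)
  i <- m + 1L; j <- n + 1L
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ai <- c(x[i - 1L], ai); bi <- c(y[j - 1L], bi); i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ai <- c(x[i - 1L], ai); bi <- c("-", bi); i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(y[j - 1L], bi); j <- j - 1L
    }
  }
  list(a_aln = paste(ai, collapse = ""), b_aln = paste(bi, collapse = ""),
       score = F[m + 1L, n + 1L])
}

# internal: k-mer count vector distance between two residue strings
kmer_distance <- function(s1, s2, k = 3L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  }
  t1 <- km(s1); t2 <- km(s2)
  keys <- union(names(t1), names(t2))
  v1 <- as.numeric(t1[keys]); v1[is.na(v1)] <- 0
  v2 <- as.numeric(t2[keys]); v2[is.na(v2)] <- 0
  sum(abs(v1 - v2))
}

#' Multiple sequence alignment container
#'
#' @param ids Character vector of row ids (unique).
#' @param rows Character vector of aligned rows (residues plus `-`), all the
#'   same length; degapping each row must reproduce the input sequence.
#' @return An object of class `msa`.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("all msa rows must have equal length")
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 ncol = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns\n", length(x$ids), x$ncol))
  for (i in seq_along(x$ids)) cat(sprintf(" %-15s %s\n", x$ids[i], x$rows[i]))
  invisible(x)
}

#' Degap msa rows
#' @param x An `msa`.
#' @return Named character vector of ungapped row sequences.
#' @export
degap <- function(x) {
  stopifnot(inherits(x, "msa"))
  stats::setNames(gsub("-", "", x$rows, fixed = TRUE), x$ids)
}

# internal: merge a center-vs-new pairwise alignment into a growing MSA whose
# first row is the (gapped) center. "Once a gap, always a gap".
merge_into_msa <- function(rows, center_aln, new_aln) {
  mcols <- strsplit(rows, "")
  pc <- strsplit(center_aln, "")[[1]]
  pn <- strsplit(new_aln, "")[[1]]
  nr <- length(rows)
  ncol_msa <- length(mcols[[1]])
  out <- vector("list", nr + 1L)
  for (r in seq_len(nr + 1L)) out[[r]] <- character(0)
  i <- 1L; j <- 1L
  center_msa <- mcols[[1]]
  while (i <= ncol_msa || j <= length(pc)) {
    if (i <= ncol_msa && center_msa[i] == "-") {
      for (r in seq_len(nr)) out[[r]] <- c(out[[r]], mcols[[r]][i])
      out[[nr + 1L]] <- c(out[[nr + 1L]], "-")
      i <- i + 1L
    } else if (j <= length(pc) && pc[j] == "-") {
      for (r in seq_len(nr)) out[[r]] <- c(out[[r]], "-")
      out[[nr + 1L]] <- c(out[[nr + 1L]], pn[j])
      j <- j + 1L
    } else {
      for (r in seq_len(nr)) out[[r]] <- c(out[[r]], mcols[[r]][i])
      out[[nr + 1L]] <- c(out[[nr + 1L]], pn[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  vapply(out, paste, "", collapse = "")
}

#' Progressive multiple alignment of an ortholog family
#'
#' Center-star progressive alignment: the center sequence is the one with
#' the smallest summed k-mer distance to all others; the remaining
#' sequences are merged in order of increasing k-mer distance to the center
#' ("once a gap, always a gap"). Deterministic given input order.
#'
#' @param family A list of at least two `nuc_sequence` objects sharing an
#'   alphabet (e.g. the output of [read_fasta()]).
#' @param match,mismatch,gap Pairwise scoring parameters.
#' @return An [msa()] whose rows, in input order, degap to the inputs.
#' @export
progressive_msa <- function(family, match = 1, mismatch = -1, gap = -2) {
  if (length(family) < 2L) stop("progressive_msa requires at least 2 sequences")
  family <- lapply(family, as_nuc)
  alpha <- unique(vapply(family, function(s) s$alphabet, ""))
  if (length(alpha) != 1L) stop("all family members must share an alphabet")
  ids <- vapply(family, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("duplicate sequence ids in family")
  res <- vapply(family, function(s) s$residues, "")
  n <- length(res)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- kmer_distance(res[i], res[j])
  }
  center <- which.min(rowSums(D))
  others <- setdiff(seq_len(n), center)
  others <- others[order(D[center, others], others)]
  rows <- res[center]
  order_built <- center
  for (k in others) {
    aln <- pairwise_align(nuc_sequence("c", gsub("-", "", rows[1]), alpha),
                          family[[k]], match, mismatch, gap)
    # re-express the pairwise center against the current gapped center row
    rows <- merge_into_msa(rows, aln$a_aln, aln$b_aln)
    order_built <- c(order_built, k)
  }
  # restore input order
  perm <- match(seq_len(n), order_built)
  msa(ids, rows[perm])
}

#' Per-column conservation profile of an alignment
#'
#' The default column score is the modal-residue fraction: the count of the
#' most frequent non-gap residue divided by the number of non-gap residues,
#' a direct "conserved or not" reading of an alignment figure. An entropy
#' alternative (1 minus normalized Shannon entropy over non-gap residues) is
#' available. Columns with gap fraction above 0.5 are flagged; all-gap
#' columns get `NA` score and are excluded from region means.
#'
#' @param x An [msa()].
#' @param metric `"modal"` (default) or `"entropy"`.
#' @return A data frame of class `conservation_profile` with columns
#'   `column`, `score`, `gap_fraction`, `flagged`.
#' @export
conservation_profile <- function(x, metric = c("modal", "entropy")) {
  metric <- match.arg(metric)
  stopifnot(inherits(x, "msa"))
  chars <- do.call(rbind, strsplit(x$rows, ""))
  nr <- nrow(chars)
  score <- numeric(x$ncol); gapf <- numeric(x$ncol)
  for (j in seq_len(x$ncol)) {
    col <- chars[, j]
    gaps <- sum(col == "-")
    gapf[j] <- gaps / nr
    resid <- col[col != "-"]
    if (!length(resid)) {
      score[j] <- NA_real_
    } else if (metric == "modal") {
      score[j] <- max(table(resid)) / length(resid)
    } else {
      p <- table(resid) / length(resid)
      h <- -sum(p * log(p))
      score[j] <- 1 - h / log(4)
    }
  }
  out <- data.frame(column = seq_len(x$ncol), score = score,
                    gap_fraction = gapf,
                    flagged = gapf > 0.5 | is.na(score))
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Region annotation on a reference pre-miRNA
#'
#' Mature / star / loop coordinates, 1-based inclusive on the (ungapped)
#' reference sequence. Regions must not overlap and the mature arm must be
#' at least 18 nt (a biological lower bound for a processed miRNA).
#'
#' @param reference_id Id of the reference sequence the coordinates refer to.
#' @param mature,star,loop Integer pairs `c(start, end)`.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(reference_id, mature, star, loop) {
  regs <- list(mature = mature, star = star, loop = loop)
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (length(r) != 2L || any(r < 1L) || r[2] < r[1]) {
      stop("region '", nm, "' must be c(start, end) with 1 <= start <= end")
    }
  }
  if (mature[2] - mature[1] + 1L < 18L) stop("mature region must be >= 18 nt")
  spans <- lapply(regs, function(r) r[1]:r[2])
  if (length(unlist(spans)) != length(unique(unlist(spans)))) {
    stop("regions must be non-overlapping")
  }
  structure(list(reference_id = reference_id, regions = regs),
            class = "region_annotation")
}

#' Read a region annotation TSV
#'
#' Expected columns: `reference_id`, `region_name`, `start`, `end`
#' (1-based inclusive).
#'
#' @param path Path to the TSV.
#' @return A `region_annotation`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reference_id", "region_name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("region table must have columns: ", paste(need, collapse = ", "))
  }
  ref <- unique(df$reference_id)
  if (length(ref) != 1L) stop("region table must annotate a single reference")
  get <- function(nm) {
    r <- df[df$region_name == nm, ]
    if (nrow(r) != 1L) stop("region table must have exactly one '", nm, "' row")
    c(r$start, r$end)
  }
  region_annotation(ref, get("mature"), get("star"), get("loop"))
}

#' Per-region conservation of an aligned family
#'
#' Region coordinates are defined on one reference sequence and projected
#' through its aligned row onto alignment columns; the region score is the
#' arithmetic mean of the member-column scores (all-gap columns excluded).
#' Regions are also rank-ordered by mean score, most conserved first.
#'
#' @param x An [msa()] containing the annotation's reference row.
#' @param profile Output of [conservation_profile()] on `x` (computed if
#'   missing).
#' @param annot A [region_annotation()].
#' @return A data frame with `region`, `mean_score`, `n_columns` and `rank`,
#'   ordered mature, star, loop.
#' @export
region_conservation <- function(x, profile = NULL, annot) {
  stopifnot(inherits(x, "msa"), inherits(annot, "region_annotation"))
  if (is.null(profile)) profile <- conservation_profile(x)
  ridx <- match(annot$reference_id, x$ids)
  if (is.na(ridx)) stop("reference id '", annot$reference_id, "' not in msa")
  refrow <- strsplit(x$rows[ridx], "")[[1]]
  pos2col <- which(refrow != "-")
  reflen <- length(pos2col)
  means <- vapply(names(annot$regions), function(nm) {
    r <- annot$regions[[nm]]
    if (r[2] > reflen) stop("region '", nm, "' outside reference length ", reflen)
    cols <- pos2col[r[1]:r[2]]
    mean(profile$score[cols], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(region = names(means), mean_score = unname(means),
                    n_columns = vapply(annot$regions,
                                       function(r) r[2] - r[1] + 1L, 0L),
                    row.names = NULL)
  out$rank <- rank(-out$mean_score, ties.method = "min")
  out
}
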