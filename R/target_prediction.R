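#' Mature miRNA with a seed span
#'
#' Wraps a mature miRNA sequence (RNA) together with its seed span, the
#' 1-based positions whose reverse complement defines a target site
#' (default nucleotides 2-7, the canonical seed hexamer).
#'
#' @param id miRNA id.
#' @param sequence `nuc_sequence` (RNA), or a string / DNA sequence which is
#'   coerced to RNA.
#' @param seed_span Integer pair, default `c(2, 7)`.
#' @return An object of class `mature_mirna`.
#' @examples
#' mature_mirna("omy-miR-122", "UGGAGUGUGACAAUGGUGUUUGU")
#' @export
mature_mirna <- function(id, sequence, seed_span = c(2L, 7L)) {
  seq <- coerce_alphabet(as_nuc(sequence, id), "RNA")
  seq$id <- id
  n <- nchar(seq$residues)
  if (length(seed_span) != 2L || seed_span[1] < 1L || seed_span[2] > n ||
      seed_span[2] < seed_span[1]) {
    stop("seed_span must lie within the mature sequence (length ", n, ")")
  }
  structure(list(id = id, sequence = seq, seed_span = as.integer(seed_span)),
            class = "mature_mirna")
}

#' The bundled omy-miR-122 working sequence
#'
#' The mature omy-miR-122 proxy used throughout examples and defaults:
#' the DNA qPCR forward-primer sequence `TGGAGTGTGACAATGGTGTTTGT`, coerced
#' to RNA. It is a working proxy (primer sequences can carry extra 3'
#' bases), overridable wherever a `mature_mirna` is accepted; the seed
#' region (positions 2-7) is what every downstream operation uses.
#'
#' @return A [mature_mirna()].
#' @export
omy_mir122 <- function() {
  mature_mirna("omy-miR-122", "TGGAGTGTGACAATGGTGTTTGT")
}

#' The bundled 13-nt LNA miR-122 inhibitor sequence
#'
#' The antisense oligo `5' ATTGTCACACTCC 3'`, the DNA reverse complement of
#' mature miR-122 positions 2-14, chosen to cover the seed while remaining
#' indifferent to 3' isomiR variation.
#'
#' @return A DNA `nuc_sequence`.
#' @export
lna_122i <- function() {
  nuc_sequence("LNA-122i", "ATTGTCACACTCC", "DNA")
}

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' UTR-strand site string for a miRNA and site class
#'
#' Returns the DNA string that a 3'UTR (read 5'->3') must contain for a
#' perfect site of the given class:
#' \describe{
#'   \item{6mer}{reverse complement of mature positions 2-7}
#'   \item{7mer-m8}{pairing extended to position 8}
#'   \item{7mer-A1}{6mer plus an `A` opposite position 1 (appended 3')}
#'   \item{8mer}{both extensions}
#' }
#'
#' @param mirna A [mature_mirna()].
#' @param site_type One of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @return A DNA `nuc_sequence` holding the match string.
#' @examples
#' site_sequence(omy_mir122(), "6mer")  # CACTCC
#' @export
site_sequence <- function(mirna, site_type = "6mer") {
  stopifnot(inherits(mirna, "mature_mirna"))
  site_type <- match.arg(site_type, SITE_TYPES)
  s <- mirna$sequence$residues
  span <- mirna$seed_span
  m8 <- site_type %in% c("7mer-m8", "8mer")
  a1 <- site_type %in% c("7mer-A1", "8mer")
  hi <- if (m8) span[2] + 1L else span[2]
  if (hi > nchar(s)) stop("site span outside mature sequence")
  core <- substr(s, span[1], hi)
  match_str <- revcomp_chr(gsub("U", "T", core, fixed = TRUE), "DNA")
  if (a1) match_str <- paste0(match_str, "A")
  nuc_sequence(paste0(mirna$id, ":", site_type), match_str, "DNA")
}

# internal: all (possibly overlapping) 1-based start positions of fixed
# pattern in subject; N in the subject never matches
find_all <- function(pattern, subject) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Scan 3'UTRs for perfect seed-match sites
#'
#' Every occurrence of each requested site string is reported, including
#' overlapping ones; a UTR is called a target iff it carries at least one
#' site of any requested class. UTRs are auto-coerced to DNA; `N` never
#' matches any site position. Output order is deterministic: UTR input
#' order, then position, then site type.
#'
#' @param utrs A list of `nuc_sequence` (e.g. [read_fasta()] output) or a
#'   named character vector.
#' @param mirna A [mature_mirna()].
#' @param site_types Character vector from `"6mer"`, `"7mer-A1"`,
#'   `"7mer-m8"`, `"8mer"`; default `"6mer"` only (the canonical perfect
#'   seed match).
#' @return An object of class `target_set`: list with `scanned_ids`,
#'   `sites` (data frame `utr_id`, `start`, `site_type`, `matched_seq`) and
#'   `target_ids`.
#' @export
scan_utrs <- function(utrs, mirna, site_types = "6mer") {
  if (is.character(utrs)) {
    utrs <- Map(function(id, s) as_nuc(s, id), names(utrs), utrs)
  }
  if (!length(utrs)) stop("empty UTR set")
  if (!length(site_types)) stop("at least one site type must be requested")
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  utrs <- lapply(utrs, as_nuc)
  ids <- unname(vapply(utrs, function(s) s$id, ""))
  seqs <- unname(vapply(utrs, function(s) coerce_alphabet(s, "DNA")$residues, ""))
  pats <- vapply(site_types, function(st) site_sequence(mirna, st)$residues, "")
  recs <- vector("list", length(utrs))
  for (i in seq_along(seqs)) {
    rows <- list()
    for (k in seq_along(pats)) {
      st <- find_all(pats[[k]], seqs[[i]])
      if (length(st)) {
        rows[[length(rows) + 1L]] <- data.frame(
          utr_id = ids[i], start = st, site_type = site_types[k],
          matched_seq = pats[[k]], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      recs[[i]] <- df[order(df$start, match(df$site_type, SITE_TYPES)), ]
    }
  }
  sites <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(sites)) {
    sites <- data.frame(utr_id = character(0), start = integer(0),
                        site_type = character(0), matched_seq = character(0),
                        stringsAsFactors = FALSE)
  }
  rownames(sites) <- NULL
  structure(list(scanned_ids = ids, sites = sites,
                 target_ids = ids[ids %in% unique(sites$utr_id)],
                 site_types = site_types, mirna_id = mirna$id),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %d/%d UTRs carry >=1 %s site for %s (%d sites)\n",
              length(x$target_ids), length(x$scanned_ids),
              paste(x$site_types, collapse = "/"), x$mirna_id,
              nrow(x$sites)))
  invisible(x)
}

#' Read a two-column ortholog mapping table
#'
#' TSV with columns `source_id`, `ortholog_id`. One row per source id is
#' kept (first occurrence wins; duplicates are reported in a message).
#'
#' @param path Path to the TSV.
#' @return A data frame of class `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "ortholog_id") %in% names(df))) {
    stop("ortholog map must have columns source_id, ortholog_id")
  }
  ortholog_map(df$source_id, df$ortholog_id)
}

#' Build an ortholog map from vectors
#' @param source_id,ortholog_id Equal-length character vectors.
#' @return A data frame of class `ortholog_map`.
#' @export
ortholog_map <- function(source_id, ortholog_id) {
  stopifnot(length(source_id) == length(ortholog_id))
  dup <- duplicated(source_id)
  if (any(dup)) {
    message("ortholog map: dropping ", sum(dup),
            " duplicate source id row(s) (first occurrence wins)")
  }
  df <- data.frame(source_id = source_id[!dup],
                   ortholog_id = ortholog_id[!dup],
                   stringsAsFactors = FALSE)
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' Map predicted targets to orthologs
#'
#' Transfers target ids (e.g. trout UTR/gene ids) to ortholog ids (e.g.
#' human symbols) via a user-supplied table. Missing mappings are data, not
#' errors: unmapped ids are returned by name.
#'
#' @param targets A `target_set` or character vector of target ids.
#' @param map An [ortholog_map()].
#' @return List with `mapped` (data frame `source_id`, `ortholog_id`, in
#'   target order), `unmapped` (character) and `n_mapped`.
#' @export
map_orthologs <- function(targets, map) {
  ids <- if (inherits(targets, "target_set")) targets$target_ids else targets
  stopifnot(inherits(map, "ortholog_map"))
  idx <- match(ids, map$source_id)
  hit <- !is.na(idx)
  list(mapped = data.frame(source_id = ids[hit],
                           ortholog_id = map$ortholog_id[idx[hit]],
                           stringsAsFactors = FALSE),
       unmapped = ids[!hit],
       n_mapped = sum(hit))
}

#' Conserved-target overlap and percentage
#'
#' Fraction of predicted targets that appear in a reference list of
#' conserved targets (e.g. targets validated in another species), as
#' `100 * overlap / n_targets` with half-up rounding to the nearest whole
#' percent; the unrounded value is returned alongside.
#'
#' When `targets` is a single number it is taken as the denominator (the
#' predicted-target count) and `reference_list` as the ids of the overlap
#' itself — the bookkeeping used when only counts and the overlapping gene
#' names are known.
#'
#' @param targets A `target_set`, a character vector of predicted target
#'   ids, or a single count (denominator).
#' @param reference_list Character vector of reference conserved-target ids.
#' @return List with `overlap` (count), `n_targets`, `percent` (unrounded)
#'   and `percent_rounded`.
#' @examples
#' conserved_fraction(83, c("dditl4", "igf2", "parp3", "rtn3", "serpinh1",
#'                          "socs6", "ucp2a", "slc2a1", "adam10"))
#' @export
conserved_fraction <- function(targets, reference_list) {
  if (is.numeric(targets) && length(targets) == 1L) {
    n <- as.integer(targets)
    overlap <- length(unique(reference_list))
  } else {
    ids <- if (inherits(targets, "target_set")) targets$target_ids else targets
    n <- length(unique(ids))
    overlap <- length(intersect(tolower(trimws(ids)),
                                tolower(trimws(reference_list))))
  }
  if (n <= 0L) stop("conserved_fraction: empty target set (denominator 0)")
  pct <- 100 * overlap / n
  list(overlap = overlap, n_targets = n, percent = pct,
       percent_rounded = floor(pct + 0.5))
}
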