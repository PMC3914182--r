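#' An isomiR family sharing a 5' core
#'
#' Mature miRNA variants (isomiRs) typically share their 5' end — and hence
#' the seed — while differing at the 3' end. An inhibitor anchored in the
#' shared core inhibits every member regardless of 3' heterogeneity. The
#' declared core span must be identical across members.
#'
#' @param id Family id.
#' @param members List of [mature_mirna()] objects (or sequences coerced
#'   via `mature_mirna`).
#' @param core_span 1-based span `c(start, end)` over which all members are
#'   identical; default `c(1, L_min)` trimmed to the longest shared prefix.
#' @return Object of class `isomir_family`.
#' @export
isomir_family <- function(id, members, core_span = NULL) {
  stopifnot(length(members) >= 1L)
  members <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    if (inherits(m, "mature_mirna")) m else mature_mirna(paste0(id, "-", i), m)
  })
  res <- vapply(members, function(m) m$sequence$residues, "")
  lmin <- min(nchar(res))
  if (is.null(core_span)) {
    # longest shared prefix
    k <- 0L
    while (k < lmin && length(unique(substr(res, k + 1L, k + 1L))) == 1L) {
      k <- k + 1L
    }
    if (k == 0L) stop("members share no 5' prefix; specify core_span")
    core_span <- c(1L, k)
  }
  cores <- substr(res, core_span[1], core_span[2])
  if (any(nchar(res) < core_span[2])) {
    short <- vapply(members, function(m) m$id, "")[nchar(res) < core_span[2]]
    stop("core span exceeds member length: ", paste(short, collapse = ", "))
  }
  if (length(unique(cores)) != 1L) {
    bad <- vapply(members, function(m) m$id, "")[cores != cores[1]]
    stop("members differ inside the declared core span: ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, members = members,
                 core_span = as.integer(core_span)),
            class = "isomir_family")
}

#' The bundled omy-miR-122 isomiR stand-in family
#'
#' The mature working sequence plus synthetic 3'-truncated and 3'-extended
#' variants standing in for the sequenced trout isomiRs (whose exact 3'
#' ends are not published). All members share positions 1-20.
#'
#' @return An [isomir_family()].
#' @export
omy_mir122_family <- function() {
  base <- omy_mir122()$sequence$residues  # UGGAGUGUGACAAUGGUGUUUGU
  isomir_family("omy-miR-122", list(
    mature_mirna("omy-miR-122", base),
    mature_mirna("omy-miR-122-3p-trunc", substr(base, 1, nchar(base) - 2L)),
    mature_mirna("omy-miR-122-3p-ext", paste0(base, "UA"))
  ))
}

#' Design an antisense inhibitor for an isomiR family
#'
#' The oligo is the DNA reverse complement of mature positions
#' `[anchor_start, anchor_start + length - 1]`. Anchoring at position 2
#' (the seed start) makes the oligo complementary to the seed of every
#' family member while ignoring 3' isomiR variation; a 13-nt oligo then
#' covers positions 2-14.
#'
#' @param family An [isomir_family()] (or a single [mature_mirna()]).
#' @param length Oligo length in nt, default 13.
#' @param anchor_start First mature position covered, default 2.
#' @return A DNA `nuc_sequence`.
#' @examples
#' design_inhibitor(omy_mir122_family(), length = 13)  # ATTGTCACACTCC
#' @export
design_inhibitor <- function(family, length = 13L, anchor_start = 2L) {
  if (inherits(family, "mature_mirna")) {
    family <- isomir_family(family$id, list(family))
  }
  stopifnot(inherits(family, "isomir_family"), length >= 1L, anchor_start >= 1L)
  span_end <- anchor_start + length - 1L
  if (anchor_start < family$core_span[1] || span_end > family$core_span[2]) {
    lens <- vapply(family$members, function(m) nchar(m$sequence$residues), 0L)
    offending <- vapply(family$members, function(m) m$id, "")[which.min(lens)]
    stop("requested span [", anchor_start, ",", span_end,
         "] exits the shared core [", family$core_span[1], ",",
         family$core_span[2], "] (shortest member: ", offending, ")")
  }
  core <- substr(family$members[[1]]$sequence$residues, anchor_start, span_end)
  nuc_sequence(paste0(family$id, "-inhibitor"),
               revcomp_chr(gsub("U", "T", core, fixed = TRUE), "DNA"), "DNA")
}

#' Verify an inhibitor oligo against a mature miRNA
#'
#' Finds the longest contiguous stretch of the mature sequence whose DNA
#' reverse complement occurs as a contiguous substring of the oligo, so the
#' full oligo is tested against every mature window. Reports whether the
#' matched mature span covers the seed (positions 2-7 by default) and
#' whether the entire oligo is matched.
#'
#' @param oligo DNA `nuc_sequence` or string.
#' @param mirna A [mature_mirna()].
#' @return List with `oligo_id`, `mirna_id`, `match_start` (1-based on the
#'   mature), `match_len`, `covers_seed`, `full_match`. `match_len = 0`
#'   when no single base pairs.
#' @examples
#' verify_inhibitor(lna_122i(), omy_mir122())
#' @export
verify_inhibitor <- function(oligo, mirna) {
  oligo <- as_nuc(oligo, "oligo")
  if (!nchar(oligo$residues)) stop("verify_inhibitor: empty oligo")
  stopifnot(inherits(mirna, "mature_mirna"))
  olig <- coerce_alphabet(oligo, "DNA")$residues
  mat <- coerce_alphabet(mirna$sequence, "DNA")$residues
  L <- nchar(mat); W <- nchar(olig)
  best_start <- NA_integer_; best_len <- 0L
  for (len in seq.int(min(L, W), 1L)) {
    for (start in seq_len(L - len + 1L)) {
      rc <- revcomp_chr(substr(mat, start, start + len - 1L), "DNA")
      if (grepl(rc, olig, fixed = TRUE)) {
        best_start <- start; best_len <- len
        break
      }
    }
    if (best_len > 0L) break
  }
  seed <- mirna$seed_span
  covers <- best_len > 0L && best_start <= seed[1] &&
    (best_start + best_len - 1L) >= seed[2]
  list(oligo_id = oligo$id, mirna_id = mirna$id,
       match_start = best_start, match_len = best_len,
       covers_seed = covers, full_match = best_len == W)
}

#' Screen an oligo for seed-level off-targets in a miRNA panel
#'
#' A panel member is reported when its entire seed region (positions 2-7 by
#' default) is fully complementary to some contiguous oligo window — the
#' condition under which the oligo could sequester that miRNA. The cognate
#' miRNA of a seed-anchored inhibitor always appears; unrelated miRNAs
#' (distinct seeds) should not.
#'
#' @param oligo DNA `nuc_sequence` or string.
#' @param panel List of [mature_mirna()] objects.
#' @return Data frame `mirna_id`, `seed_hit` (logical), in panel order.
#' @export
offtarget_screen <- function(oligo, panel) {
  if (!length(panel)) stop("offtarget_screen: empty panel")
  oligo <- coerce_alphabet(as_nuc(oligo, "oligo"), "DNA")$residues
  hits <- vapply(panel, function(m) {
    stopifnot(inherits(m, "mature_mirna"))
    grepl(site_sequence(m, "6mer")$residues, oligo, fixed = TRUE)
  }, logical(1))
  data.frame(mirna_id = vapply(panel, function(m) m$id, ""),
             seed_hit = unname(hits), stringsAsFactors = FALSE)
}
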