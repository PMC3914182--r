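#' Nucleotide sequence objects
#'
#' `nuc_sequence()` builds a validated single nucleotide sequence with an
#' explicit alphabet. Residues are uppercase-normalized on ingest (a warning
#' is raised when lowercase masking characters are present, as is common in
#' UTR database exports); the ambiguity code `N` is permitted in either
#' alphabet and never participates in seed matching downstream.
#'
#' All coordinates used throughout the package are 1-based and inclusive, on
#' the given (sense) strand.
#'
#' @param id Character scalar, the sequence label.
#' @param residues Character scalar over `A,C,G,T,U,N` (case-insensitive).
#' @param alphabet Either `"DNA"` or `"RNA"`. `"DNA"` forbids `U`, `"RNA"`
#'   forbids `T`.
#' @return An object of class `nuc_sequence`: a list with elements `id`,
#'   `residues` and `alphabet`.
#' @examples
#' nuc_sequence("lna-122i", "ATTGTCACACTCC", "DNA")
#' @export
nuc_sequence <- function(id, residues, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  if (grepl("[acgtun]", residues)) {
    warning("lowercase residues in '", id, "' uppercased; soft-masking is ignored")
  }
  residues <- toupper(residues)
  bad <- gsub("[ACGTUN]", "", residues)
  if (nzchar(bad)) {
    stop("invalid symbol(s) in sequence '", id, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  if (alphabet == "DNA" && grepl("U", residues, fixed = TRUE)) {
    stop("alphabet error: 'U' not allowed in DNA sequence '", id, "'")
  }
  if (alphabet == "RNA" && grepl("T", residues, fixed = TRUE)) {
    stop("alphabet error: 'T' not allowed in RNA sequence '", id, "'")
  }
  structure(list(id = id, residues = residues, alphabet = alphabet),
            class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat(sprintf("<nuc_sequence> %s [%s, %d nt]\n", x$id, x$alphabet,
              nchar(x$residues)))
  cat(" ", x$residues, "\n", sep = "")
  invisible(x)
}

#' @export
length.nuc_sequence <- function(x) nchar(x$residues)

# internal: accept a nuc_sequence or a bare string (assumed DNA unless it has U)
as_nuc <- function(x, id = "seq") {
  if (inherits(x, "nuc_sequence")) return(x)
  alpha <- if (grepl("U", toupper(x), fixed = TRUE)) "RNA" else "DNA"
  nuc_sequence(id, x, alpha)
}

COMPLEMENT_DNA <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
COMPLEMENT_RNA <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

# internal complement/reverse on bare strings
revcomp_chr <- function(s, alphabet = "DNA") {
  if (!nzchar(s)) return(s)
  comp <- if (alphabet == "RNA") COMPLEMENT_RNA else COMPLEMENT_DNA
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

#' Reverse complement
#'
#' Returns the reverse complement of a sequence in the same alphabet.
#' `N` maps to `N`; the empty sequence maps to itself. This is the primitive
#' behind seed-site strings and antisense inhibitor design: a 13-nt
#' antagonist anchored at the seed is simply the DNA reverse complement of
#' mature miRNA positions 2-14.
#'
#' @param seq A `nuc_sequence` (or bare string, treated as DNA unless it
#'   contains `U`).
#' @return A `nuc_sequence` of the same alphabet and length.
#' @examples
#' reverse_complement(nuc_sequence("oligo", "ATTGTCACACTCC", "DNA"))
#' @export
reverse_complement <- function(seq) {
  seq <- as_nuc(seq)
  nuc_sequence(seq$id, revcomp_chr(seq$residues, seq$alphabet), seq$alphabet)
}

#' Convert between DNA and RNA representations
#'
#' Substitutes `T` for `U` (or vice versa) so that, e.g., a DNA qPCR primer
#' sequence can stand in for the mature miRNA it amplifies. The conversion is
#' an isomorphism: DNA -> RNA -> DNA is the identity, and coercing to the
#' current alphabet is a no-op.
#'
#' @param seq A `nuc_sequence` or bare string.
#' @param target `"DNA"` or `"RNA"`.
#' @return A `nuc_sequence` in the target alphabet.
#' @examples
#' coerce_alphabet("TGGAGTGTGACAATGGTGTTTGT", "RNA")
#' @export
coerce_alphabet <- function(seq, target = c("DNA", "RNA")) {
  target <- match.arg(target)
  seq <- as_nuc(seq)
  res <- if (target == "DNA") {
    gsub("U", "T", seq$residues, fixed = TRUE)
  } else {
    gsub("T", "U", seq$residues, fixed = TRUE)
  }
  nuc_sequence(seq$id, res, target)
}

#' Read a multi-record FASTA file
#'
#' A strict reader for plain-text FASTA: any input wrap width is accepted,
#' record order is preserved, duplicate ids are rejected, and malformed
#' input (sequence data before the first header, empty records) raises an
#' error naming the offending line. Ids are the header token up to the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"`, `"RNA"`, or `"auto"` (default: per record, RNA
#'   iff the record contains `U`).
#' @return A named list of `nuc_sequence` objects, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, alphabet = c("auto", "DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  header_line <- integer(0)
  cur <- NULL
  buf <- character(0)
  flush <- function() {
    if (is.null(cur)) return()
    if (!length(buf) || !nzchar(paste(buf, collapse = ""))) {
      stop("FASTA parse error at line ", header_line[length(header_line)],
           ": empty record '", cur, "'")
    }
    ids[[length(ids) + 1L]] <<- cur
    seqs[[length(seqs) + 1L]] <<- paste(buf, collapse = "")
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      id <- sub("\\s.*$", "", sub("^>", "", ln))
      if (!nzchar(id)) stop("FASTA parse error at line ", i, ": empty header")
      cur <- id
      header_line <- c(header_line, i)
      buf <- character(0)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) {
        stop("FASTA parse error at line ", i, ": sequence data before first header")
      }
      buf <- c(buf, trimws(ln))
    }
  }
  flush()
  if (!length(ids)) stop("FASTA parse error: no records in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    alpha <- if (alphabet == "auto") {
      if (grepl("U", toupper(seqs[[i]]), fixed = TRUE)) "RNA" else "DNA"
    } else alphabet
    out[[i]] <- nuc_sequence(ids[[i]], seqs[[i]], alpha)
  }
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' Records are written in input order with 60-column line wrapping. A named
#' character vector may carry alignment gaps (`-`), so aligned families can
#' be written as-is; `nuc_sequence` records are validated gap-free.
#'
#' @param records A list of `nuc_sequence` objects, or a named character
#'   vector of residues (gaps allowed).
#' @param path Output path.
#' @param wrap Line width, default 60.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.character(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records)))) {
      stop("character records must be named (non-empty ids)")
    }
    bad <- grepl("[^ACGTUNacgtun-]", records)
    if (any(bad)) {
      stop("invalid symbol(s) in record '", names(records)[bad][1], "'")
    }
    records <- Map(function(id, s) list(id = id, residues = toupper(s)),
                   names(records), records)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    if (!nzchar(rec$id)) stop("record with empty id cannot be written")
    writeLines(paste0(">", rec$id), con)
    s <- rec$residues
    n <- nchar(s)
    if (n == 0L) {
      writeLines("", con)
    } else {
      starts <- seq.int(1L, n, by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, n)), con)
    }
  }
  invisible(path)
}
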