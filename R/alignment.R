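# The allele alignment container: a tibble with one row per allele and
# columns `allele` (unique id), `species`, `genus`, `seq` (equal-length
# ungapped nucleotide strings). Extra columns (read support, lineage tags)
# pass through untouched so alignments chain through dplyr verbs.

#' Coerce to an allele alignment tibble
#'
#' Validates and normalises an alignment: a data frame with columns
#' `allele` and `seq` (plus optional `species` / `genus`, filled with
#' `"unknown"` when absent). Sequences are uppercased and must be equal
#' length with alphabet ACGTN and no gaps.
#'
#' @param x A data frame with columns `allele`, `seq` and optionally
#'   `species`, `genus`; or a named character vector of sequences.
#' @return A tibble with columns `allele`, `species`, `genus`, `seq` first.
#' @export
as_allele_alignment <- function(x) {
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("a", seq_along(x))
    x <- tibble(allele = nm, seq = unname(x))
  }
  x <- as_tibble(x)
  if (!all(c("allele", "seq") %in% names(x))) {
    abort("alignment needs `allele` and `seq` columns", class = "mhctsp_error")
  }
  if (!"species" %in% names(x)) x$species <- "unknown"
  if (!"genus" %in% names(x)) x$genus <- "unknown"
  x$seq <- toupper(x$seq)
  lens <- nchar(x$seq)
  if (nrow(x) > 0 && length(unique(lens)) != 1L) {
    abort("alignment sequences must all be the same length",
          class = "mhctsp_error")
  }
  if (nrow(x) > 0 && any(grepl("[^ACGTN]", x$seq))) {
    abort("alignment sequences must use alphabet ACGTN (no gaps)",
          class = "mhctsp_error")
  }
  if (anyDuplicated(x$allele)) {
    abort("allele ids must be unique", class = "mhctsp_error")
  }
  dplyr::relocate(x, "allele", "species", "genus", "seq")
}

alignment_length <- function(alignment) {
  if (nrow(alignment) == 0L) return(0L)
  nchar(alignment$seq[[1]])
}

#' Default peptide-binding-region codon mask
#'
#' Codon positions (1-based, within the codons spanned by the amplicon)
#' treated as peptide-binding-region (PBR) sites. The default ships as a
#' configurable input: it maps the classical human class II beta-1 PBR
#' residue list onto an 82-codon exon-2 fragment assumed to start at mature
#' beta-1 residue 5. Supply your own mask whenever the fragment coordinates
#' differ.
#'
#' @param n_codons Number of complete codons in the fragment.
#' @param offset_aa Mature-protein residue number of the fragment's first
#'   complete codon.
#' @return Sorted integer vector of codon positions within the fragment.
#' @export
default_pbr_mask <- function(n_codons = 82L, offset_aa = 5L) {
  beta1_pbr <- c(9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 57, 60, 61,
                 65, 66, 67, 68, 70, 71, 74, 76, 78, 81, 82, 85, 86)
  pos <- beta1_pbr - offset_aa + 1L
  sort(pos[pos >= 1L & pos <= n_codons])
}

# FASTA helpers ---------------------------------------------------------

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` (full header) and `seq`.
#' @export
read_fasta_tbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(tibble(id = character(0), seq = character(0)))
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(
    split(lines[!hdr], grp[!hdr]),
    function(x) paste(x, collapse = ""),
    character(1)
  )
  tibble(id = ids, seq = toupper(unname(seqs)))
}

#' Write sequences to FASTA
#'
#' @param x Data frame with an id column and a `seq` column, or a named
#'   character vector.
#' @param path Output path.
#' @param id_col Name of the id column when `x` is a data frame.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path, id_col = "id") {
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x))
  stopifnot(id_col %in% names(x), "seq" %in% names(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x) > 0) {
    writeLines(paste0(">", x[[id_col]], "\n", x$seq), con)
  }
  invisible(path)
}
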