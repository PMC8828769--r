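AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ALN_ALPHABET <- c(AA_LETTERS, "-", "X")

#' Aligned peptide set
#'
#' A validated multiple protein alignment: records of equal-length aligned
#' peptide strings over the 20 amino acids plus gap `-` and unknown `X`,
#' with one record designated as the reference (the human sequence in the
#' TRPA1 analyses). Unaligned input (unequal lengths) is rejected.
#'
#' @param sequences Named character vector of aligned peptide strings.
#' @param reference Name of the reference record (default: the first).
#' @return An `aligned_set`.
#' @export
aligned_set <- function(sequences, reference = names(sequences)[1]) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("`sequences` must be a named character vector.")
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort("Sequences are not aligned: unequal lengths.")
  }
  bad <- setdiff(unique(unlist(strsplit(sequences, ""))), ALN_ALPHABET)
  if (length(bad)) {
    abort(paste0("Illegal alignment characters: ", paste(bad, collapse = " ")))
  }
  if (!reference %in% names(sequences)) {
    abort(sprintf("Reference '%s' not found in the alignment.", reference))
  }
  structure(list(sequences = sequences, reference = reference,
                 width = unname(lens[1])),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d sequences x %d columns (reference: %s)\n",
              length(x$sequences), x$width, x$reference))
  invisible(x)
}

#' Read a protein alignment from FASTA or Clustal
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference Reference record name (default: first record).
#' @return An [aligned_set()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference = NULL) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  aligned_set(seqs, reference = reference %||% names(seqs)[1])
}

# columns of an aligned_set as a character matrix (rows = records)
aln_matrix <- function(aligned) {
  do.call(rbind, strsplit(unname(aligned$sequences), ""))
}

#' Threshold consensus of an alignment
#'
#' Per alignment column, the most frequent symbol is called if its frequency
#' reaches `threshold` (default 65%); below-threshold columns and tied
#' columns yield `X`. By default gaps count as a symbol (they enter the
#' denominator and can themselves be called); `count_gaps = FALSE` drops
#' them from the column before counting.
#'
#' @param aligned An [aligned_set()].
#' @param threshold Minimum column frequency for a call, default 0.65.
#' @param count_gaps Count gaps as a 21st symbol (default `TRUE`).
#' @return A `consensus_seq`: list with `sequence` (single string, same
#'   width as the alignment) and `threshold`.
#' @examples
#' aln <- aligned_set(c(a = "AAG", b = "AAG", c = "AGG"))
#' consensus_sequence(aln)$sequence  # "AAG": 2/3 = 0.667 >= 0.65 in column 2
#' @export
consensus_sequence <- function(aligned, threshold = 0.65, count_gaps = TRUE) {
  stopifnot(inherits(aligned, "aligned_set"))
  check_fraction(threshold, "threshold")
  m <- aln_matrix(aligned)
  res <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (!count_gaps) {
      col <- col[col != "-"]
      if (!length(col)) return("-")
    }
    tab <- table(col)
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (length(winners) > 1L || top / length(col) < threshold) "X"
    else winners
  }, character(1))
  structure(list(sequence = paste(res, collapse = ""), threshold = threshold),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq> threshold %.0f%%: %s\n", 100 * x$threshold,
              if (nchar(x$sequence) > 60)
                paste0(substr(x$sequence, 1, 57), "...") else x$sequence))
  invisible(x)
}

#' Percent identity of a consensus to the reference
#'
#' Over the alignment columns where the reference is not a gap (optionally
#' restricted to a reference-coordinate region), the percentage of columns
#' where the consensus equals the reference residue. No-call (`X`) consensus
#' positions count as mismatches, so a fully ambiguous consensus scores 0%.
#'
#' @param consensus A `consensus_seq` from [consensus_sequence()].
#' @param aligned The [aligned_set()] it was computed from.
#' @param start,end Optional 1-based inclusive region in *ungapped reference
#'   coordinates*; default: the whole reference.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(consensus, aligned, start = NULL, end = NULL) {
  stopifnot(inherits(consensus, "consensus_seq"),
            inherits(aligned, "aligned_set"))
  ref <- strsplit(aligned$sequences[[aligned$reference]], "")[[1]]
  cons <- strsplit(consensus$sequence, "")[[1]]
  if (length(cons) != length(ref)) {
    abort("Consensus width does not match the alignment.")
  }
  nongap <- ref != "-"
  refpos <- cumsum(nongap)
  ref_len <- refpos[length(refpos)]
  start <- start %||% 1L
  end <- end %||% ref_len
  if (start > end) abort("Region out of order: start exceeds end.")
  if (end > ref_len) abort("Region exceeds the reference length.")
  use <- nongap & refpos >= start & refpos <= end
  if (!any(use)) abort("Empty region.")
  100 * mean(cons[use] == ref[use] & cons[use] != "X")
}

#' Per-domain consensus identity across clades
#'
#' For each annotated domain and each clade alignment (all sharing the same
#' reference coordinates), computes the clade consensus and its percent
#' identity to the reference over the domain — the per-domain conservation
#' table used to contrast e.g. mammalian vs non-mammalian TRPA1 homologs.
#'
#' @param clades Named list of [aligned_set()]s sharing a reference.
#' @param domains Tibble/data frame with `name`, `start`, `end` (1-based
#'   inclusive, reference coordinates, `start <= end`).
#' @param threshold,count_gaps Passed to [consensus_sequence()].
#' @return Tibble: `domain`, `start`, `end`, `clade`, `identity_pct`.
#' @export
domain_identity_table <- function(clades, domains, threshold = 0.65,
                                  count_gaps = TRUE) {
  stopifnot(is.list(clades), length(clades) >= 1,
            all(c("name", "start", "end") %in% names(domains)))
  if (is.null(names(clades))) abort("`clades` must be a named list.")
  if (any(domains$start > domains$end) || any(domains$start < 1)) {
    abort("Domain annotations out of order: need 1 <= start <= end.")
  }
  cons <- lapply(clades, consensus_sequence, threshold = threshold,
                 count_gaps = count_gaps)
  purrr::map_dfr(seq_len(nrow(domains)), function(i) {
    purrr::imap_dfr(clades, function(aln, cl) {
      tibble(domain = domains$name[i],
             start = domains$start[i], end = domains$end[i], clade = cl,
             identity_pct = percent_identity(cons[[cl]], aln,
                                             start = domains$start[i],
                                             end = domains$end[i]))
    })
  })
}
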