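#' Protein-to-CDS coordinate arithmetic for mutant constructs
#'
#' Maps 1-based protein residue ranges to 1-based CDS nucleotide ranges:
#' the codon of residue `r` spans nucleotides `3r - 2` to `3r`, so a
#' deletion of residues `a..b` removes nucleotides `3a - 2` to `3b`. Used to
#' derive the nucleotide edits of deletion and point-mutant constructs
#' (e.g. swapping the TM2 tyrosine at residue 785 edits CDS nucleotides
#' 2353-2355).
#'
#' @param start_aa First residue (1-based, >= 1).
#' @param end_aa Last residue (default `start_aa` for a single codon).
#' @return Tibble: `start_aa`, `end_aa`, `start_nt`, `end_nt`.
#' @examples
#' aa_to_cds(785)      # nucleotides 2353-2355
#' aa_to_cds(1, 25)    # nucleotides 1-75
#' @export
aa_to_cds <- function(start_aa, end_aa = start_aa) {
  if (any(start_aa < 1) || any(start_aa != round(start_aa)) ||
      any(end_aa != round(end_aa))) {
    abort("Residue positions must be positive integers.")
  }
  if (any(end_aa < start_aa)) abort("`end_aa` must be >= `start_aa`.")
  tibble(start_aa = as.integer(start_aa), end_aa = as.integer(end_aa),
         start_nt = as.integer(3 * start_aa - 2),
         end_nt = as.integer(3 * end_aa))
}

#' @rdname aa_to_cds
#' @param start_nt,end_nt CDS nucleotide range; must cover whole codons.
#' @return `cds_to_aa()`: tibble with `start_aa`, `end_aa`.
#' @export
cds_to_aa <- function(start_nt, end_nt) {
  if (any(start_nt < 1) || any(end_nt < start_nt)) {
    abort("Invalid CDS range.")
  }
  if (any((start_nt - 1) %% 3 != 0) || any(end_nt %% 3 != 0)) {
    abort("CDS range must cover whole codons (start at 3r-2, end at 3r).")
  }
  tibble(start_aa = as.integer((start_nt + 2) / 3),
         end_aa = as.integer(end_nt / 3))
}
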