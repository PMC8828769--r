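# Nonpolar residue set used by the optional strict spacer mode.
NONPOLAR_AA <- c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C")

motif_grammars <- list(
  CRAC = list(anchor1 = c("L", "V"), central = "Y", anchor2 = c("R", "K")),
  CARC = list(anchor1 = c("R", "K"), central = c("Y", "F"),
              anchor2 = c("L", "V"))
)

#' Scan a peptide for CRAC/CARC cholesterol-recognition motifs
#'
#' Fuzzy pattern search for the cholesterol-interaction consensus motifs
#' CRAC, `[LV]-X(1,5)-Y-X(1,5)-[RK]`, and its mirrored form CARC,
#' `[RK]-X(1,5)-[YF]-X(1,5)-[LV]`, on an ungapped peptide. Every
#' `(start, end, central)` combination satisfying the grammar is reported;
#' overlapping and nested matches are all kept (match lengths range from 5
#' to 13 residues). By default the spacer `X` matches any residue
#' (fuzzy-search semantics); `strict_spacers = TRUE` restricts spacers to
#' the nonpolar set A, V, L, I, P, F, M, W, G, C.
#'
#' @param sequence Ungapped peptide string over the 20 amino-acid alphabet.
#' @param pattern `"CRAC"`, `"CARC"`, or both (default).
#' @param strict_spacers Restrict spacer residues to nonpolar amino acids.
#' @param offset Added to all reported positions; use when `sequence` is a
#'   fragment so hits come back in full-protein coordinates (an offset of
#'   `k` means the fragment starts at full-protein residue `k + 1`).
#' @return Tibble: `pattern`, `start`, `end`, `central` (position of the
#'   central aromatic), `match` (the matched substring), sorted by start.
#' @examples
#' scan_motifs("LAYAR")  # one CRAC hit, central Y at 3
#' @export
scan_motifs <- function(sequence, pattern = c("CRAC", "CARC"),
                        strict_spacers = FALSE, offset = 0L) {
  pattern <- match.arg(pattern, several.ok = TRUE)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ch <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(ch), AA_LETTERS)
  if (length(bad)) {
    abort(paste0("Illegal residue characters: ", paste(bad, collapse = " ")))
  }
  n <- length(ch)
  spacer_ok_cum <- cumsum(!(ch %in% NONPOLAR_AA))  # for strict mode
  hits <- purrr::map_dfr(pattern, function(pn) {
    g <- motif_grammars[[pn]]
    a1 <- which(ch %in% g$anchor1)
    ce <- ch %in% g$central
    a2 <- ch %in% g$anchor2
    out <- list()
    for (g1 in 1:5) {
      for (g2 in 1:5) {
        span <- 2L + g1 + g2
        i <- a1[a1 + span <= n]
        i <- i[ce[i + 1L + g1] & a2[i + span]]
        if (strict_spacers && length(i)) {
          # all residues in both spacer runs must be nonpolar
          s1_bad <- spacer_ok_cum[i + g1] - spacer_ok_cum[i]
          s2_bad <- spacer_ok_cum[i + 1L + g1 + g2] - spacer_ok_cum[i + 1L + g1]
          i <- i[s1_bad == 0 & s2_bad == 0]
        }
        if (length(i)) {
          out[[length(out) + 1L]] <- tibble(
            pattern = pn, start = i, end = i + span,
            central = i + 1L + g1,
            match = vapply(i, function(s)
              paste(ch[s:(s + span)], collapse = ""), character(1)))
        }
      }
    }
    if (length(out)) dplyr::bind_rows(out) else
      tibble(pattern = character(), start = integer(), end = integer(),
             central = integer(), match = character())
  })
  hits |>
    dplyr::mutate(start = .data$start + offset, end = .data$end + offset,
                  central = .data$central + offset) |>
    dplyr::arrange(.data$pattern, .data$start, .data$end)
}
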