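#' Parse a one-letter amino-acid sequence
#'
#' Accepts a character string of one-letter amino-acid codes (whitespace and
#' case are tolerated) and returns a validated \code{peptide_sequence}.
#'
#' @param text character string of one-letter codes.
#' @param name optional free-text label for the peptide.
#' @return An object of class \code{peptide_sequence}: a list with elements
#'   \code{residues} (character vector of one-letter codes) and \code{name}.
#' @examples
#' bombinin <- parse_sequence("IIGPVLGLVGSALGGLLKKI", name = "bombinin H2")
#' length(bombinin$residues)  # 20
#' @export
parse_sequence <- function(text, name = "") {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("'text' must be a single character string")
  }
  codes <- strsplit(gsub("\\s", "", text), "")[[1]]
  if (length(codes) == 0L) {
    stop("empty sequence")
  }
  codes <- toupper(codes)
  bad <- setdiff(unique(codes), .AA_CODES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid code(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  }
  structure(list(residues = codes, name = name), class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("peptide_sequence: %s (%d residues)\n",
              if (nzchar(x$name)) x$name else "<unnamed>",
              length(x$residues)))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Residue-type composition of a peptide
#'
#' Counts and fractions per residue type present in the sequence.
#'
#' @param seq a \code{peptide_sequence}.
#' @return data.frame with columns \code{residue}, \code{count},
#'   \code{fraction}, one row per residue type present, ordered by residue
#'   code. Counts sum to the sequence length, fractions to 1.
#' @export
composition <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  tab <- table(factor(seq$residues, levels = .AA_CODES))
  tab <- tab[tab > 0L]
  data.frame(
    residue = names(tab),
    count = as.integer(tab),
    fraction = as.numeric(tab) / length(seq$residues),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Formal net charge at neutral pH
#'
#' Sum of formal side-chain charges (Lys/Arg +1, Asp/Glu -1, His 0) plus the
#' free termini (+1 N-terminus, -1 C-terminus). No pKa model is applied.
#'
#' @param seq a \code{peptide_sequence}.
#' @return integer net charge in elementary units.
#' @export
net_charge <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  side <- c(K = 1L, R = 1L, D = -1L, E = -1L)
  # free termini: +1 and -1, which cancel
  as.integer(sum(side[seq$residues], na.rm = TRUE))
}

#' Build a residue-class scheme
#'
#' Partition of the 20 standard residues into hydrophobic, polar and charged
#' classes. The default places Gly and Pro with the hydrophobics, reflecting
#' the dominant role of the apolar surface in glycine-rich peptide collapse;
#' histidine is treated as neutral polar at physiological pH.
#'
#' @param charged,polar,hydrophobic character vectors of one-letter codes.
#'   Together they must cover each standard residue exactly once.
#' @return named character vector of class \code{residue_class_scheme}
#'   mapping every one-letter code to one of
#'   \code{"hydrophobic"}, \code{"polar"}, \code{"charged"}.
#' @export
residue_class_scheme <- function(charged = c("K", "R", "D", "E"),
                                 polar = c("S", "T", "N", "Q", "C", "Y",
                                           "H", "W"),
                                 hydrophobic = c("A", "V", "L", "I", "M",
                                                 "F", "P", "G")) {
  all_codes <- c(charged, polar, hydrophobic)
  if (anyDuplicated(all_codes)) {
    stop("residue assigned to more than one class: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  }
  missing <- setdiff(.AA_CODES, all_codes)
  if (length(missing) > 0L) {
    stop("scheme does not cover residue(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(all_codes, .AA_CODES)
  if (length(extra) > 0L) {
    stop("unknown residue code(s) in scheme: ", paste(extra, collapse = ", "))
  }
  scheme <- c(
    stats::setNames(rep("charged", length(charged)), charged),
    stats::setNames(rep("polar", length(polar)), polar),
    stats::setNames(rep("hydrophobic", length(hydrophobic)), hydrophobic)
  )
  structure(scheme[.AA_CODES], class = "residue_class_scheme")
}

#' Default residue-class scheme
#' @return the default \code{residue_class_scheme}.
#' @export
default_class_scheme <- function() residue_class_scheme()

#' Classify residues of a sequence
#'
#' @param seq a \code{peptide_sequence}.
#' @param scheme a \code{residue_class_scheme}; default scheme if omitted.
#' @return character vector, one class label per residue.
#' @export
classify_residues <- function(seq, scheme = default_class_scheme()) {
  stopifnot(inherits(seq, "peptide_sequence"),
            inherits(scheme, "residue_class_scheme"))
  unname(unclass(scheme)[seq$residues])
}
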