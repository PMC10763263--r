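# Amino-acid alphabet and physicochemical classification used by the tier rules.

#' The 20 standard amino acids
#'
#' One-letter codes, alphabetical. All peptide and pocket sequences handled by
#' the package are over this alphabet; `X` is tolerated only at scoring time
#' (contributing zero, with a warning).
#'
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Physicochemical classes and drastic substitution pairs
#'
#' Partitions the 20 standard amino acids into six classes and lists the
#' unordered class pairs considered a drastic change. The defaults mark as
#' drastic every substitution that crosses charge sign, any charged/uncharged
#' swap, polar/aliphatic swaps, and aromatic/polar swaps -- the changes most
#' likely to reshape the solvent-exposed, TCR-facing surface of a bound
#' peptide. Same-class substitutions are conservative; everything else is
#' moderate.
#'
#' @param class_of Named character vector mapping each one-letter amino-acid
#'   code to a class label. Every one of the 20 standard residues must appear
#'   exactly once.
#' @param drastic_pairs Character vector of unordered class pairs written
#'   `"classA:classB"` with the two names in sorted order.
#' @return An object of class `physchem_table`: a list with elements
#'   `class_of` and `drastic_pairs`.
#' @examples
#' tab <- physchem_table()
#' classify_physchem("D", "K", tab)  # charge reversal -> drastic
#' classify_physchem("L", "I", tab)  # same class -> conservative
#' @export
physchem_table <- function(class_of = NULL, drastic_pairs = NULL) {
  if (is.null(class_of)) {
    class_of <- c(
      A = "aliphatic", I = "aliphatic", L = "aliphatic", M = "aliphatic",
      V = "aliphatic",
      F = "aromatic", W = "aromatic", Y = "aromatic",
      N = "polar", Q = "polar", S = "polar", T = "polar",
      H = "positive", K = "positive", R = "positive",
      D = "negative", E = "negative",
      C = "special", G = "special", P = "special"
    )
  }
  missing <- setdiff(AA_STANDARD, names(class_of))
  if (length(missing))
    stop("physchem table leaves residues unclassified: ",
         paste(missing, collapse = ", "))
  dup <- names(class_of)[duplicated(names(class_of))]
  if (length(dup))
    stop("physchem table classifies residues twice: ",
         paste(unique(dup), collapse = ", "))
  if (is.null(drastic_pairs)) {
    charged <- c("positive", "negative")
    uncharged <- c("aliphatic", "aromatic", "polar", "special")
    drastic_pairs <- unique(c(
      .pair_key("positive", "negative"),
      unlist(lapply(charged, function(ch)
        vapply(uncharged, function(u) .pair_key(ch, u), character(1)))),
      .pair_key("polar", "aliphatic"),
      .pair_key("aromatic", "polar")
    ))
  }
  structure(list(class_of = class_of, drastic_pairs = drastic_pairs),
            class = "physchem_table")
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

#' Classify the severity of a single amino-acid substitution
#'
#' @param wt_aa,mut_aa One-letter codes of the wild-type and mutant residue.
#'   Vectorised; recycled to a common length.
#' @param table A [physchem_table()].
#' @return Character vector over `{"drastic", "moderate", "conservative"}`.
#' @export
classify_physchem <- function(wt_aa, mut_aa, table = physchem_table()) {
  stopifnot(inherits(table, "physchem_table"))
  n <- max(length(wt_aa), length(mut_aa))
  wt_aa <- rep_len(wt_aa, n)
  mut_aa <- rep_len(mut_aa, n)
  unknown <- !(wt_aa %in% names(table$class_of)) |
    !(mut_aa %in% names(table$class_of))
  if (any(unknown))
    stop("unknown residue(s): ",
         paste(unique(c(wt_aa, mut_aa)[c(unknown, unknown)]), collapse = ", "))
  cw <- table$class_of[wt_aa]
  cm <- table$class_of[mut_aa]
  key <- mapply(.pair_key, cw, cm, USE.NAMES = FALSE)
  out <- ifelse(cw == cm, "conservative",
                ifelse(key %in% table$drastic_pairs, "drastic", "moderate"))
  unname(out)
}
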