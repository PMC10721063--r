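#' The ordered amino-acid alphabet
#'
#' The twenty standard amino acids in the fixed order
#' `A C D E F G H I K L M N P Q R S T V W Y`, optionally extended by a single
#' unknown symbol that absorbs ambiguous or non-standard residues
#' (B, Z, J, X, U, O, `*`). One-hot positions are defined by this order, so it
#' must be identical across every run of a pipeline.
#'
#' @param unknown_enabled Add the extra unknown unit (default `TRUE`).
#' @param unknown_symbol Letter used for the unknown class (default `"X"`).
#' @return An object of class `aa_alphabet`: a character vector of letters with
#'   attributes `unknown_symbol` (or `NA`) and `dimension`.
#' @examples
#' aa_alphabet()
#' aa_alphabet(unknown_enabled = FALSE)
#' @export
aa_alphabet <- function(unknown_enabled = TRUE, unknown_symbol = "X") {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (unknown_enabled) {
    stopifnot(nchar(unknown_symbol) == 1L)
    letters <- c(letters20, unknown_symbol)
  } else {
    letters <- letters20
    unknown_symbol <- NA_character_
  }
  structure(letters,
            unknown_symbol = unknown_symbol,
            dimension = length(letters),
            class = "aa_alphabet")
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet> dimension", attr(x, "dimension"), "\n")
  cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

# Letters folded into the unknown class when encountered in input sequences.
AMBIGUOUS_RESIDUES <- c("B", "Z", "J", "X", "U", "O", "*")

alphabet_index <- function(residues, alphabet) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, unclass(alphabet))
  unk <- attr(alphabet, "unknown_symbol")
  if (anyNA(idx)) {
    if (is.na(unk)) {
      abort(paste0("residue(s) outside the alphabet with unknown unit disabled: ",
                   paste(unique(chars[is.na(idx)]), collapse = ", ")))
    }
    idx[is.na(idx)] <- match(unk, unclass(alphabet))
  }
  idx
}
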