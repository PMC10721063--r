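#' Read labelled protein sequences from FASTA
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a tibble of
#' protein records. Family labels come either from a sidecar tab-separated
#' table with columns `id` and `family`, or, when no table is given, from a
#' `"|"`-delimited FASTA header of the form `id|family`. Residues are
#' upper-cased; characters outside the canonical alphabet are replaced by the
#' unknown symbol and counted in a warning.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to a TSV with columns `id`, `family`, or a data
#'   frame with those columns. `NULL` (default) falls back to header parsing.
#' @param alphabet An [aa_alphabet()].
#' @return A tibble with columns `id`, `residues`, `family` (one row per FASTA
#'   entry) and attribute `n_replaced`, the count of substituted residues.
#' @export
read_fasta <- function(path, labels = NULL, alphabet = aa_alphabet()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("record(s) with empty sequence: ",
                 paste(headers[empty], collapse = ", ")))
  }

  if (is.null(labels)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- map_chr(parts, 1)
    fams <- map_chr(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_)
  } else {
    lab <- if (is.data.frame(labels)) {
      as_tibble(labels)
    } else {
      readr::read_tsv(labels, col_types = readr::cols(.default = readr::col_character()))
    }
    if (!all(c("id", "family") %in% names(lab))) {
      abort("label table must have columns `id` and `family`")
    }
    ids <- map_chr(strsplit(headers, "[| ]"), 1)
    fams <- lab$family[match(ids, lab$id)]
  }

  cleaned <- clean_residues(seqs, alphabet)
  if (cleaned$n_replaced > 0L) {
    warn(paste0(cleaned$n_replaced,
                " residue(s) outside the 20-letter alphabet mapped to the unknown symbol"))
  }
  out <- tibble(id = ids, residues = cleaned$residues, family = fams)
  attr(out, "n_replaced") <- cleaned$n_replaced
  out
}

# Replace out-of-alphabet characters with the unknown symbol, counting them.
clean_residues <- function(seqs, alphabet) {
  letters <- unclass(alphabet)
  unk <- attr(alphabet, "unknown_symbol")
  canonical <- setdiff(letters, unk)
  n_replaced <- 0L
  fixed <- map_chr(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !(chars %in% canonical)
    if (any(bad)) {
      if (is.na(unk)) {
        abort(paste0("residue(s) outside the alphabet with unknown unit disabled: ",
                     paste(unique(chars[bad]), collapse = ", ")))
      }
      n_replaced <<- n_replaced + sum(chars[bad] != unk)
      chars[bad] <- unk
    }
    paste(chars, collapse = "")
  })
  list(residues = unname(fixed), n_replaced = n_replaced)
}

#' Write protein records to FASTA (and optionally a label TSV)
#'
#' @param records Tibble with columns `id`, `residues`, and (optionally)
#'   `family`.
#' @param path Output FASTA path.
#' @param labels_path Optional TSV path for the `id`/`family` sidecar table.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, labels_path = NULL, width = 60L) {
  set <- Biostrings::BStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  if (!is.null(labels_path)) {
    readr::write_tsv(records[, c("id", "family")], labels_path)
  }
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Partitions records into train/validation/test sets, stratified per family so
#' every family contributes the requested fractions (largest-remainder rounding
#' within each family, remainders resolved in split order train, validation,
#' test). The assignment depends only on the set of record ids and the seed,
#' never on input row order, so shuffled inputs yield the same partition.
#'
#' @param records Tibble with columns `id` and `family`.
#' @param fractions Numeric triple `(train, validation, test)` summing to 1.
#' @param seed Integer seed controlling the within-family shuffle.
#' @return An object of class `dataset_split`: a list with integer index
#'   vectors `train`, `validation`, `test` (row indices into `records`), plus
#'   `fractions` and `seed`.
#' @examples
#' recs <- tibble::tibble(id = sprintf("s%02d", 1:40),
#'                        residues = strrep("ACDE", 10),
#'                        family = rep(c("f1", "f2"), each = 20))
#' sp <- stratified_split(recs, c(0.7, 0.1, 0.2), seed = 1)
#' lengths(sp[c("train", "validation", "test")])
#' @export
stratified_split <- function(records, fractions, seed) {
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1)) {
    abort("`fractions` must be three proportions in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1")
  fams <- sort(unique(records$family))
  idx <- list(train = integer(), validation = integer(), test = integer())
  with_seed(derive_seed(seed, 0L), {
    for (fam in fams) {
      rows <- which(records$family == fam)
      rows <- rows[order(records$id[rows])]
      rows <- rows[sample.int(length(rows))]
      counts <- largest_remainder(length(rows), fractions)
      bounds <- cumsum(counts)
      idx$train <- c(idx$train, rows[seq_len(counts[1])])
      if (counts[2] > 0) {
        idx$validation <- c(idx$validation, rows[(bounds[1] + 1):bounds[2]])
      }
      if (counts[3] > 0) {
        idx$test <- c(idx$test, rows[(bounds[2] + 1):bounds[3]])
      }
    }
  })
  structure(list(train = idx$train, validation = idx$validation,
                 test = idx$test, fractions = fractions, seed = seed),
            class = "dataset_split")
}

# Integer apportionment of n into parts proportional to fractions; leftover
# units go to the largest fractional remainders, ties broken by part order.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> seed", x$seed, "fractions",
      paste(x$fractions, collapse = "/"), "\n")
  cat("  train:", length(x$train), " validation:", length(x$validation),
      " test:", length(x$test), "\n")
  invisible(x)
}
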