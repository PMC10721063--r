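#' One-hot encode a single residue
#'
#' A residue maps to a binary vector of length `dimension(alphabet)` with a
#' single 1 at the residue's alphabet position; `A` lights position 1, `C`
#' position 2, and so on in the fixed order. Ambiguous residues light the
#' extra unknown unit when the alphabet carries one.
#'
#' @param residue Single character.
#' @param alphabet An [aa_alphabet()].
#' @return Integer 0/1 vector of length `attr(alphabet, "dimension")`.
#' @examples
#' one_hot("A")[1:4]
#' which(one_hot("X") == 1)
#' @export
one_hot <- function(residue, alphabet = aa_alphabet()) {
  stopifnot(is.character(residue), nchar(residue) == 1L)
  idx <- alphabet_index(toupper(residue), alphabet)
  v <- integer(attr(alphabet, "dimension"))
  v[idx] <- 1L
  v
}

#' Encode a protein sequence as a 1-D numeric signal
#'
#' Under the default `onehot-flat` scheme the per-residue one-hot vectors are
#' concatenated in sequence order, giving a binary signal of length
#' `dimension × nchar(residues)` that preserves both residue identity and
#' position. The `index` scheme instead emits one value per residue: the
#' 0-based alphabet index.
#'
#' @param residues A single sequence string (or a one-row record tibble with a
#'   `residues` column).
#' @param alphabet An [aa_alphabet()].
#' @param scheme `"onehot-flat"` (default) or `"index"`.
#' @return An `encoded_signal`: numeric vector with attributes
#'   `source_length`, `scheme`, `norm_mean`, `norm_sd` (the latter two `NA`
#'   until [normalize_signal()] is applied).
#' @examples
#' encode_sequence("AC", scheme = "index")
#' sum(encode_sequence("MKVL"))
#' @export
encode_sequence <- function(residues, alphabet = aa_alphabet(),
                            scheme = c("onehot-flat", "index")) {
  scheme <- match.arg(scheme)
  if (is.data.frame(residues)) residues <- residues$residues[[1]]
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) abort("empty sequence cannot be encoded")
  idx <- alphabet_index(residues, alphabet)
  L <- length(idx)
  values <- if (scheme == "onehot-flat") {
    dim <- attr(alphabet, "dimension")
    v <- numeric(dim * L)
    v[(seq_len(L) - 1L) * dim + idx] <- 1
    v
  } else {
    as.numeric(idx - 1L)
  }
  new_encoded_signal(values, source_length = L, scheme = scheme)
}

new_encoded_signal <- function(values, source_length, scheme,
                               norm_mean = NA_real_, norm_sd = NA_real_) {
  structure(values, source_length = source_length, scheme = scheme,
            norm_mean = norm_mean, norm_sd = norm_sd,
            class = "encoded_signal")
}

#' @export
print.encoded_signal <- function(x, ...) {
  cat("<encoded_signal>", attr(x, "scheme"), "length", length(x),
      "from", attr(x, "source_length"), "residues\n")
  if (!is.na(attr(x, "norm_mean"))) {
    cat("  normalized with mean", format(attr(x, "norm_mean")),
        "sd", format(attr(x, "norm_sd")), "\n")
  }
  invisible(x)
}

#' Encode a table of protein records
#'
#' @param records Tibble with columns `id`, `residues`, `family`.
#' @inheritParams encode_sequence
#' @return The input tibble with a `signal` list-column of `encoded_signal`s.
#' @export
encode_records <- function(records, alphabet = aa_alphabet(),
                           scheme = c("onehot-flat", "index")) {
  scheme <- match.arg(scheme)
  records$signal <- map(records$residues, encode_sequence,
                        alphabet = alphabet, scheme = scheme)
  records
}

#' Per-family normalization statistics
#'
#' Pools the raw signal values of each family's training members and records
#' the pooled mean and sample standard deviation; downstream signals are
#' z-scored with these statistics. Fit on training rows only — pass the
#' training subset, not the full table. Under the `onehot-flat` scheme every
#' family pools to the same statistics (each residue contributes exactly one
#' 1), so composition differences only show up under the `index` scheme.
#'
#' @param encoded Tibble from [encode_records()] with columns `family`,
#'   `signal`.
#' @return Tibble with columns `family`, `mean`, `sd`, `n_values`, plus
#'   attributes `global_mean`/`global_sd` pooled over all supplied rows.
#' @export
fit_family_norms <- function(encoded) {
  fams <- split(encoded$signal, encoded$family)
  if (any(lengths(fams) < 2L)) {
    abort("every family needs at least 2 training signals to fit norms")
  }
  rows <- imap(fams, function(signals, fam) {
    pooled <- unlist(lapply(signals, as.numeric), use.names = FALSE)
    s <- sd(pooled)
    if (!is.finite(s) || s <= 0) {
      abort(paste0("family `", fam, "` has zero pooled variance; ",
                   "use a different encoding scheme"))
    }
    tibble(family = fam, mean = mean(pooled), sd = s,
           n_values = length(pooled))
  })
  out <- bind_rows(rows)
  pooled_all <- unlist(lapply(encoded$signal, as.numeric), use.names = FALSE)
  attr(out, "global_mean") <- mean(pooled_all)
  attr(out, "global_sd") <- sd(pooled_all)
  out
}

#' Z-score an encoded signal
#'
#' @param signal An `encoded_signal`.
#' @param mean,sd Normalization statistics (sd must be positive).
#' @return The z-scored `encoded_signal` with `norm_mean`/`norm_sd` recorded.
#' @export
normalize_signal <- function(signal, mean, sd) {
  if (!is.finite(sd) || sd <= 0) abort("`sd` must be a positive finite number")
  new_encoded_signal((as.numeric(signal) - mean) / sd,
                     source_length = attr(signal, "source_length"),
                     scheme = attr(signal, "scheme"),
                     norm_mean = mean, norm_sd = sd)
}

#' Normalize a table of encoded records
#'
#' Training rows are z-scored with their family's statistics; rows whose
#' family is unseen (or when `mode = "global"`) use the pooled global
#' statistics, which keeps inference label-free.
#'
#' @param encoded Tibble from [encode_records()].
#' @param norms Output of [fit_family_norms()].
#' @param mode `"family"`, `"global"`, or `"none"`.
#' @return `encoded` with the `signal` column normalized.
#' @export
normalize_records <- function(encoded, norms, mode = c("family", "global", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(encoded)
  gm <- attr(norms, "global_mean")
  gs <- attr(norms, "global_sd")
  encoded$signal <- map2(encoded$signal, encoded$family, function(sig, fam) {
    i <- match(fam, norms$family)
    if (mode == "family" && !is.na(i)) {
      normalize_signal(sig, norms$mean[i], norms$sd[i])
    } else {
      normalize_signal(sig, gm, gs)
    }
  })
  encoded
}
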