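# Triple-blinding by cell scrambling: analyses are run under three codes --
# one real labeling and two decoys that permute the real labels while
# preserving exact class counts -- and unblinded once, at the end.

#' Generate scrambled classification codes
#'
#' Produces `n_decoys` random permutations of the real labels (cell
#' scrambling: exact class counts are preserved, so group-size-dependent
#' power is unchanged), shuffles the order of the real code among the
#' decoys, and seals the index of the real one behind a checksum.
#'
#' @param labels vector of group labels (>= 2 distinct values).
#' @param n_decoys number of decoy codes (default 2).
#' @param seed integer seed.
#' @return list of class `blinding_key`: `codes` (data frame with columns
#'   `code_A`, `code_B`, ...), `sealed` (opaque sealed index), `checksum`,
#'   `seed`. Use [reveal()] to unblind.
#' @export
make_scrambled_codes <- function(labels, n_decoys = 2, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("all labels identical: nothing to scramble", call. = FALSE)
  n_decoys <- stopifnot_count(n_decoys, "n_decoys", 1L)
  key <- with_seed(seed, {
    decoys <- lapply(seq_len(n_decoys), function(i) sample(labels))
    codes <- c(list(labels), decoys)
    ord <- sample.int(length(codes))
    codes <- codes[ord]
    real_idx <- which(ord == 1L)
    df <- as.data.frame(codes, col.names = paste0("code_", LETTERS[seq_along(codes)]),
                        stringsAsFactors = FALSE)
    list(codes = df, sealed = bitwXor(real_idx, 19088743L),
         seed = seed)
  })
  key$checksum <- blinding_checksum(key$codes, key$sealed)
  class(key) <- "blinding_key"
  key
}

blinding_checksum <- function(codes, sealed) {
  str_hash31(paste(c(unlist(codes), sealed), collapse = "|"))
}

#' Reveal the real code of a blinding key
#'
#' Verifies the key's checksum, logs the unblinding event, and returns the
#' index of the real labeling within the key's codes. Idempotent.
#'
#' @param key a `blinding_key` from [make_scrambled_codes()].
#' @return integer index of the real code column.
#' @export
reveal <- function(key) {
  if (!inherits(key, "blinding_key"))
    stop("not a blinding_key", call. = FALSE)
  if (!identical(blinding_checksum(key$codes, key$sealed), key$checksum))
    stop("blinding key checksum mismatch: key was tampered with",
         call. = FALSE)
  idx <- bitwXor(key$sealed, 19088743L)
  message(sprintf("unblinding event: real code is column %s",
                  names(key$codes)[idx]))
  idx
}
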