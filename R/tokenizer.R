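#' Tokenize a SMILES string at the character level
#'
#' Splits a SMILES string into tokens under the conventions used for
#' SMILES language modelling: every bracket expression `[...]` is a single
#' token, the two-character halogens `Cl` and `Br` are single tokens,
#' two-digit ring closures `%NN` are single tokens, and every other
#' character is a token of its own. Tokenization is lossless:
#' `paste(tokenize_smiles(s), collapse = "")` reproduces `s` exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("Cc1cc[nH]c1")
#' tokenize_smiles("BrCCl")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("\\[[^][]*\\]|Cl|Br|%[0-9]{2}|.", smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (any(toks == "[" | toks == "]")) {
    stop("tokenization error: unmatched bracket in SMILES: ", smiles,
         call. = FALSE)
  }
  if (paste(toks, collapse = "") != smiles) {
    stop("tokenization error: could not tokenize SMILES losslessly: ",
         smiles, call. = FALSE)
  }
  toks
}

# Reserved special tokens, in their fixed index order (PAD = 0, UNK = 1,
# BOS = 2, EOS = 3). All public indices in this package are zero-based so
# that the padding index is 0.
PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
BOS_TOKEN <- "<bos>"
EOS_TOKEN <- "<eos>"
RESERVED_TOKENS <- c(PAD_TOKEN, UNK_TOKEN, BOS_TOKEN, EOS_TOKEN)
PAD_INDEX <- 0L
UNK_INDEX <- 1L
BOS_INDEX <- 2L
EOS_INDEX <- 3L

#' Build a token vocabulary from a tokenized corpus
#'
#' The vocabulary consists of the four reserved tokens (`<pad>`, `<unk>`,
#' `<bos>`, `<eos>` at indices 0..3) followed by every corpus token with
#' frequency at least `min_freq`, ordered by descending frequency and then
#' lexicographically (byte order, locale-independent). Construction is
#' deterministic: permuting the corpus never changes the result.
#'
#' @param corpus A list of character vectors, one tokenized SMILES each.
#' @param min_freq Minimum corpus frequency for a token to be included.
#' @return An object of class `smiles_vocab`.
#' @export
build_vocab <- function(corpus, min_freq = 1L) {
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop("`corpus` must be a non-empty list of token vectors", call. = FALSE)
  }
  all_tokens <- unlist(corpus, use.names = FALSE)
  freq <- table(all_tokens)
  keep <- freq[freq >= min_freq]
  toks <- names(keep)
  if (any(toks %in% RESERVED_TOKENS)) {
    stop("corpus contains reserved tokens", call. = FALSE)
  }
  ord <- order(-as.integer(keep), toks, method = "radix")
  new_vocab(c(RESERVED_TOKENS, toks[ord]))
}

new_vocab <- function(tokens) {
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary", call. = FALSE)
  if (!identical(tokens[1:4], RESERVED_TOKENS)) {
    stop("reserved tokens must occupy indices 0..3 in fixed order",
         call. = FALSE)
  }
  index <- seq_along(tokens) - 1L
  names(index) <- tokens
  structure(list(tokens = tokens, index = index), class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("<smiles_vocab> size", length(x$tokens), "\n")
  cat("  tokens:", paste(utils::head(x$tokens, 12L), collapse = " "),
      if (length(x$tokens) > 12L) "..." else "", "\n")
  invisible(x)
}

#' Vocabulary size
#' @param vocab A `smiles_vocab`.
#' @return Integer number of tokens including the reserved block.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  length(vocab$tokens)
}

#' Map tokens to integer indices
#'
#' Indices are zero-based; tokens absent from the vocabulary map to the
#' `<unk>` index (1). With `add_bos_eos = TRUE` the sequence is wrapped in
#' `<bos>`/`<eos>`.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `smiles_vocab`.
#' @param add_bos_eos Wrap with begin/end-of-sequence markers?
#' @return A `token_seq`: list with aligned `tokens` and zero-based `indices`.
#' @export
numericalize <- function(tokens, vocab, add_bos_eos = TRUE) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  if (add_bos_eos) tokens <- c(BOS_TOKEN, tokens, EOS_TOKEN)
  idx <- unname(vocab$index[tokens])
  unk <- is.na(idx)
  idx[unk] <- UNK_INDEX
  tokens[unk] <- UNK_TOKEN
  structure(list(tokens = tokens, indices = as.integer(idx)),
            class = "token_seq")
}

#' Map integer indices back to tokens
#'
#' Inverse of [numericalize()] on sequences without `<unk>`; the reserved
#' `<pad>`, `<bos>` and `<eos>` tokens are stripped from the output.
#'
#' @param seq A `token_seq` or a vector of zero-based indices.
#' @param vocab A `smiles_vocab`.
#' @return Character vector of tokens.
#' @export
denumericalize <- function(seq, vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  idx <- if (inherits(seq, "token_seq")) seq$indices else as.integer(seq)
  if (length(idx) == 0L) return(character(0))
  if (any(idx < 0L) || any(idx >= length(vocab$tokens))) {
    stop("index out of vocabulary range", call. = FALSE)
  }
  toks <- vocab$tokens[idx + 1L]
  toks[!(toks %in% c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN))]
}

#' Write a vocabulary to JSON
#' @param vocab A `smiles_vocab`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  jsonlite::write_json(
    list(reserved = RESERVED_TOKENS,
         tokens = setdiff(vocab$tokens, RESERVED_TOKENS)),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' Read a vocabulary from JSON, verifying its invariants
#' @param path JSON file written by [write_vocab()].
#' @return A `smiles_vocab`.
#' @export
read_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(x$reserved), RESERVED_TOKENS)) {
    stop("vocabulary file has an invalid reserved block", call. = FALSE)
  }
  new_vocab(c(RESERVED_TOKENS, as.character(x$tokens)))
}
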