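#' Derive a deterministic sub-seed from a root seed and a stream name
#'
#' All randomness in the package fans out from one root seed through named
#' substreams, so individual components can be regenerated independently and
#' whole runs are bit-reproducible.
#'
#' @param root integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(name))
  m <- 2147483647  # 2^31 - 1, Lehmer modulus
  h <- as.double(root %% m)
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  h <- (h * 48271) %% m
  as.integer(h)
}

#' Evaluate an expression with a fixed RNG seed, restoring RNG state after
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integer base codes (A=0, C=1, G=2, T=3, else -1)
#' @param seq a single character string.
#' @return Integer vector of per-base codes.
#' @keywords internal
encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  out <- rep(-1L, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

#' @keywords internal
decode_dna <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

#' Reverse complement of a DNA string (case preserved)
#' @param seq character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
    intToUtf8(rev(utf8ToInt(flipped)))
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of sequences (over unambiguous bases, case-insensitive)
#' @param seq character vector of sequences.
#' @return Numeric fraction in `[0, 1]` (NaN for sequences with no ACGT).
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    codes <- encode_dna(s)
    codes <- codes[codes >= 0L]
    if (!length(codes)) return(NaN)
    mean(codes == 1L | codes == 2L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Repeat-masked fraction of sequences (lowercase letters / total length)
#' @param seq character vector of sequences.
#' @return Numeric fraction in `[0, 1]`.
#' @export
repeat_fraction <- function(seq) {
  vapply(seq, function(s) {
    v <- utf8ToInt(s)
    if (!length(v)) return(0)
    mean(v >= 97L & v <= 122L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param scores_pos scores of positive examples.
#' @param scores_neg scores of negative examples.
#' @return AUC in `[0, 1]`; ties contribute 1/2.
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both classes must be non-empty")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

STAGES <- paste0("TP", 1:5)

#' @keywords internal
assert_stage <- function(stage) {
  if (!all(stage %in% STAGES))
    stop("stage labels must be one of ", paste(STAGES, collapse = ", "),
         "; got: ", paste(setdiff(stage, STAGES), collapse = ", "))
  invisible(stage)
}
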