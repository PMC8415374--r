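# Independent oracles used across tests.  These deliberately re-derive
# quantities with naive R code (enumeration, per-base loops, log-space
# combinatorics) so they share no code path with the package internals.

BASES <- c("A", "C", "G", "T")

enc1 <- function(seq) match(strsplit(toupper(seq), "")[[1]], BASES) - 1L

# --- gapped k-mer weight / score oracle -------------------------------------

# canonical feature codes of a single L-mer word, one per mask
oracle_feature_codes <- function(word, L, k) {
  masks <- utils::combn(L, k)             # lexicographic, 1-based positions
  n_masks <- ncol(masks)
  b <- enc1(word)
  mask_key <- apply(masks, 2, paste, collapse = ",")
  rc_index <- vapply(seq_len(n_masks), function(m) {
    match(paste(sort(L + 1 - masks[, m]), collapse = ","), mask_key)
  }, integer(1))
  vapply(seq_len(n_masks), function(m) {
    pos <- masks[, m]
    code <- sum(b[pos] * 4^(rev(seq_len(k)) - 1))
    rcb <- 3 - b[rev(pos)]
    rc_code <- sum(rcb * 4^(rev(seq_len(k)) - 1))
    min((m - 1) * 4^k + code, (rc_index[m] - 1) * 4^k + rc_code)
  }, numeric(1))
}

# weight of a word = sum of canonical-feature weights
oracle_weight <- function(w, word, L, k) {
  sum(w[oracle_feature_codes(word, L, k) + 1])
}

# score = enumerate every L-mer window, sum weights (skip non-ACGT windows)
oracle_score <- function(w, seq, L, k, intercept = 0) {
  b <- enc1(seq)
  total <- intercept
  for (i in seq_len(nchar(seq) - L + 1)) {
    word <- substr(seq, i, i + L - 1)
    if (anyNA(b[i:(i + L - 1)])) next
    total <- total + oracle_weight(w, word, L, k)
  }
  total
}

# deltaSVM restricted to windows covering substituted positions (locality)
oracle_delta_local <- function(model, anc, focal, positions) {
  L <- model$config$L
  n <- nchar(anc)
  starts <- sort(unique(unlist(lapply(positions, function(p) {
    max(0, p - L + 1):min(p, n - L)
  }))))
  total <- 0
  for (s in starts) {
    wf <- substr(focal, s + 1, s + L)
    wa <- substr(anc, s + 1, s + L)
    total <- total + kmer_weight(model, wf) - kmer_weight(model, wa)
  }
  total
}

# --- Fisher exact test oracle ------------------------------------------------

# two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, probabilities in log space via lchoose
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(a, support)]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# --- interval oracles --------------------------------------------------------

# per-base projection of a 0-based half-open interval through a block map
oracle_translate <- function(chrom, start, end, bm) {
  hits <- data.frame(chrom = character(), pos = integer(), strand = character())
  for (p in start:(end - 1)) {
    for (j in seq_len(nrow(bm))) {
      if (bm$chromA[j] == chrom && p >= bm$startA[j] && p < bm$endA[j]) {
        off <- p - bm$startA[j]
        q <- if (bm$strand[j] == "+") bm$startB[j] + off else
          bm$endB[j] - 1 - off
        hits <- rbind(hits, data.frame(chrom = bm$chromB[j], pos = q,
                                       strand = bm$strand[j]))
      }
    }
  }
  hits
}

# O(n^2) per-peak count of other stages with >= 1 bp overlap
oracle_stage_usage <- function(peaks) {
  vapply(seq_len(nrow(peaks)), function(i) {
    other <- peaks[peaks$stage != peaks$stage[i] &
                     peaks$chrom == peaks$chrom[i], ]
    ov <- other$start < peaks$end[i] & other$end > peaks$start[i]
    1L + length(unique(other$stage[ov]))
  }, integer(1))
}

# --- shared fixtures ---------------------------------------------------------

fixture_env <- new.env()

# a small trained model on planted-motif enhancers, cached across tests
tiny_model <- function() {
  if (is.null(fixture_env$tiny_model)) {
    mot <- make_motifs(2, 8, 1.3, 71)
    pos <- vapply(1:50, function(i) make_enhancer(mot, 160, 0.4, 2, i)$seq, "")
    neg <- vapply(1:50, function(i) make_enhancer(mot, 160, 0.4, 0, 5000 + i)$seq, "")
    fixture_env$tiny_model <- train_gkm(pos, neg, gkm_config(L = 6, k = 4),
                                        stage = "TP1")
    fixture_env$tiny_motifs <- mot
  }
  fixture_env$tiny_model
}

tiny_motifs <- function() { tiny_model(); fixture_env$tiny_motifs }

# a small world shared by conservation / pipeline tests
small_world <- function() {
  if (is.null(fixture_env$small_world)) {
    fixture_env$small_world <- make_two_species_world(world_config(
      n_enhancers = 20, extra_partner = 4, n_pleiotropic = 5, n_proximal = 3,
      seed = 42))
  }
  fixture_env$small_world
}

# hand-built two-block map with a 50 bp insertion in B between the blocks
two_block_map <- function() {
  validate_block_map(tibble::tibble(
    chromA = "cA", startA = c(100L, 200L), endA = c(200L, 300L),
    chromB = "cB", startB = c(1000L, 1150L), endB = c(1100L, 1250L),
    strand = "+"))
}

# vectorized brute-force score: enumerate every L-mer window, compute each
# window's weight by explicit mask enumeration (matrix form), and sum.
# independent of the package's rolling-code/table path.
oracle_score_fast <- function(w, seq, L, k, intercept = 0) {
  b <- enc1(seq)
  n <- length(b)
  nr <- n - L + 1
  W <- vapply(seq_len(L), function(j) b[j:(nr + j - 1)], integer(nr))
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  valid <- rowSums(is.na(W)) == 0
  W[is.na(W)] <- 0L
  masks <- utils::combn(L, k)
  mask_key <- apply(masks, 2, paste, collapse = ",")
  rc_index <- vapply(seq_len(ncol(masks)), function(m) {
    match(paste(sort(L + 1 - masks[, m]), collapse = ","), mask_key)
  }, integer(1))
  pow <- 4^(rev(seq_len(k)) - 1)
  total <- numeric(nr)
  for (m in seq_len(ncol(masks))) {
    sub <- W[, masks[, m], drop = FALSE]
    code <- drop(sub %*% pow)
    rc <- drop((3 - sub[, k:1, drop = FALSE]) %*% pow)
    canon <- pmin((m - 1) * 4^k + code, (rc_index[m] - 1) * 4^k + rc)
    total <- total + ifelse(valid, w[canon + 1], 0)
  }
  sum(total[valid]) + intercept
}
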