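test_that("featurization enumerates gapped k-mers and conserves total counts", {
  cfg <- gkm_config(L = 2, k = 1)
  X <- featurize("AC", cfg)
  # one window, two masks -> total count 2
  expect_equal(sum(X), 2)
  expect_equal(ncol(X), 2 * 4)

  cfg6 <- gkm_config(L = 6, k = 4)
  set.seed(21)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    Xs <- featurize(s, cfg6)
    Xr <- featurize(revcomp(s), cfg6)
    expect_identical(as.matrix(Xs), as.matrix(Xr))
    expect_equal(sum(Xs), (30 - 6 + 1) * choose(6, 4))
  }
  # N-containing windows are skipped and logged
  Xn <- featurize("ACGTNACGTA", cfg6)
  expect_equal(attr(Xn, "skipped"), 5L)  # all windows covering the N
  expect_equal(sum(Xn), 0)
  expect_error(featurize("ACG", cfg6), "shorter")
})

test_that("featurize matches the hand-enumerated canonical features of single words", {
  cfg <- gkm_config(L = 4, k = 2)
  info <- gkm_space_info(4, 2)
  set.seed(8)
  for (i in 1:25) {
    word <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
    X <- featurize(word, cfg)
    codes <- sort(oracle_feature_codes(word, 4, 2))
    sm <- Matrix::summary(X)
    expanded <- sort(rep(sm$j - 1, sm$x))
    expect_equal(expanded, codes)
  }
})

test_that("model weights obey the scoring contract and strand symmetry exactly", {
  m <- tiny_model()
  L <- m$config$L
  set.seed(31)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    expect_identical(score_sequences(m, s), score_sequences(m, revcomp(s)))
  }
  # score of an L-length sequence = weight(word) + intercept
  word <- "ACGTGC"
  expect_equal(score_sequences(m, word), kmer_weight(m, word) + m$intercept,
               tolerance = 1e-12)
  # sliding-window score equals the brute-force oracle over all L-mers
  s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  expect_equal(score_sequences(m, s),
               oracle_score(m$w, s, L, m$config$k, m$intercept),
               tolerance = 1e-9)
  # cached table equals the on-demand weight for random words
  tab <- weight_table(m)
  for (i in 1:30) {
    wd <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    expect_equal(tab[word_code(wd) + 1], kmer_weight(m, wd), tolerance = 1e-12)
    expect_equal(oracle_weight(m$w, wd, L, m$config$k), kmer_weight(m, wd),
                 tolerance = 1e-12)
  }
  expect_error(score_sequences(m, "ACG"), "shorter")
  expect_error(kmer_weight(m, "ACG"), "length exactly")
})

test_that("training is deterministic, rejects degenerate input, and duplication is a no-op", {
  mot <- tiny_motifs()
  pos <- vapply(1:20, function(i) make_enhancer(mot, 120, 0.4, 2, i)$seq, "")
  neg <- vapply(1:20, function(i) make_enhancer(mot, 120, 0.4, 0, 900 + i)$seq, "")
  cfg <- gkm_config(L = 5, k = 3)
  m1 <- train_gkm(pos, neg, cfg)
  m2 <- train_gkm(pos, neg, cfg)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$intercept, m2$intercept)
  # balanced duplication leaves the solution unchanged (per-sample lambda)
  m3 <- train_gkm(c(pos, pos), c(neg, neg), cfg)
  expect_equal(m3$w, m1$w, tolerance = 1e-6)
  expect_equal(m3$intercept, m1$intercept, tolerance = 1e-6)

  expect_error(train_gkm(pos, character(0), cfg), "non-empty")
})

test_that("matched negatives satisfy the tolerance contract and never overlap positives", {
  w <- small_world()
  dA <- classify_distal(w$peaks[w$peaks$species == "A", ],
                        w$tss[w$tss$species == "A", ])
  sa <- call_stage_specific(dA)
  sa <- sa[sa$specific & sa$stage == "TP1", ][1:12, ]
  ts <- sample_matched_negatives(sa, w$genomes$A, seed = 5)
  expect_length(ts$negatives, nrow(sa))
  expect_true(all(nchar(ts$negatives) == nchar(ts$positives)))
  unwidened <- ts$report$widened == 0
  expect_true(all(abs(ts$report$gc_pos - ts$report$gc_neg)[unwidened] <= 0.02))
  expect_true(all(abs(ts$report$repeat_pos - ts$report$repeat_neg)[unwidened] <= 0.1))
  # no negative overlaps any positive interval
  for (i in seq_len(nrow(ts$negative_intervals))) {
    ni <- ts$negative_intervals[i, ]
    expect_false(any(sa$chrom == ni$chrom & sa$start < ni$end & sa$end > ni$start))
  }
  # negatives carry background accessibility, below the planted positives
  mot <- w$motifs$TP1
  expect_lt(mean(true_score(ts$negatives, mot)), mean(true_score(ts$positives, mot)))
  # deterministic in seed
  ts2 <- sample_matched_negatives(sa, w$genomes$A, seed = 5)
  expect_identical(ts$negatives, ts2$negatives)
})

test_that("cross-validated AUC equals the rank statistic and hits the toy extremes", {
  expect_equal(auc_rank(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(auc_rank(c(1, 2), c(5, 6, 7)), 0)
  # AUC equals Mann-Whitney U / (n_pos x n_neg) on pooled out-of-fold scores
  mot <- tiny_motifs()
  pos <- vapply(1:25, function(i) make_enhancer(mot, 140, 0.4, 2, 40 + i)$seq, "")
  neg <- vapply(1:25, function(i) make_enhancer(mot, 140, 0.4, 0, 800 + i)$seq, "")
  cv <- cross_validate(pos, neg, gkm_config(L = 5, k = 3, seed = 11), folds = 5)
  sp <- cv$scores$score[cv$scores$label == 1]
  sn <- cv$scores$score[cv$scores$label == -1]
  u <- wilcox.test(sp, sn, exact = FALSE)$statistic
  expect_equal(cv$auc, unname(u) / (length(sp) * length(sn)), tolerance = 1e-12)
  expect_true(all(cv$roc$fpr >= 0 & cv$roc$fpr <= 1))
  # deterministic folds
  cv2 <- cross_validate(pos, neg, gkm_config(L = 5, k = 3, seed = 11), folds = 5)
  expect_identical(cv$auc, cv2$auc)
})

test_that("cross-stage matrix is constant when stages share motifs", {
  mot <- tiny_motifs()
  mk_set <- function(seed0) {
    list(positives = vapply(1:25, function(i)
      make_enhancer(mot, 140, 0.4, 2, seed0 + i)$seq, ""),
      negatives = vapply(1:25, function(i)
        make_enhancer(mot, 140, 0.4, 0, 3000 + seed0 + i)$seq, ""))
  }
  sets <- list(TP1 = mk_set(0), TP2 = mk_set(100))
  models <- lapply(names(sets), function(st)
    train_gkm(sets[[st]]$positives, sets[[st]]$negatives,
              gkm_config(L = 5, k = 3), stage = st))
  names(models) <- names(sets)
  test_sets <- list(TP1 = mk_set(5000), TP2 = mk_set(6000))
  M <- cross_stage_matrix(models, test_sets)
  expect_equal(dim(M), c(2, 2))
  expect_true(all(diag(M) > 0.5))      # each model beats chance on its stage
  expect_lt(max(abs(M - mean(M))), 0.25)  # near-constant under shared motifs
})

test_that("model serialization and external weight tables round-trip", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_kmer_model(m, path)
  back <- read_kmer_model(path)
  expect_equal(back$w, m$w, tolerance = 1e-15)
  expect_equal(back$intercept, m$intercept, tolerance = 1e-15)
  s <- "ACGTACGTACGT"
  expect_equal(score_sequences(back, s), score_sequences(m, s), tolerance = 1e-12)

  # external all-L-mer table import
  wt <- withr::local_tempfile(fileext = ".tsv")
  words <- c("AAAA", "ACGT", "GGCC")
  writeLines(sprintf("%s\t%.3f", words, c(0.5, -1, 2)), wt)
  ext <- read_weight_table(wt, 4)
  expect_equal(kmer_weight(ext, "AAAA"), 0.5)
  expect_equal(kmer_weight(ext, "TTTT"), 0.5)  # reverse complement mirrored
  expect_equal(kmer_weight(ext, "CCCC"), 0)
  expect_equal(score_sequences(ext, "AAAAA"), 1.0)  # two windows of AAAA
})
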