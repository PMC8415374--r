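#' Configuration for the gapped k-mer accessibility model
#'
#' Features are all choose(L, k) placements of `k` informative positions
#' within an `L`-bp word, canonicalized against reverse complementation, so
#' model scores are exactly strand-symmetric.
#'
#' @param L word length (default 10; per-10-mer weights are the unit the
#'   deltaSVM statistic sums over).
#' @param k number of informative positions within each word (default 6).
#' @param lambda ridge regularization strength, scaled per training sample.
#' @param seed integer seed controlling fold assignment and any sampling.
#' @return List of class `gkm_config`.
#' @export
gkm_config <- function(L = 10L, k = 6L, lambda = 1, seed = 1L) {
  L <- as.integer(L); k <- as.integer(k)
  if (L < 2) stop("L must be >= 2")
  if (k < 1 || k > L) stop("k must satisfy 1 <= k <= L")
  if (L > 12) stop("L > 12 is not supported (weight table would exceed memory)")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(L = L, k = k, lambda = lambda, seed = as.integer(seed)),
            class = "gkm_config")
}

#' Featurize sequences into canonical gapped k-mer counts
#'
#' Every L-window of each sequence contributes one count to each of its
#' choose(L, k) masked features; features are canonicalized so that
#' `featurize(s)` equals `featurize(revcomp(s))`.  Windows containing
#' non-ACGT characters are skipped and counted in the `skipped` attribute.
#'
#' @param seqs character vector of sequences (each of length >= L).
#' @param config a [gkm_config()].
#' @return Sparse `dgCMatrix` (rows = sequences, columns = features) with a
#'   `skipped` attribute (per-sequence skipped-window counts).
#' @export
featurize <- function(seqs, config) {
  stopifnot(inherits(config, "gkm_config"))
  res <- gkm_featurize_cpp(seqs, config$L, config$k)
  X <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                            dims = c(length(seqs), res$n_features))
  attr(X, "skipped") <- res$skipped
  X
}

# Least-squares ridge (LS-SVM style) fit in the dual: minimizes
# sum_i (x_i.w + b - y_i)^2 + lambda * n * ||w||^2 with unpenalized intercept.
# Per-sample lambda scaling makes balanced duplication of the training set a
# no-op on the solution.
fit_ridge_dual <- function(X, y, lambda) {
  n <- nrow(X)
  K <- as.matrix(Matrix::tcrossprod(X))
  A <- matrix(0, n + 1, n + 1)
  A[1, 2:(n + 1)] <- 1
  A[2:(n + 1), 1] <- 1
  A[2:(n + 1), 2:(n + 1)] <- K + diag(lambda * n, n)
  rhs <- c(0, y)
  sol <- solve(A, rhs)
  b <- sol[1]
  alpha <- sol[-1]
  w <- as.numeric(Matrix::crossprod(X, alpha))
  list(w = w, intercept = b, alpha = alpha)
}

#' Train the gapped k-mer accessibility classifier
#'
#' Fits a regularized linear model (ridge regression on +/-1 labels, solved in
#' the dual) over per-sequence L2-normalized gapped k-mer counts.  The fitted
#' feature weights define a weight for every L-mer word, and
#' `score(seq) = sum of window weights + intercept` is increasing in
#' predicted accessibility.
#'
#' @param positives character vector of positive (accessible) sequences.
#' @param negatives character vector of matched negative sequences.
#' @param config a [gkm_config()].
#' @param stage optional stage label stored as training metadata.
#' @return Object of class `kmer_model`.
#' @export
train_gkm <- function(positives, negatives, config = gkm_config(),
                      stage = NA_character_) {
  if (!length(positives) || !length(negatives))
    stop("degenerate training set: both classes must be non-empty")
  seqs <- c(positives, negatives)
  y <- c(rep(1, length(positives)), rep(-1, length(negatives)))
  X <- featurize(seqs, config)
  fit <- fit_ridge_dual(normalize_rows(X), y, config$lambda)
  model <- list(config = config, w = fit$w, intercept = fit$intercept,
                stage = stage, n_pos = length(positives),
                n_neg = length(negatives),
                skipped_windows = sum(attr(X, "skipped")),
                cache = new.env(parent = emptyenv()))
  class(model) <- "kmer_model"
  model
}

#' @keywords internal
normalize_rows <- function(X) {
  nrm <- sqrt(Matrix::rowSums(X^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% X
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf(
    "<kmer_model> L=%d k=%d lambda=%g | stage=%s | n_pos=%d n_neg=%d\n",
    x$config$L, x$config$k, x$config$lambda, x$stage, x$n_pos, x$n_neg))
  invisible(x)
}

#' Dense per-L-mer weight table of a model
#'
#' `weight_table(model)[code(word) + 1]` equals [kmer_weight()] of that word;
#' the table is cached on the model after first construction.
#'
#' @param model a `kmer_model` (or external weight-table model).
#' @return Numeric vector of length `4^L`, indexed by base-4 word code
#'   (A=0, C=1, G=2, T=3, most significant base first).
#' @export
weight_table <- function(model) {
  if (!is.null(model$table)) return(model$table)
  if (is.null(model$cache$table))
    model$cache$table <- gkm_weight_table_cpp(model$w, model$config$L,
                                              model$config$k)
  model$cache$table
}

#' Model score of sequences (sum of window weights plus intercept)
#'
#' @param model a `kmer_model`.
#' @param seqs character vector of sequences of length >= L.
#' @return Numeric scores; exactly strand-symmetric.
#' @export
score_sequences <- function(model, seqs) {
  tab <- weight_table(model)
  as.numeric(gkm_score_cpp(seqs, tab, model$config$L)) +
    (model$intercept %||% 0)
}

#' Weight of individual L-mer words under a model
#'
#' Computed on demand from the feature weights (dot product of the model's
#' canonical-feature weights with the word's single-window features); equals
#' the cached [weight_table()] entry.
#'
#' @param model a `kmer_model`.
#' @param words character vector of words, each of length exactly L.
#' @return Numeric weights.
#' @export
kmer_weight <- function(model, words) {
  L <- model$config$L
  if (any(nchar(words) != L)) stop("words must have length exactly L = ", L)
  if (!is.null(model$table))
    return(model$table[word_code(words) + 1])
  res <- gkm_featurize_cpp(words, L, model$config$k)
  out <- numeric(length(words))
  contrib <- model$w[res$j] * res$x
  for (g in split(seq_along(res$i), res$i)) {
    out[res$i[g[1]]] <- sum(contrib[g])
  }
  out
}

#' Base-4 code of L-mer words (A=0, C=1, G=2, T=3, msb first)
#' @param words character vector of equal-length ACGT words.
#' @return Numeric codes.
#' @export
word_code <- function(words) {
  vapply(words, function(w) {
    codes <- encode_dna(w)
    if (any(codes < 0)) stop("word contains non-ACGT characters")
    sum(codes * 4^(rev(seq_along(codes)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Folds are stratified by class and deterministic in `config$seed`.  The AUC
#' is the rank statistic on the pooled out-of-fold scores.
#'
#' @param positives,negatives training sequences.
#' @param config a [gkm_config()].
#' @param folds number of folds (default 5).
#' @return List with `auc`, per-fold `fold_auc`, pooled out-of-fold `scores`
#'   (tibble with `label`), and `roc` (tibble of fpr/tpr points).
#' @export
cross_validate <- function(positives, negatives, config = gkm_config(),
                           folds = 5L) {
  np <- length(positives); nn <- length(negatives)
  if (np < folds || nn < folds)
    stop("need at least `folds` sequences per class")
  seqs <- c(positives, negatives)
  y <- c(rep(1, np), rep(-1, nn))
  X <- featurize(seqs, config)
  # one gram matrix serves every fold: the raw-count score of a held-out
  # sequence is K_raw[test, train] %*% (alpha / row_norm[train]) + b
  nrm <- sqrt(Matrix::rowSums(X^2)); nrm[nrm == 0] <- 1
  K_raw <- as.matrix(Matrix::tcrossprod(X))
  K_norm <- K_raw / outer(nrm, nrm)
  fold_id <- with_seed(config$seed, {
    c(sample(rep(seq_len(folds), length.out = np)),
      sample(rep(seq_len(folds), length.out = nn)))
  })
  scores <- numeric(length(seqs))
  fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    n_tr <- sum(tr)
    A <- matrix(0, n_tr + 1, n_tr + 1)
    A[1, -1] <- 1; A[-1, 1] <- 1
    A[-1, -1] <- K_norm[tr, tr] + diag(config$lambda * n_tr, n_tr)
    sol <- solve(A, c(0, y[tr]))
    sc <- as.numeric(K_raw[!tr, tr, drop = FALSE] %*% (sol[-1] / nrm[tr])) +
      sol[1]
    scores[!tr] <- sc
    fold_auc[f] <- auc_rank(sc[y[!tr] == 1], sc[y[!tr] == -1])
  }
  list(auc = auc_rank(scores[y == 1], scores[y == -1]),
       fold_auc = fold_auc,
       scores = tibble(score = scores, label = y, fold = fold_id),
       roc = roc_points(scores[y == 1], scores[y == -1]))
}

#' ROC curve points from class scores
#' @param scores_pos,scores_neg numeric score vectors.
#' @return Tibble with columns `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
roc_points <- function(scores_pos, scores_neg) {
  thr <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_neg >= t), numeric(1))
  tibble(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Cross-stage AUC matrix
#'
#' Entry (i, j) is the AUC of the stage-j model scoring the stage-i held-out
#' positives against the stage-i negatives.
#'
#' @param models named list of per-stage `kmer_model`s.
#' @param test_sets named list (same names) of lists with elements
#'   `positives` and `negatives`.
#' @return Numeric matrix, rows = test stage, columns = model stage.
#' @export
cross_stage_matrix <- function(models, test_sets) {
  stopifnot(length(models) == length(test_sets),
            identical(names(models), names(test_sets)))
  stages <- names(models)
  out <- matrix(NA_real_, length(stages), length(stages),
                dimnames = list(test = stages, model = stages))
  for (i in stages) {
    for (j in stages) {
      sp <- score_sequences(models[[j]], test_sets[[i]]$positives)
      sn <- score_sequences(models[[j]], test_sets[[i]]$negatives)
      out[i, j] <- auc_rank(sp, sn)
    }
  }
  out
}

#' Sample genome-matched negative training sequences
#'
#' For every positive interval, rejection-samples a genome window of identical
#' length that does not overlap any positive (nor a previously chosen
#' negative), with GC content within `gc_tol` and repeat-masked fraction
#' within `repeat_tol` of the positive.  After `max_reject` failed draws the
#' tolerances for that positive are widened stepwise (doubled, with a
#' warning), up to four times.
#'
#' @param positives interval tibble (`chrom, start, end`, optional `id`).
#' @param genome named character vector of chromosome sequences (lowercase =
#'   repeat-masked).
#' @param gc_tol absolute GC-content tolerance (default 0.02).
#' @param repeat_tol absolute repeat-fraction tolerance (default 0.1).
#' @param seed integer seed; sampling is deterministic in it.
#' @param max_reject failed draws per positive before widening (default 10000).
#' @return List of class `training_set`: `positives` and `negatives` (named
#'   character vectors), `negative_intervals`, and a per-pair matching
#'   `report` tibble.
#' @export
sample_matched_negatives <- function(positives, genome, gc_tol = 0.02,
                                     repeat_tol = 0.1, seed = 1L,
                                     max_reject = 10000L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(positives)),
            all(positives$chrom %in% names(genome)))
  ids <- positives$id %||% paste0("pos", seq_len(nrow(positives)))
  if (!"id" %in% names(positives)) positives$id <- ids
  pos_seqs <- extract_sequences(genome, positives)
  names(pos_seqs) <- positives$id
  chrom_len <- nchar(genome)
  taken <- positives[, c("chrom", "start", "end")]
  neg <- vector("list", nrow(positives))
  report <- vector("list", nrow(positives))
  with_seed(seed, {
    for (i in seq_len(nrow(positives))) {
      len <- positives$end[i] - positives$start[i]
      gc_i <- gc_content(pos_seqs[i])
      rep_i <- repeat_fraction(pos_seqs[i])
      tol_gc <- gc_tol; tol_rep <- repeat_tol
      widened <- 0L; rejected <- 0L; found <- FALSE
      eligible <- names(chrom_len)[chrom_len >= len]
      if (!length(eligible)) stop("genome too short to host a window of ", len, " bp")
      pr <- chrom_len[eligible] - len + 1
      while (!found) {
        chunk <- 64L
        ch <- sample(eligible, chunk, replace = TRUE, prob = pr)
        st <- floor(runif(chunk) * (chrom_len[ch] - len)) # 0-based start
        for (j in seq_len(chunk)) {
          cand <- substr(genome[[ch[j]]], st[j] + 1, st[j] + len)
          ok <- !any(taken$chrom == ch[j] & taken$start < st[j] + len &
                       taken$end > st[j]) &&
            abs(gc_content(cand) - gc_i) <= tol_gc &&
            abs(repeat_fraction(cand) - rep_i) <= tol_rep
          if (ok) {
            neg[[i]] <- list(seq = cand, chrom = ch[j], start = st[j],
                             end = st[j] + len)
            taken <- rbind(taken, tibble(chrom = ch[j], start = as.integer(st[j]),
                                         end = as.integer(st[j] + len)))
            found <- TRUE
            break
          }
          rejected <- rejected + 1L
          if (rejected >= max_reject) {
            if (widened >= 4L)
              stop("could not match positive ", ids[i],
                   " even after widening tolerances")
            tol_gc <- tol_gc * 2; tol_rep <- tol_rep * 2
            widened <- widened + 1L; rejected <- 0L
            warning("widening matching tolerances for positive ", ids[i],
                    " (step ", widened, ")", call. = FALSE)
          }
        }
      }
      report[[i]] <- tibble(
        id = ids[i], length = len, gc_pos = gc_i,
        gc_neg = gc_content(neg[[i]]$seq), repeat_pos = rep_i,
        repeat_neg = repeat_fraction(neg[[i]]$seq), widened = widened)
    }
  })
  neg_seqs <- vapply(neg, `[[`, character(1), "seq")
  names(neg_seqs) <- paste0(ids, "_neg")
  out <- list(
    positives = pos_seqs,
    negatives = neg_seqs,
    negative_intervals = tibble(
      chrom = vapply(neg, `[[`, character(1), "chrom"),
      start = vapply(neg, function(x) as.integer(x$start), integer(1)),
      end = vapply(neg, function(x) as.integer(x$end), integer(1)),
      id = names(neg_seqs)),
    report = dplyr::bind_rows(report))
  class(out) <- "training_set"
  out
}

#' Extract interval sequences from a genome
#' @param genome named character vector of chromosome sequences.
#' @param intervals tibble with `chrom, start, end` (0-based half-open).
#' @return Character vector of sequences.
#' @export
extract_sequences <- function(genome, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    substr(genome[[intervals$chrom[i]]], intervals$start[i] + 1,
           intervals$end[i])
  }, character(1))
}

#' Serialize a model to a versioned flat text file
#' @param model a `kmer_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#ehourglass_kmer_model v1",
               sprintf("#L=%d k=%d lambda=%g intercept=%.17g n_pos=%d n_neg=%d stage=%s",
                       model$config$L, model$config$k, model$config$lambda,
                       model$intercept, model$n_pos, model$n_neg, model$stage)),
             con)
  nz <- which(model$w != 0)
  writeLines(sprintf("%d\t%.17g", nz, model$w[nz]), con)
  invisible(path)
}

#' Read a model serialized by [write_kmer_model()]
#' @param path path to the flat file.
#' @return A `kmer_model`.
#' @export
read_kmer_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#ehourglass_kmer_model"))
    stop("not a kmer model file: ", path)
  hdr <- lines[2]
  gv <- function(key, conv = as.numeric) {
    conv(sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr))
  }
  config <- gkm_config(L = gv("L", as.integer), k = gv("k", as.integer),
                       lambda = gv("lambda"))
  info <- gkm_space_info(config$L, config$k)
  w <- numeric(info$n_features)
  body <- lines[-(1:2)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    idx <- as.integer(vapply(parts, `[[`, character(1), 1))
    val <- as.numeric(vapply(parts, `[[`, character(1), 2))
    w[idx] <- val
  }
  model <- list(config = config, w = w, intercept = gv("intercept"),
                stage = gv("stage", as.character),
                n_pos = gv("n_pos", as.integer), n_neg = gv("n_neg", as.integer),
                cache = new.env(parent = emptyenv()))
  class(model) <- "kmer_model"
  model
}

#' Import an externally produced all-L-mers weight table
#'
#' Provides a parity path for weight tables produced by other gapped k-mer
#' implementations: a two-column TSV of word and weight.  Missing words score
#' zero; the reverse complement of each listed word receives the same weight.
#'
#' @param path word TAB weight file (no header).
#' @param L word length.
#' @return A `kmer_model`-like object scoring by direct table lookup.
#' @export
read_weight_table <- function(path, L) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("word", "weight"))
  if (any(nchar(df$word) != L)) stop("all words must have length ", L)
  tab <- numeric(4^L)
  codes <- word_code(df$word) + 1
  tab[codes] <- df$weight
  rc <- word_code(revcomp(df$word)) + 1
  missing_rc <- setdiff(rc, codes)
  tab[rc[!(rc %in% codes)]] <- df$weight[!(rc %in% codes)]
  model <- list(config = gkm_config(L = L, k = max(1L, L - 4L)),
                table = tab, intercept = 0, stage = NA_character_,
                n_pos = NA_integer_, n_neg = NA_integer_,
                external = TRUE, cache = new.env(parent = emptyenv()))
  class(model) <- "kmer_model"
  model
}
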