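#' Infer the ancestral sequence of a focal/sister pair with an outgroup
#'
#' Column-wise parsimony: if focal equals sister the ancestor keeps that base;
#' if they differ and the outgroup sides with the sister, a focal-branch
#' substitution is recorded; if the outgroup sides with the focal, the change
#' is placed on the sister branch (no focal substitution).  Columns with
#' three distinct bases, gaps or ambiguous bases are excluded from
#' substitution calling (ancestor takes the focal base).  The ancestor is
#' reported in focal coordinates: columns where the focal sequence is gapped
#' are dropped.
#'
#' @param triple an `aligned_triple` (focal, sister, outgroup; equal lengths).
#' @return List of class `ancestor_call`: `ancestor` (character, focal
#'   coordinates), `substitutions` (tibble `pos` 0-based, `anc`, `der` bases,
#'   `dinuc` flag), `excluded` (0-based positions excluded from calling),
#'   `n_excluded`.
#' @export
infer_ancestor <- function(triple) {
  stopifnot(inherits(triple, "aligned_triple") ||
              (is.list(triple) && all(c("focal", "sister", "outgroup") %in% names(triple))))
  if (length(unique(nchar(c(triple$focal, triple$sister, triple$outgroup)))) != 1)
    stop("aligned records have unequal lengths")
  f <- strsplit(toupper(triple$focal), "")[[1]]
  s <- strsplit(toupper(triple$sister), "")[[1]]
  o <- strsplit(toupper(triple$outgroup), "")[[1]]
  keep <- f != "-"                       # focal coordinates
  valid <- f %in% DNA_BASES & s %in% DNA_BASES & o %in% DNA_BASES
  anc <- f
  is_sub <- logical(length(f))
  resolved <- valid & (f == s | o == s | o == f)
  anc[resolved & f != s & o == s] <- s[resolved & f != s & o == s]
  is_sub[resolved & f != s & o == s] <- TRUE
  # everything else keeps the focal base and is excluded from calling
  excluded_col <- keep & !resolved
  pos_focal <- cumsum(keep) - 1L         # 0-based focal coordinate per column
  subs_cols <- which(is_sub & keep)
  subs <- tibble(pos = pos_focal[subs_cols],
                 anc = anc[subs_cols], der = f[subs_cols],
                 dinuc = FALSE)
  subs <- subs[order(subs$pos), ]
  out <- list(ancestor = paste(anc[keep], collapse = ""),
              substitutions = subs,
              excluded = pos_focal[excluded_col],
              n_excluded = sum(excluded_col))
  class(out) <- "ancestor_call"
  flag_dinucleotides(out)
}

#' Flag dinucleotide (adjacent) substitutions in an ancestor call
#'
#' A substitution is flagged iff another substitution exists at an adjacent
#' position (distance exactly 1); runs of adjacent substitutions are all
#' flagged.
#'
#' @param call an `ancestor_call`.
#' @return The call with updated `dinuc` flags.
#' @export
flag_dinucleotides <- function(call) {
  p <- call$substitutions$pos
  if (length(p) >= 2) {
    adj <- c(diff(p) == 1, FALSE) | c(FALSE, diff(p) == 1)
    call$substitutions$dinuc <- adj
  } else if (length(p)) {
    call$substitutions$dinuc <- FALSE
  }
  call
}

#' Pooled substitution spectrum over a set of ancestor calls
#'
#' Rates follow the opportunity convention: rate(X to Y) = count(X to Y)
#' substitutions divided by the count of ancestral base X, split by CpG
#' context (the ancestral base participates in a CG dinucleotide in the
#' ancestor, either position).  The transition/transversion ratio is
#' opportunity-normalized: (transitions / transition opportunities) /
#' (transversions / transversion opportunities), with one transition and two
#' transversion opportunities per ancestral base.
#'
#' @param calls list of `ancestor_call`s.
#' @return List of class `substitution_spectrum`: `rates` (4 x 4 x 2 array,
#'   contexts `nonCpG`/`CpG`, NA where opportunities are zero), `counts`,
#'   `opportunities`, `ts_tv_ratio`.
#' @export
estimate_spectrum <- function(calls) {
  if (!length(calls)) stop("need at least one ancestor call")
  counts <- array(0, c(4, 4, 2), dimnames = list(DNA_BASES, DNA_BASES,
                                                 c("nonCpG", "CpG")))
  opp <- matrix(0, 4, 2, dimnames = list(DNA_BASES, c("nonCpG", "CpG")))
  for (call in calls) {
    codes <- encode_dna(call$ancestor)
    n <- length(codes)
    cpg <- logical(n)
    if (n >= 2) {
      is_cg <- codes[-n] == 1L & codes[-1] == 2L   # C then G
      cpg[which(is_cg)] <- TRUE
      cpg[which(is_cg) + 1L] <- TRUE
    }
    for (b in 1:4) {
      opp[b, "nonCpG"] <- opp[b, "nonCpG"] + sum(codes == b - 1L & !cpg)
      opp[b, "CpG"] <- opp[b, "CpG"] + sum(codes == b - 1L & cpg)
    }
    subs <- call$substitutions
    if (nrow(subs)) {
      ctx <- ifelse(cpg[subs$pos + 1L], "CpG", "nonCpG")
      for (i in seq_len(nrow(subs)))
        counts[subs$anc[i], subs$der[i], ctx[i]] <-
          counts[subs$anc[i], subs$der[i], ctx[i]] + 1
    }
  }
  rates <- counts
  for (ctx in 1:2) rates[, , ctx] <- sweep(counts[, , ctx], 1, opp[, ctx], "/")
  for (b in 1:4) rates[b, b, ] <- NA
  pooled <- counts[, , 1] + counts[, , 2]
  ts_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n_ts <- sum(pooled[ts_pairs])
  n_tv <- sum(pooled) - n_ts - sum(diag(pooled))
  total_opp <- sum(opp)
  ts_tv <- if (n_tv == 0 || total_opp == 0) NA_real_ else
    (n_ts / total_opp) / (n_tv / (2 * total_opp))
  out <- list(rates = rates, counts = counts, opportunities = opp,
              ts_tv_ratio = ts_tv)
  class(out) <- "substitution_spectrum"
  out
}

# applied substitutions of a call under the exclusion mode
applied_subs <- function(call, exclude_dinucleotides) {
  subs <- call$substitutions
  if (exclude_dinucleotides) subs <- subs[!subs$dinuc, ]
  subs
}

#' deltaSVM of an enhancer's focal-branch substitutions
#'
#' The sum of model weights over all L-mers of the focal sequence minus the
#' sum over the ancestor sequence (the intercept cancels); positive values
#' mean the substitutions increase predicted accessibility.  With
#' `exclude_dinucleotides`, flagged substitutions are neither applied nor
#' counted.
#'
#' @param model a `kmer_model`.
#' @param call an `ancestor_call`.
#' @param exclude_dinucleotides drop adjacent-substitution pairs.
#' @return Numeric deltaSVM with attributes `n_substitutions` and
#'   `no_substitution` (TRUE when nothing was applied, value 0).
#' @export
delta_svm <- function(model, call, exclude_dinucleotides = FALSE) {
  subs <- applied_subs(call, exclude_dinucleotides)
  if (nrow(subs) == 0) {
    return(structure(0, n_substitutions = 0L, no_substitution = TRUE))
  }
  anc <- call$ancestor
  focal <- apply_subs_chr(anc, subs)
  d <- score_sequences(model, focal) - score_sequences(model, anc)
  structure(d, n_substitutions = nrow(subs), no_substitution = FALSE)
}

# apply character substitutions (tibble pos/der in bases) to a sequence
apply_subs_chr <- function(seq, subs) {
  v <- strsplit(seq, "")[[1]]
  v[subs$pos + 1L] <- subs$der
  paste(v, collapse = "")
}

# alternative-base cumulative sampling weights per ancestral base code (0..3)
# rows: ancestral base; cols: the three alternatives in fixed order
alt_base_matrix <- function() {
  t(vapply(0:3, function(b) setdiff(0:3, b), integer(3)))
}

alt_base_weights <- function(base_sampling, spectrum = NULL, kappa = 3) {
  alts <- alt_base_matrix()
  w <- matrix(1, 4, 3)
  if (base_sampling == "ts_tv_weighted") {
    ts <- c(2L, 1L, 0L, 3L)  # transition partner of A, C, G, T
    for (b in 1:4) w[b, ] <- ifelse(alts[b, ] == ts[b], kappa, 1)
  } else if (base_sampling == "spectrum") {
    if (is.null(spectrum)) stop("spectrum sampling needs an estimated spectrum")
    pooled <- spectrum$counts[, , 1] + spectrum$counts[, , 2]
    for (b in 1:4) {
      row <- pooled[b, alts[b, ] + 1L]
      if (sum(row) == 0) row <- rep(1, 3)
      w[b, ] <- row
    }
  }
  w / rowSums(w)
}

#' Empirical null distribution of deltaSVM for one enhancer
#'
#' Each permutation draws the observed number of substitutions at distinct
#' positions sampled uniformly from the non-excluded ancestor positions and,
#' per position, an alternative base: uniform over the three alternatives
#' (`"uniform"`), transition weighted `kappa`-fold over each transversion
#' (`"ts_tv_weighted"`, default 3:1), or proportional to the estimated
#' substitution spectrum row (`"spectrum"`).  The deltaSVM of each
#' pseudo-focal sequence is computed against the ancestor.
#'
#' @param model a `kmer_model`.
#' @param call an `ancestor_call` with at least 2 applied substitutions.
#' @param n_permutations number of permutations (default 10000).
#' @param base_sampling null base-sampling mode.
#' @param spectrum a `substitution_spectrum` (for `"spectrum"` mode).
#' @param kappa transition weight for `"ts_tv_weighted"` (default 3).
#' @param exclude_dinucleotides match the observed statistic's exclusion mode.
#' @param seed integer seed; the null is deterministic in it.
#' @param keep_deltas return the full null sample.
#' @return List: `observed`, `n_substitutions`, `n_permutations`,
#'   `exceed_upper` (# null >= observed), `exceed_lower`, and `deltas` (if
#'   kept).
#' @export
null_distribution <- function(model, call, n_permutations = 10000,
                              base_sampling = c("uniform", "ts_tv_weighted", "spectrum"),
                              spectrum = NULL, kappa = 3,
                              exclude_dinucleotides = FALSE, seed = 1L,
                              keep_deltas = FALSE) {
  base_sampling <- match.arg(base_sampling)
  subs <- applied_subs(call, exclude_dinucleotides)
  n_sub <- nrow(subs)
  if (n_sub < 2) stop("need at least two applied substitutions")
  anc_codes <- encode_dna(call$ancestor)
  eligible <- setdiff(which(anc_codes >= 0L) - 1L, call$excluded)
  if (length(eligible) < n_sub)
    stop("ancestor has fewer eligible positions than substitutions")
  obs <- as.numeric(delta_svm(model, call, exclude_dinucleotides))
  alts <- alt_base_matrix()
  w <- alt_base_weights(base_sampling, spectrum, kappa)
  tab <- weight_table(model)
  deltas <- with_seed(seed, {
    pos <- t(vapply(seq_len(n_permutations),
                    function(i) eligible[sample.int(length(eligible), n_sub)],
                    integer(n_sub)))
    anc_at <- matrix(anc_codes[pos + 1L], nrow = n_permutations)
    pick <- matrix(0L, n_permutations, n_sub)
    for (b in 0:3) {
      idx <- which(anc_at == b)
      if (!length(idx)) next
      choice <- sample.int(3L, length(idx), replace = TRUE, prob = w[b + 1L, ])
      pick[idx] <- alts[b + 1L, choice]
    }
    as.numeric(gkm_delta_batch_cpp(anc_codes, tab, model$config$L, pos, pick))
  })
  list(observed = obs, n_substitutions = n_sub,
       n_permutations = n_permutations,
       exceed_upper = sum(deltas >= obs),
       exceed_lower = sum(deltas <= obs),
       deltas = if (keep_deltas) deltas else NULL)
}

#' Positive-selection test over a set of enhancers
#'
#' For each enhancer with at least `min_substitutions` applied substitutions,
#' compares the observed deltaSVM with its empirical null.  Empirical
#' p-values use the (r + 1)/(N + 1) estimator (never 0); q-values are
#' Benjamini-Hochberg within the tested set and `positive_call` is
#' `q < q_threshold`.
#'
#' @param model a `kmer_model` trained on the same stage's enhancers.
#' @param calls named list of `ancestor_call`s.
#' @param n_permutations permutations per enhancer (default 10000).
#' @param min_substitutions minimum applied substitutions (default 2, counted
#'   after dinucleotide exclusion when that mode is on).
#' @param tail `"upper"` (selection for stronger accessibility), `"lower"`,
#'   or `"two_sided"` (doubled smaller tail, capped at 1).
#' @param base_sampling,spectrum,kappa,exclude_dinucleotides passed to
#'   [null_distribution()].
#' @param q_threshold q-value threshold for `positive_call` (default 0.05).
#' @param seed root seed; each enhancer's null uses a named substream.
#' @return Tibble of class `selection_test_result` (one row per tested
#'   enhancer): `enhancer_id, n_substitutions, observed_delta,
#'   null_exceed_count, n_permutations, p_value, q_value, positive_call`;
#'   attribute `n_dropped` counts enhancers below the substitution minimum.
#' @export
test_enhancers <- function(model, calls, n_permutations = 10000,
                           min_substitutions = 2,
                           tail = c("upper", "lower", "two_sided"),
                           base_sampling = "uniform", spectrum = NULL,
                           kappa = 3, exclude_dinucleotides = FALSE,
                           q_threshold = 0.05, seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(!is.null(names(calls)))
  rows <- list()
  n_dropped <- 0L
  for (id in names(calls)) {
    call <- calls[[id]]
    n_sub <- nrow(applied_subs(call, exclude_dinucleotides))
    if (n_sub < min_substitutions) { n_dropped <- n_dropped + 1L; next }
    nd <- null_distribution(model, call, n_permutations = n_permutations,
                            base_sampling = base_sampling, spectrum = spectrum,
                            kappa = kappa,
                            exclude_dinucleotides = exclude_dinucleotides,
                            seed = substream_seed(seed, paste0("null_", id)))
    p_up <- (nd$exceed_upper + 1) / (n_permutations + 1)
    p_lo <- (nd$exceed_lower + 1) / (n_permutations + 1)
    p <- switch(tail, upper = p_up, lower = p_lo,
                two_sided = min(1, 2 * min(p_up, p_lo)))
    rows[[id]] <- tibble(
      enhancer_id = id, n_substitutions = n_sub,
      observed_delta = nd$observed,
      null_exceed_count = switch(tail, upper = nd$exceed_upper,
                                 lower = nd$exceed_lower,
                                 two_sided = min(nd$exceed_upper, nd$exceed_lower)),
      n_permutations = n_permutations, p_value = p)
  }
  if (!length(rows)) {
    out <- tibble(enhancer_id = character(), n_substitutions = integer(),
                  observed_delta = numeric(), null_exceed_count = integer(),
                  n_permutations = integer(), p_value = numeric(),
                  q_value = numeric(), positive_call = logical())
  } else {
    out <- dplyr::bind_rows(rows)
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out$positive_call <- out$q_value < q_threshold
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("selection_test_result", class(out))
  out
}

#' Proportion of positive-selection calls by group
#'
#' @param results a `selection_test_result` tibble.
#' @param groups tibble with `enhancer_id` and `group` covering every tested
#'   enhancer.
#' @param reference optional reference group for pairwise Fisher exact tests.
#' @return Tibble: `group, n, n_positive, proportion`, plus `fisher_p` /
#'   `fisher_q` versus the reference when given.
#' @export
positive_proportion_by_group <- function(results, groups, reference = NULL) {
  stopifnot(all(c("enhancer_id", "group") %in% names(groups)))
  merged <- dplyr::inner_join(as_tibble(results), groups, by = "enhancer_id")
  tab <- dplyr::summarise(dplyr::group_by(merged, .data$group),
                          n = dplyr::n(),
                          n_positive = sum(.data$positive_call),
                          .groups = "drop")
  tab$proportion <- ifelse(tab$n == 0, NA_real_, tab$n_positive / tab$n)
  if (!is.null(reference)) {
    cmp <- compare_stage_proportions(
      tibble(stage = tab$group, k = tab$n_positive, n = tab$n),
      reference = reference)
    tab$fisher_p <- cmp$fisher_p
    tab$fisher_q <- cmp$fisher_q
  }
  tab
}

#' Cross-fitted positive-selection scan for one stage
#'
#' Training a model on the very enhancers being tested memorizes their
#' k-mers and inflates score(focal) over score(ancestor), making the
#' upper-tail test anticonservative.  This scan therefore splits the stage's
#' enhancers into folds and scores each fold with a model trained on the
#' remaining folds' positives (and their matched negatives); p-values are
#' pooled and Benjamini-Hochberg corrected across the stage.
#'
#' @param positives named character vector of enhancer sequences (names are
#'   enhancer ids).
#' @param negatives matched negative sequences (same length as `positives`;
#'   negative i is the match of positive i).
#' @param calls named list of `ancestor_call`s covering the same ids.
#' @param config a [gkm_config()].
#' @param folds number of cross-fitting folds (default 3).
#' @param seed root seed (fold assignment and per-enhancer nulls).
#' @param ... further arguments passed to [test_enhancers()]
#'   (`n_permutations`, `tail`, `base_sampling`, ...).
#' @param q_threshold q-value threshold for `positive_call` (default 0.05).
#' @return A `selection_test_result` tibble as from [test_enhancers()], plus
#'   a `fold` column; attribute `models` holds the per-fold models.
#' @export
cross_fit_test <- function(positives, negatives, calls, config = gkm_config(),
                           folds = 3L, seed = 1L, q_threshold = 0.05, ...) {
  ids <- names(positives)
  stopifnot(!is.null(ids), length(negatives) == length(positives),
            all(names(calls) %in% ids))
  fold_id <- with_seed(substream_seed(seed, "folds"),
                       sample(rep(seq_len(folds), length.out = length(ids))))
  names(fold_id) <- ids
  # featurize the whole training set once; folds refit on row subsets
  X <- featurize(c(positives, negatives), config)
  Xn <- normalize_rows(X)
  y <- rep(c(1, -1), c(length(positives), length(negatives)))
  rows <- list()
  models <- list()
  n_dropped <- 0L
  for (f in seq_len(folds)) {
    tr <- rep(fold_id != f, 2)
    fit <- fit_ridge_dual(Xn[tr, , drop = FALSE], y[tr], config$lambda)
    model <- structure(
      list(config = config, w = fit$w, intercept = fit$intercept,
           stage = NA_character_, n_pos = sum(fold_id != f),
           n_neg = sum(fold_id != f),
           cache = new.env(parent = emptyenv())),
      class = "kmer_model")
    models[[f]] <- model
    test_ids <- intersect(ids[fold_id == f], names(calls))
    if (!length(test_ids)) next
    res <- test_enhancers(model, calls[test_ids], q_threshold = q_threshold,
                          seed = substream_seed(seed, paste0("fold", f)), ...)
    n_dropped <- n_dropped + attr(res, "n_dropped")
    if (nrow(res)) {
      res$fold <- f
      rows[[f]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out$positive_call <- out$q_value < q_threshold
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "models") <- models
  class(out) <- c("selection_test_result", class(out))
  out
}
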