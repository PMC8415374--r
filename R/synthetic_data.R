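#' Generate a set of position weight matrices with a target information content
#'
#' Each PWM column is a single-preferred-base distribution whose major-base
#' probability is solved so the column's information content (2 + sum p log2 p
#' bits) hits a jittered target; the mean per-column IC lands within 0.2 bits
#' of `ic_target`.
#'
#' @param n_motifs number of motifs (>= 1).
#' @param width motif width in bp (>= 6).
#' @param ic_target target mean per-column information content in bits
#'   (0 < ic_target <= 2).
#' @param seed integer seed; generation is deterministic in it.
#' @return List of class `motif_set` with elements `motifs` (list of 4 x width
#'   probability matrices, rows ACGT), `information_content` (mean bits per
#'   motif), and `seed`.
#' @export
make_motifs <- function(n_motifs, width, ic_target, seed) {
  if (n_motifs < 1) stop("n_motifs must be >= 1")
  if (width < 6) stop("width must be >= 6")
  if (ic_target > 2 || ic_target <= 0)
    stop("ic_target must be in (0, 2] bits per column")
  column_for_ic <- function(ic, major) {
    f <- function(x) 2 + x * log2(x) + (1 - x) * log2((1 - x) / 3) - ic
    x <- uniroot(f, c(0.2500001, 0.9999999), tol = 1e-12)$root
    p <- rep((1 - x) / 3, 4)
    p[major] <- x
    p
  }
  with_seed(seed, {
    motifs <- lapply(seq_len(n_motifs), function(m) {
      ic_cols <- pmin(1.98, pmax(0.05, rnorm(width, ic_target, 0.08)))
      ic_cols <- ic_cols - (mean(ic_cols) - ic_target)  # recentre the mean
      ic_cols <- pmin(1.98, pmax(0.05, ic_cols))
      majors <- sample.int(4, width, replace = TRUE)
      pwm <- vapply(seq_len(width), function(j) column_for_ic(ic_cols[j], majors[j]),
                    numeric(4))
      rownames(pwm) <- DNA_BASES
      pwm
    })
    out <- list(motifs = motifs,
                information_content = vapply(motifs, function(p) {
                  mean(2 + colSums(p * log2(p)))
                }, numeric(1)),
                seed = as.integer(seed))
    class(out) <- "motif_set"
    out
  })
}

#' Ground-truth accessibility score of sequences
#'
#' Sum over motifs of the best (max over positions and strands) log2-odds
#' match against a uniform background.  This scorer is deliberately distinct
#' from the gapped k-mer model so that classifier performance is a genuine
#' generalization test.
#'
#' @param seqs character vector of sequences.
#' @param motifs a `motif_set`.
#' @return Numeric score per sequence (bits).
#' @export
true_score <- function(seqs, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  logodds <- lapply(motifs$motifs, function(p) log2(pmax(p, 1e-12) / 0.25))
  vapply(seqs, function(s) {
    pwm_true_score_cpp(encode_dna(s), logodds)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate an enhancer sequence with planted motif instances
#'
#' Background bases are drawn i.i.d. at the requested GC content; `n_sites`
#' motif instances are sampled from the PWMs and planted at non-overlapping
#' positions (random strand).
#'
#' @param motifs a `motif_set`.
#' @param length sequence length in bp (>= 10 x motif width).
#' @param gc background GC content, in (0, 1).
#' @param n_sites number of planted motif instances.
#' @param seed integer seed.
#' @return List with `seq` (character) and `sites` (tibble of planted
#'   intervals: `start`, `end` 0-based half-open, `motif`, `strand`).
#' @export
make_enhancer <- function(motifs, length, gc, n_sites, seed) {
  stopifnot(inherits(motifs, "motif_set"))
  w <- ncol(motifs$motifs[[1]])
  if (length < 10 * w) stop("length must be >= 10 x motif width")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (n_sites * w > length) stop("n_sites x width exceeds sequence length")
  with_seed(seed, {
    p_bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    codes <- sample.int(4, length, replace = TRUE, prob = p_bg) - 1L
    sites <- tibble(start = integer(), end = integer(), motif = integer(),
                    strand = character())
    if (n_sites > 0) {
      placed <- 0L; tries <- 0L
      while (placed < n_sites) {
        if ((tries <- tries + 1L) > 1000L * n_sites)
          stop("could not place ", n_sites, " non-overlapping sites")
        st <- sample.int(length - w + 1L, 1L) - 1L
        if (any(st < sites$end & st + w > sites$start)) next
        m <- sample.int(base::length(motifs$motifs), 1L)
        strand <- sample(c("+", "-"), 1L)
        pwm <- motifs$motifs[[m]]
        inst <- vapply(seq_len(w), function(j) {
          sample.int(4, 1L, prob = pwm[, j]) - 1L
        }, integer(1))
        if (strand == "-") inst <- rev(3L - inst)
        codes[(st + 1L):(st + w)] <- inst
        sites <- dplyr::bind_rows(sites, tibble(start = st, end = st + w,
                                                motif = m, strand = strand))
        placed <- placed + 1L
      }
    }
    list(seq = decode_dna(codes), sites = sites[order(sites$start), ])
  })
}

#' Evolution parameters for a three-species enhancer triple
#'
#' @param branch_focal,branch_sister,branch_outgroup expected substitutions
#'   per site on each branch from the common ancestor (defaults 0.05/0.05/0.12,
#'   the within-group divergence regime of a focal/sister pair with a close
#'   outgroup).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param selection_mode `"neutral"`, `"up"` (selection for stronger
#'   accessibility on the focal branch), or `"down"`.
#' @param selection_strength nonnegative; must be 0 iff mode is neutral.
#' @param drift_threshold effect size (bits) below which drift dominates:
#'   proposed substitutions fix with probability
#'   `plogis(strength * (effect - drift_threshold))`, so near-neutral changes
#'   fix rarely under strong selection while beneficial ones fix almost
#'   surely.
#' @param dinuc_fraction fraction of focal-branch substitutions injected as
#'   adjacent pairs (exercises the dinucleotide-exclusion control).
#' @param seed integer seed.
#' @return List of class `evolution_params`.
#' @export
evolution_params <- function(branch_focal = 0.05, branch_sister = 0.05,
                             branch_outgroup = 0.12, kappa = 3,
                             selection_mode = c("neutral", "up", "down"),
                             selection_strength = 0, drift_threshold = 0.5,
                             dinuc_fraction = 0, seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  if (branch_focal <= 0 || branch_sister <= 0 || branch_outgroup <= 0)
    stop("branch lengths must be > 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if ((selection_strength == 0) != (selection_mode == "neutral"))
    stop("selection_strength must be 0 iff selection_mode is neutral")
  structure(list(branch_focal = branch_focal, branch_sister = branch_sister,
                 branch_outgroup = branch_outgroup, kappa = kappa,
                 selection_mode = selection_mode,
                 selection_strength = selection_strength,
                 drift_threshold = drift_threshold,
                 dinuc_fraction = dinuc_fraction, seed = as.integer(seed)),
            class = "evolution_params")
}

# draw an alternative base: transition with relative weight kappa, each
# transversion with weight 1.  transitions: A<->G (0,2), C<->T (1,3)
draw_alt_base <- function(base, kappa) {
  ts <- c(2L, 3L, 0L, 1L)[base + 1L]
  tv <- setdiff(0:3, c(base, ts))
  alts <- c(ts, tv)
  alts[sample.int(3L, 1L, prob = c(kappa, 1, 1))]
}

# fixed-count neutral substitution process on one branch
neutral_branch_subs <- function(codes, branch_length, kappa, n_subs = NULL,
                                dinuc_fraction = 0) {
  len <- length(codes)
  n <- n_subs %||% min(len, rpois(1, branch_length * len))
  if (n == 0)
    return(tibble(pos = integer(), anc = integer(), der = integer()))
  n_pair <- floor(n * dinuc_fraction / 2)
  pos <- integer(0)
  if (n_pair > 0) {
    while (length(pos) < 2 * n_pair) {
      p <- sample.int(len - 1L, 1L) - 1L
      if (!any(c(p, p + 1L) %in% pos)) pos <- c(pos, p, p + 1L)
    }
  }
  n_single <- n - 2L * n_pair
  free <- setdiff(seq_len(len) - 1L, pos)
  pos <- c(pos, free[sample.int(length(free), min(n_single, length(free)))])
  der <- vapply(pos, function(p) draw_alt_base(codes[p + 1L], kappa), integer(1))
  tibble(pos = as.integer(pos), anc = codes[pos + 1L], der = der)
}

# selection on the focal branch: propose substitutions sequentially and accept
# with the sigmoid fixation probability plogis(strength * (sign * delta -
# drift_threshold)), resampling until the target count is reached; the drift
# threshold makes near-neutral proposals fix rarely when selection is strong
selected_branch_subs <- function(codes, branch_length, kappa, strength, sign,
                                 scorer, drift_threshold = 0.5,
                                 n_subs = NULL) {
  len <- length(codes)
  n <- n_subs %||% min(len, rpois(1, branch_length * len))
  current <- codes
  current_str <- decode_dna(codes)
  sub_pos <- integer(0); sub_der <- integer(0)
  score_now <- scorer(current_str)
  tries <- 0L
  while (length(sub_pos) < n) {
    if ((tries <- tries + 1L) > 10000L * max(1L, n))
      stop("selection simulation failed to reach the target substitution count")
    p <- sample.int(len, 1L) - 1L
    if (p %in% sub_pos) next
    alt <- draw_alt_base(current[p + 1L], kappa)
    prop_str <- current_str
    substr(prop_str, p + 1L, p + 1L) <- DNA_BASES[alt + 1L]
    delta <- scorer(prop_str) - score_now
    if (runif(1) < stats::plogis(strength * (sign * delta - drift_threshold))) {
      sub_pos <- c(sub_pos, p)
      sub_der <- c(sub_der, alt)
      current[p + 1L] <- alt
      current_str <- prop_str
      score_now <- score_now + delta
    }
  }
  ord <- order(sub_pos)
  tibble(pos = as.integer(sub_pos[ord]), anc = codes[sub_pos[ord] + 1L],
         der = sub_der[ord])
}

apply_subs <- function(codes, subs) {
  if (nrow(subs)) codes[subs$pos + 1L] <- subs$der
  codes
}

#' Evolve an ancestral enhancer into a focal/sister/outgroup aligned triple
#'
#' The outgroup, focal, and sister sequences each evolve independently from
#' the ancestor by a fixed-count conditional substitution process (count drawn
#' from the branch length, positions distinct, alternative base drawn with
#' transition weight kappa).  Under `selection_mode = "up"` (`"down"`),
#' proposed focal-branch substitutions are accepted with probability
#' increasing (decreasing) in their effect on the true accessibility score,
#' resampling until the target count is reached.  Substitutions only - no
#' indels - so all sequences keep the ancestral length.
#'
#' @param ancestral ancestral sequence (no gap characters).
#' @param params an [evolution_params()].
#' @param true_scorer function(sequence) -> numeric accessibility; required
#'   for non-neutral modes.
#' @param n_focal_subs optional fixed focal-branch substitution count
#'   (otherwise drawn from the branch length).
#' @return An `aligned_triple` with attributes `substitutions` (true
#'   focal-branch substitution tibble: `pos`, `anc`, `der` base codes) and
#'   `ancestor`.
#' @export
evolve_triple <- function(ancestral, params, true_scorer = NULL,
                          n_focal_subs = NULL) {
  stopifnot(inherits(params, "evolution_params"))
  if (grepl("-", ancestral, fixed = TRUE)) stop("ancestral sequence has gaps")
  codes <- encode_dna(ancestral)
  if (any(codes < 0)) stop("ancestral sequence must be ACGT only")
  if (params$selection_mode != "neutral" && is.null(true_scorer))
    stop("non-neutral modes need a true_scorer")
  with_seed(params$seed, {
    out_subs <- neutral_branch_subs(codes, params$branch_outgroup, params$kappa)
    sis_subs <- neutral_branch_subs(codes, params$branch_sister, params$kappa)
    foc_subs <- if (params$selection_mode == "neutral") {
      neutral_branch_subs(codes, params$branch_focal, params$kappa,
                          n_subs = n_focal_subs,
                          dinuc_fraction = params$dinuc_fraction)
    } else {
      selected_branch_subs(codes, params$branch_focal, params$kappa,
                           params$selection_strength,
                           if (params$selection_mode == "up") 1 else -1,
                           true_scorer,
                           drift_threshold = params$drift_threshold %||% 0.5,
                           n_subs = n_focal_subs)
    }
    triple <- as_aligned_triple(c(
      decode_dna(apply_subs(codes, foc_subs)),
      decode_dna(apply_subs(codes, sis_subs)),
      decode_dna(apply_subs(codes, out_subs))))
    attr(triple, "substitutions") <- foc_subs[order(foc_subs$pos), ]
    attr(triple, "ancestor") <- ancestral
    triple
  })
}

#' Simulate per-enhancer polymorphism counts
#'
#' Neutral enhancers receive SNP counts ~ Poisson(theta x length); enhancers
#' under positive selection receive Poisson(theta x length x sweep_factor),
#' emulating the polymorphism deficit left by a selective sweep.
#'
#' @param triples named list of `aligned_triple`s (names are enhancer ids).
#' @param truth tibble with columns `id` and `selection` (`"neutral"` or a
#'   selected mode) covering every triple.
#' @param theta per-bp pairwise diversity (> 0).
#' @param sweep_factor multiplier in (0, 1] applied to selected enhancers.
#' @param seed integer seed.
#' @return `snp_table` tibble (`enhancer_id`, `n_snps`).
#' @export
make_polymorphisms <- function(triples, truth, theta, sweep_factor, seed = 1L) {
  if (theta <= 0) stop("theta must be > 0")
  if (sweep_factor <= 0 || sweep_factor > 1) stop("sweep_factor must be in (0, 1]")
  ids <- names(triples)
  stopifnot(!is.null(ids), all(ids %in% truth$id))
  len <- vapply(triples, function(t) nchar(t$focal), numeric(1))
  if (any(len == 0)) stop("zero-length enhancer sequence")
  sel <- truth$selection[match(ids, truth$id)] != "neutral"
  with_seed(seed, {
    mu <- theta * len * ifelse(sel, sweep_factor, 1)
    out <- tibble(enhancer_id = ids, n_snps = rpois(length(ids), mu))
    attr(out, "granularity") <- "counts"
    class(out) <- c("snp_table", class(out))
    out
  })
}
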