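#' @title Stage-specificity, orthologous translation and conservation calling
#'
#' @description
#' The overlap predicate everywhere is ">= 1 bp" on 0-based half-open
#' intervals: touching intervals do not overlap.
#' @name conservation
NULL

# IRanges helper: 0-based half-open -> 1-based closed
as_ir <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}

# per-chromosome >=1bp overlap hits between two interval tibbles;
# returns a two-column matrix of row indices (query, subject)
overlap_pairs <- function(a, b) {
  hits <- list()
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    if (!length(ai) || !length(bi)) next
    ov <- IRanges::findOverlaps(as_ir(a[ai, ]), as_ir(b[bi, ]), minoverlap = 1L)
    if (length(ov))
      hits[[ch]] <- cbind(ai[S4Vectors::queryHits(ov)],
                          bi[S4Vectors::subjectHits(ov)])
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}

#' Keep distal peaks (putative enhancers) far from any TSS
#'
#' A peak is kept iff its minimum distance from every TSS point exceeds
#' `min_tss_distance` (strict).  Distance between a point and an interval is
#' 0 if the point lies inside, otherwise the gap to the nearest edge.
#'
#' @param peaks interval tibble (`chrom, start, end`, ...).
#' @param tss_annotation tibble of TSS points with `chrom` and `pos` (or
#'   `start`, used as the point).
#' @param min_tss_distance minimum distance in bp (default 500).
#' @return The distal subset of `peaks`.
#' @export
classify_distal <- function(peaks, tss_annotation, min_tss_distance = 500) {
  if (is.null(tss_annotation) || nrow(tss_annotation) == 0) {
    warning("empty TSS annotation: keeping all peaks")
    return(peaks)
  }
  pos <- tss_annotation$pos %||% tss_annotation$start
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    p <- pos[tss_annotation$chrom == peaks$chrom[i]]
    if (!length(p)) return(TRUE)
    d <- ifelse(p >= peaks$end[i], p - peaks$end[i],
                ifelse(p < peaks$start[i], peaks$start[i] - p, 0))
    min(d) > min_tss_distance
  }, logical(1))
  peaks[keep, ]
}

#' Call stage-specific peaks across the five stages of one species
#'
#' A peak is specific to its stage iff it overlaps (>= 1 bp) no peak of any
#' other stage; `n_stages_active` is 1 plus the number of other stages with
#' at least one overlapping peak.
#'
#' @param peak_sets interval tibble with a `stage` column covering all five
#'   stages (one species).
#' @return `peak_sets` with added columns `n_stages_active` and `specific`
#'   (logical), plus `specific_to` (the stage for specific peaks, NA else).
#' @export
call_stage_specific <- function(peak_sets) {
  stopifnot("stage" %in% names(peak_sets))
  assert_stage(unique(peak_sets$stage))
  if (!setequal(unique(peak_sets$stage), STAGES))
    stop("all five stages must be present; missing: ",
         paste(setdiff(STAGES, unique(peak_sets$stage)), collapse = ", "))
  n_other <- integer(nrow(peak_sets))
  for (st in STAGES) {
    qi <- which(peak_sets$stage == st)
    if (!length(qi)) next
    other <- peak_sets[peak_sets$stage != st, ]
    hits <- overlap_pairs(peak_sets[qi, ], other)
    if (nrow(hits)) {
      stages_hit <- tapply(other$stage[hits[, 2]], hits[, 1],
                           function(s) length(unique(s)))
      n_other[qi[as.integer(names(stages_hit))]] <- as.integer(stages_hit)
    }
  }
  out <- peak_sets
  out$n_stages_active <- 1L + n_other
  out$specific <- n_other == 0L
  out$specific_to <- ifelse(out$specific, out$stage, NA_character_)
  out
}

#' Temporal pleiotropy: per-stage usage histogram and adjacent-stage sharing
#'
#' For each stage, the fraction of its peaks used in 1..5 stages (usage = 1 +
#' number of other stages with a >= 1 bp overlapping peak), and for TP2-TP4
#' the fraction of peaks shared with both, one, or neither adjacent stage.
#'
#' @param peak_sets interval tibble with a `stage` column (one species).
#' @return List with `usage` (tibble: stage, n_stages_used, fraction) and
#'   `adjacent` (tibble: stage, adjacent_usage, fraction).
#' @export
temporal_pleiotropy <- function(peak_sets) {
  called <- call_stage_specific(peak_sets)
  usage <- dplyr::count(called, .data$stage, .data$n_stages_active)
  usage <- dplyr::mutate(dplyr::group_by(usage, .data$stage),
                         fraction = .data$n / sum(.data$n))
  usage <- dplyr::rename(dplyr::ungroup(usage), n_stages_used = "n_stages_active")
  adj <- list()
  for (st in c("TP2", "TP3", "TP4")) {
    i <- match(st, STAGES)
    qi <- which(peak_sets$stage == st)
    prev <- peak_sets[peak_sets$stage == STAGES[i - 1], ]
    nxt <- peak_sets[peak_sets$stage == STAGES[i + 1], ]
    in_prev <- logical(length(qi)); in_next <- logical(length(qi))
    h1 <- overlap_pairs(peak_sets[qi, ], prev)
    h2 <- overlap_pairs(peak_sets[qi, ], nxt)
    in_prev[unique(h1[, 1])] <- TRUE
    in_next[unique(h2[, 1])] <- TRUE
    n_adj <- in_prev + in_next
    adj[[st]] <- tibble(
      stage = st,
      adjacent_usage = c("both", "one", "neither"),
      fraction = c(mean(n_adj == 2), mean(n_adj == 1), mean(n_adj == 0)))
  }
  list(usage = usage, adjacent = dplyr::bind_rows(adj))
}

#' Translate intervals through a cross-species alignment block map
#'
#' Every aligned base of the interval is projected through the blocks; the
#' result is the span from first to last mapped base on the target species,
#' with the mapped-base count.  With `require_unique` (the default,
#' "one-to-one orthologous region" behavior), intervals whose mapped bases
#' land on more than one target chromosome, on both strands, or out of
#' colinear order are reported as unmapped.
#'
#' @param intervals interval tibble on species A of the map.
#' @param block_map a `block_map` (A -> B).
#' @param require_unique enforce one-to-one colinear mapping (default TRUE).
#' @return Tibble with one row per input interval: `chrom, start, end, strand,
#'   mapped_bases, mapped` (chrom/start/end NA when unmapped).
#' @export
translate <- function(intervals, block_map, require_unique = TRUE) {
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    bl <- block_map[block_map$chromA == iv$chrom &
                      block_map$startA < iv$end & block_map$endA > iv$start, ]
    none <- tibble(chrom = NA_character_, start = NA_integer_,
                   end = NA_integer_, strand = NA_character_,
                   mapped_bases = 0L, mapped = FALSE)
    if (!nrow(bl)) return(none)
    segs <- lapply(seq_len(nrow(bl)), function(j) {
      s <- max(iv$start, bl$startA[j]); e <- min(iv$end, bl$endA[j])
      if (bl$strand[j] == "+") {
        bs <- bl$startB[j] + (s - bl$startA[j])
        tibble(chrom = bl$chromB[j], start = bs, end = bs + (e - s),
               strand = "+")
      } else {
        be <- bl$endB[j] - (s - bl$startA[j])
        tibble(chrom = bl$chromB[j], start = be - (e - s), end = be,
               strand = "-")
      }
    })
    segs <- dplyr::bind_rows(segs)
    n_mapped <- sum(segs$end - segs$start)
    if (n_mapped == 0) return(none)
    if (require_unique) {
      if (length(unique(segs$chrom)) > 1 || length(unique(segs$strand)) > 1)
        return(none)
      if (segs$strand[1] == "+" && is.unsorted(segs$start)) return(none)
      if (segs$strand[1] == "-" && is.unsorted(rev(segs$start))) return(none)
    }
    tibble(chrom = segs$chrom[1], start = min(segs$start),
           end = max(segs$end), strand = segs$strand[1],
           mapped_bases = as.integer(n_mapped), mapped = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Invert a block map (swap the A and B sides)
#' @param block_map a `block_map`.
#' @return A `block_map` oriented B -> A.
#' @export
invert_block_map <- function(block_map) {
  bm <- tibble(chromA = block_map$chromB, startA = block_map$startB,
               endA = block_map$endB, chromB = block_map$chromA,
               startB = block_map$startA, endB = block_map$endA,
               strand = block_map$strand)
  bm <- bm[order(bm$chromA, bm$startA), ]
  validate_block_map(bm)
}

#' Call conserved stage-specific enhancers between two species
#'
#' An enhancer in species A is conserved iff its translated image exists and
#' (mode `"overlap"`) overlaps >= 1 bp a same-stage-specific B enhancer, or
#' (mode `"within_1kb"`) lies < 1000 bp edge-to-edge from the nearest one
#' (overlap counting as distance 0).  Both inputs must already be restricted
#' to one stage.
#'
#' @param specific_A stage-specific enhancers of species A (interval tibble).
#' @param specific_B same-stage-specific enhancers of species B.
#' @param block_map block map oriented A -> B.
#' @param mode `"overlap"` or `"within_1kb"`.
#' @param max_distance proximity threshold for `within_1kb` (default 1000,
#'   strict `<`).
#' @return Tibble of conservation calls: `enhancer_A, partner_B,
#'   has_ortholog_region, conserved_overlap, conserved_1kb, conserved`
#'   (the mode-selected flag).
#' @export
call_conserved <- function(specific_A, specific_B, block_map,
                           mode = c("overlap", "within_1kb"),
                           max_distance = 1000) {
  mode <- match.arg(mode)
  img <- translate(specific_A, block_map, require_unique = TRUE)
  ids_A <- specific_A$id %||% paste0("A", seq_len(nrow(specific_A)))
  ids_B <- specific_B$id %||% paste0("B", seq_len(nrow(specific_B)))
  n <- nrow(specific_A)
  cons_ov <- logical(n); cons_kb <- logical(n)
  partner <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!img$mapped[i]) next
    cand <- which(specific_B$chrom == img$chrom[i])
    if (!length(cand)) next
    bs <- specific_B$start[cand]; be <- specific_B$end[cand]
    d <- ifelse(bs >= img$end[i], bs - img$end[i],
                ifelse(be <= img$start[i], img$start[i] - be, 0))
    j <- which.min(d)
    cons_ov[i] <- d[j] == 0
    cons_kb[i] <- d[j] < max_distance
    if (cons_kb[i]) partner[i] <- ids_B[cand[j]]
  }
  tibble(enhancer_A = ids_A, partner_B = partner,
         has_ortholog_region = img$mapped,
         conserved_overlap = cons_ov, conserved_1kb = cons_kb,
         conserved = if (mode == "overlap") cons_ov else cons_kb)
}

#' Jaccard index of cross-species conservation
#'
#' `|conserved| / (|A| + |B| - |conserved|)`, over one-to-one orthologous
#' stage-specific enhancers: 0 when none are conserved, 1 when all are.
#'
#' @param n_A,n_B counts of stage-specific enhancers in each species.
#' @param n_conserved count of conserved (one-to-one paired) enhancers.
#' @return Numeric in `[0, 1]`, or NA when `n_A + n_B == 0`.
#' @export
jaccard_index <- function(n_A, n_B, n_conserved) {
  ifelse(n_A + n_B == 0, NA_real_, n_conserved / (n_A + n_B - n_conserved))
}

#' Pairwise Fisher exact tests of per-stage proportions against a reference
#'
#' @param counts tibble with columns `stage`, `k` (successes) and `n`
#'   (totals).
#' @param reference reference stage (default `"TP3"`).
#' @return `counts` with added `proportion`, `fisher_p` (two-sided, vs the
#'   reference stage; NA for the reference itself), `fisher_q`
#'   (Benjamini-Hochberg over the pairwise tests) and `zero_margin` flag
#'   (such tables report p = 1 by convention).
#' @export
compare_stage_proportions <- function(counts, reference = "TP3") {
  stopifnot(all(c("stage", "k", "n") %in% names(counts)),
            reference %in% counts$stage)
  ref <- counts[counts$stage == reference, ]
  p <- rep(NA_real_, nrow(counts))
  zero <- rep(FALSE, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    if (counts$stage[i] == reference) next
    tab <- matrix(c(ref$k, ref$n - ref$k,
                    counts$k[i], counts$n[i] - counts$k[i]), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      p[i] <- 1; zero[i] <- TRUE
    } else {
      p[i] <- fisher.test(tab)$p.value
    }
  }
  out <- counts
  out$proportion <- counts$k / counts$n
  out$fisher_p <- p
  out$fisher_q <- NA_real_
  tested <- !is.na(p)
  out$fisher_q[tested] <- p.adjust(p[tested], method = "BH")
  out$zero_margin <- zero
  out
}

#' Assign enhancers to tissue categories by >= 1 bp overlap
#'
#' Enhancers overlapping only the muscle set are `"muscle"`, only the neuron
#' set `"neuron"`, neither `"remaining"`; enhancers overlapping both are
#' flagged `"ambiguous"` (to be excluded from three-category splits rather
#' than assigned arbitrarily).
#'
#' @param enhancers interval tibble.
#' @param tissue_sets named list with interval tibbles `muscle` and `neuron`.
#' @return `enhancers` with an added `tissue` column.
#' @export
assign_tissue_categories <- function(enhancers, tissue_sets) {
  stopifnot(all(c("muscle", "neuron") %in% names(tissue_sets)))
  in_m <- logical(nrow(enhancers)); in_n <- logical(nrow(enhancers))
  hm <- overlap_pairs(enhancers, tissue_sets$muscle)
  hn <- overlap_pairs(enhancers, tissue_sets$neuron)
  in_m[unique(hm[, 1])] <- TRUE
  in_n[unique(hn[, 1])] <- TRUE
  enhancers$tissue <- dplyr::case_when(
    in_m & in_n ~ "ambiguous",
    in_m ~ "muscle",
    in_n ~ "neuron",
    TRUE ~ "remaining")
  enhancers
}

#' Per-stage conservation summary between two species
#'
#' Runs stage-specific calling on both species' distal peaks, conservation
#' calling in both modes, and reports per-stage counts, conserved proportions
#' (over species A, species B via the inverted map, and pooled), Jaccard, and
#' pairwise Fisher p-values versus TP3.
#'
#' @param peaks_A,peaks_B per-stage peak tibbles (with `stage`), one species
#'   each, already restricted to distal elements.
#' @param block_map block map oriented A -> B.
#' @return List with `summary` (per-stage tibble), and the per-enhancer
#'   conservation calls for A (`calls_A`) keyed by mode.
#' @export
conservation_summary <- function(peaks_A, peaks_B, block_map) {
  spec_A <- call_stage_specific(peaks_A)
  spec_B <- call_stage_specific(peaks_B)
  inv <- invert_block_map(block_map)
  rows <- list(); calls_A <- list()
  for (st in STAGES) {
    sa <- spec_A[spec_A$specific & spec_A$stage == st, ]
    sb <- spec_B[spec_B$specific & spec_B$stage == st, ]
    ca <- call_conserved(sa, sb, block_map, mode = "overlap")
    cb <- call_conserved(sb, sa, inv, mode = "overlap")
    calls_A[[st]] <- ca
    rows[[st]] <- tibble(
      stage = st, n_specific_A = nrow(sa), n_specific_B = nrow(sb),
      n_conserved_overlap = sum(ca$conserved_overlap),
      n_conserved_1kb = sum(ca$conserved_1kb),
      prop_A_overlap = mean(ca$conserved_overlap),
      prop_B_overlap = mean(cb$conserved_overlap),
      prop_pooled_overlap = (sum(ca$conserved_overlap) + sum(cb$conserved_overlap)) /
        (nrow(sa) + nrow(sb)),
      prop_A_1kb = mean(ca$conserved_1kb),
      prop_B_1kb = mean(cb$conserved_1kb),
      jaccard_overlap = jaccard_index(nrow(sa), nrow(sb), sum(ca$conserved_overlap)),
      jaccard_1kb = jaccard_index(nrow(sa), nrow(sb), sum(ca$conserved_1kb)))
  }
  summary <- dplyr::bind_rows(rows)
  fo <- compare_stage_proportions(
    tibble(stage = summary$stage, k = summary$n_conserved_overlap,
           n = summary$n_specific_A))
  fk <- compare_stage_proportions(
    tibble(stage = summary$stage, k = summary$n_conserved_1kb,
           n = summary$n_specific_A))
  summary$fisher_p_overlap_vs_TP3 <- fo$fisher_p
  summary$fisher_p_1kb_vs_TP3 <- fk$fisher_p
  list(summary = summary, calls_A = calls_A,
       specific_A = spec_A, specific_B = spec_B)
}
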