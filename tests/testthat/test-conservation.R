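iv <- function(start, end, chrom = "c1", stage = NA_character_, id = NULL) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 id = id %||% sprintf("i%d_%d", start, end), stage = stage)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("distal classification uses a strict >500 bp point-to-interval distance", {
  peaks <- iv(1000, 1200)
  expect_equal(nrow(classify_distal(peaks, tibble::tibble(chrom = "c1", pos = 1100))), 0)
  expect_equal(nrow(classify_distal(peaks, tibble::tibble(chrom = "c1", pos = 1701))), 1)
  expect_equal(nrow(classify_distal(peaks, tibble::tibble(chrom = "c1", pos = 1700))), 0)
  expect_equal(nrow(classify_distal(peaks, tibble::tibble(chrom = "c1", pos = 500))), 0)
  expect_equal(nrow(classify_distal(peaks, tibble::tibble(chrom = "c1", pos = 499))), 1)
  # TSS on another chromosome does not matter
  expect_equal(nrow(classify_distal(peaks, tibble::tibble(chrom = "c9", pos = 1100))), 1)
  expect_warning(out <- classify_distal(peaks, tibble::tibble(chrom = character(),
                                                              pos = integer())),
                 "empty TSS")
  expect_equal(nrow(out), 1)
})

test_that("stage-specific calling applies the >=1 bp overlap rule", {
  peaks <- dplyr::bind_rows(
    iv(100, 200, stage = "TP3", id = "only_tp3"),
    iv(300, 400, stage = "TP2", id = "tp2_a"),
    iv(399, 500, stage = "TP3", id = "tp3_shared"),   # 1 bp overlap with tp2_a
    iv(400, 480, stage = "TP4", id = "tp4_touching"), # touches tp2_a only
    iv(600, 700, stage = "TP1", id = "t1"),
    iv(800, 900, stage = "TP5", id = "t5"))
  called <- call_stage_specific(peaks)
  expect_true(called$specific[called$id == "only_tp3"])
  expect_identical(called$specific_to[called$id == "only_tp3"], "TP3")
  expect_false(called$specific[called$id == "tp3_shared"])
  # tp3_shared overlaps tp2_a (1 bp) and tp4_touching (80 bp) -> 3 stages
  expect_equal(called$n_stages_active[called$id == "tp3_shared"], 3L)
  # [300,400) and [400,480) touch and do NOT overlap
  expect_equal(called$n_stages_active[called$id == "tp2_a"], 2L)
  expect_equal(called$n_stages_active[called$id == "tp4_touching"], 2L)

  expect_error(call_stage_specific(iv(1, 2, stage = "TP1")), "missing")
  expect_error(call_stage_specific(iv(1, 2, stage = "TP9")), "stage labels")
})

test_that("stage-specific calls agree 100% with the synthetic world's truth labels", {
  w <- small_world()
  dA <- classify_distal(w$peaks[w$peaks$species == "A", ],
                        w$tss[w$tss$species == "A", ])
  called <- call_stage_specific(dA)
  per_id <- dplyr::distinct(called[, c("id", "n_stages_active")])
  truth <- w$truth[match(per_id$id, w$truth$id), ]
  expect_equal(per_id$n_stages_active, truth$n_stages_active)
})

test_that("temporal pleiotropy matches the quadratic overlap-counting oracle", {
  # identical peaks at all stages: usage-in-5 fraction is 1
  same <- dplyr::bind_rows(lapply(STAGES_ <- paste0("TP", 1:5), function(st)
    iv(c(100, 300), c(200, 400), stage = st)))
  tp <- temporal_pleiotropy(same)
  expect_true(all(tp$usage$n_stages_used == 5))
  expect_true(all(tp$usage$fraction == 1))
  expect_true(all(tp$adjacent$fraction[tp$adjacent$adjacent_usage == "both"] == 1))

  # fully disjoint stages: usage-in-1 fraction is 1
  disjoint <- dplyr::bind_rows(lapply(1:5, function(i)
    iv(1000 * i, 1000 * i + 100, stage = paste0("TP", i))))
  tp2 <- temporal_pleiotropy(disjoint)
  expect_true(all(tp2$usage$n_stages_used == 1))
  expect_true(all(tp2$adjacent$fraction[tp2$adjacent$adjacent_usage == "neither"] == 1))

  # random world: per-peak usage equals the O(n^2) oracle
  set.seed(13)
  rnd <- dplyr::bind_rows(lapply(paste0("TP", 1:5), function(st) {
    start <- sort(sample.int(5000, 40))
    iv(start, start + sample(20:120, 40, TRUE), stage = st,
       id = paste0(st, "_", seq_along(start)))
  }))
  called <- call_stage_specific(rnd)
  expect_equal(called$n_stages_active, oracle_stage_usage(rnd))
})

test_that("translation projects through blocks, spans insertions and enforces one-to-one", {
  bm <- two_block_map()
  # single block, offset +900
  tr <- translate(iv(110, 120, chrom = "cA"), bm)
  expect_equal(tr$start, 1010)
  expect_equal(tr$end, 1020)
  expect_equal(tr$mapped_bases, 10L)
  # entirely in an unaligned gap
  expect_false(translate(iv(320, 380, chrom = "cA"), bm)$mapped)
  # straddling the 50 bp B-side insertion: span includes the gap
  tr2 <- translate(iv(150, 250, chrom = "cA"), bm)
  expect_equal(tr2$start, 1050)
  expect_equal(tr2$end, 1200)
  expect_equal(tr2$mapped_bases, 100L)
  expect_lt(tr2$mapped_bases, tr2$end - tr2$start)
})

test_that("translation agrees with the per-base projection oracle (incl. minus strand)", {
  bm <- validate_block_map(tibble::tibble(
    chromA = "cA", startA = c(0L, 60L, 200L), endA = c(40L, 100L, 260L),
    chromB = c("cB", "cB", "cB2"), startB = c(500L, 560L, 10L),
    endB = c(540L, 600L, 70L), strand = c("+", "-", "+")))
  for (span in list(c(10, 30), c(20, 80), c(65, 95), c(150, 230), c(35, 70))) {
    hits <- oracle_translate("cA", span[1], span[2], bm)
    got <- translate(iv(span[1], span[2], chrom = "cA"), bm)
    if (nrow(hits) == 0) {
      expect_false(got$mapped)
    } else if (length(unique(hits$chrom)) > 1 || length(unique(hits$strand)) > 1) {
      expect_false(got$mapped)  # not one-to-one
      relaxed <- translate(iv(span[1], span[2], chrom = "cA"), bm, require_unique = FALSE)
      expect_equal(relaxed$mapped_bases, nrow(hits))
    } else {
      expect_true(got$mapped)
      expect_equal(got$start, min(hits$pos))
      expect_equal(got$end, max(hits$pos) + 1L)
      expect_equal(got$mapped_bases, nrow(hits))
    }
  }
})

test_that("translating back through the inverted map recovers the mapped bases", {
  bm <- two_block_map()
  inv <- invert_block_map(bm)
  for (span in list(c(120, 180), c(150, 260), c(100, 300))) {
    fwd <- translate(iv(span[1], span[2], chrom = "cA"), bm)
    back <- translate(tibble::tibble(chrom = fwd$chrom, start = fwd$start,
                                     end = fwd$end, id = "x"), inv)
    # every originally mapped base lies inside the back-translated interval
    mapped_A <- Filter(function(p) nrow(oracle_translate("cA", p, p + 1, bm)) > 0,
                       span[1]:(span[2] - 1))
    expect_true(all(mapped_A >= back$start & mapped_A < back$end))
  }
})

test_that("conserved calling honors the overlap and <1 kb definitions and their boundary", {
  bm <- validate_block_map(tibble::tibble(
    chromA = "cA", startA = 0L, endA = 10000L,
    chromB = "cB", startB = 0L, endB = 10000L, strand = "+"))
  A <- iv(1000, 1300, chrom = "cA", id = "a1", stage = "TP3")
  for (case in list(list(b = c(1000, 1300), ov = TRUE, kb = TRUE),
                    list(b = c(2299, 2400), ov = FALSE, kb = TRUE),   # 999 away
                    list(b = c(2300, 2400), ov = FALSE, kb = FALSE),  # exactly 1000
                    list(b = c(1299, 1400), ov = TRUE, kb = TRUE))) { # 1 bp overlap
    B <- iv(case$b[1], case$b[2], chrom = "cB", id = "b1", stage = "TP3")
    cc <- call_conserved(A, B, bm, mode = "within_1kb")
    expect_equal(cc$conserved_overlap, case$ov)
    expect_equal(cc$conserved_1kb, case$kb)
    # invariant: overlap-conserved implies 1kb-conserved
    expect_true(!cc$conserved_overlap || cc$conserved_1kb)
  }
  # unmapped A enhancer is never conserved
  far <- iv(20000, 20300, chrom = "cA", id = "a2", stage = "TP3")
  cc <- call_conserved(far, iv(1, 300, chrom = "cB", stage = "TP3"), bm)
  expect_false(cc$has_ortholog_region)
  expect_false(cc$conserved_1kb)
})

test_that("Jaccard arithmetic, extremes and symmetry", {
  expect_equal(jaccard_index(6, 8, 4), 0.4)
  expect_equal(jaccard_index(8, 6, 4), 0.4)  # symmetric in A/B
  expect_equal(jaccard_index(5, 5, 5), 1)
  expect_equal(jaccard_index(5, 8, 0), 0)
  expect_true(is.na(jaccard_index(0, 0, 0)))
})

test_that("pairwise Fisher tests match the enumeration oracle and handle zero margins", {
  counts <- tibble::tibble(stage = paste0("TP", 1:5),
                           k = c(5, 5, 10, 0, 2), n = c(10, 10, 10, 10, 2))
  out <- compare_stage_proportions(counts, reference = "TP3")
  expect_true(is.na(out$fisher_p[3]))
  for (i in c(1, 2, 4, 5)) {
    tab <- matrix(c(10, 0, counts$k[i], counts$n[i] - counts$k[i]), nrow = 2)
    expect_equal(out$fisher_p[i], oracle_fisher(tab), tolerance = 1e-12)
  }
  # the printed-example table: [[10,0],[0,10]] -> 2/choose(20,10)
  expect_equal(oracle_fisher(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               2 / choose(20, 10), tolerance = 1e-12)
  # no-association table
  expect_equal(fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  # zero-margin convention
  zm <- compare_stage_proportions(
    tibble::tibble(stage = c("TP3", "TP1"), k = c(0, 0), n = c(5, 5)))
  expect_equal(zm$fisher_p[2], 1)
  expect_true(zm$zero_margin[2])
})

test_that("tissue assignment uses >=1 bp overlap and flags double overlaps as ambiguous", {
  enh <- dplyr::bind_rows(
    iv(100, 200, id = "m"), iv(300, 400, id = "n"),
    iv(500, 600, id = "r"), iv(700, 800, id = "both"),
    iv(899, 1000, id = "edge"))
  tissue <- list(
    muscle = dplyr::bind_rows(iv(150, 160), iv(700, 800), iv(800, 900)),
    neuron = dplyr::bind_rows(iv(350, 360), iv(750, 760), iv(850, 899)))
  out <- assign_tissue_categories(enh, tissue)
  expect_equal(out$tissue, c("muscle", "neuron", "remaining", "ambiguous",
                             "muscle"))
})
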