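triple_of <- function(f, s, o) as_aligned_triple(c(f, s, o))

test_that("ancestor inference satisfies the parsimony truth table on all base triples", {
  b <- c("A", "C", "G", "T")
  for (f in b) for (s in b) for (o in b) {
    call <- infer_ancestor(triple_of(f, s, o))
    if (f == s) {
      expect_identical(call$ancestor, f)
      expect_equal(nrow(call$substitutions), 0)
      expect_equal(call$n_excluded, 0)
    } else if (o == s) {
      # focal-branch substitution: ancestor sides with sister + outgroup
      expect_identical(call$ancestor, s)
      expect_equal(nrow(call$substitutions), 1)
      expect_identical(call$substitutions$anc, s)
      expect_identical(call$substitutions$der, f)
    } else if (o == f) {
      # sister-branch change: ancestor = focal, no focal substitution
      expect_identical(call$ancestor, f)
      expect_equal(nrow(call$substitutions), 0)
      expect_equal(call$n_excluded, 0)
    } else {
      # three distinct bases: excluded from calling, ancestor keeps focal
      expect_identical(call$ancestor, f)
      expect_equal(nrow(call$substitutions), 0)
      expect_equal(call$n_excluded, 1)
      expect_equal(call$excluded, 0)
    }
  }
})

test_that("gap and N columns are excluded and focal gaps drop out of coordinates", {
  call <- infer_ancestor(triple_of("AC-GT", "ACCGA", "ACCGA"))
  expect_identical(call$ancestor, "ACGA")          # focal coordinates
  expect_equal(nrow(call$substitutions), 1)        # T<-A at focal position 3
  expect_equal(call$substitutions$pos, 3)
  call2 <- infer_ancestor(triple_of("ACGT", "AC-T", "ANGT"))
  expect_equal(call2$n_excluded, 2)
  expect_equal(sort(call2$excluded), c(1, 2))
  expect_equal(nrow(call2$substitutions), 0)
  expect_error(infer_ancestor(list(focal = "ACG", sister = "AC", outgroup = "ACG")),
               "unequal")
})

test_that("per-site ancestor agreement with the simulator exceeds 99% at low divergence", {
  mot <- tiny_motifs()
  agree <- vapply(1:20, function(i) {
    anc <- make_enhancer(mot, 500, 0.4, 2, 600 + i)$seq
    tr <- evolve_triple(anc, evolution_params(branch_focal = 0.02,
                                              seed = 600 + i))
    call <- infer_ancestor(tr)
    mean(strsplit(call$ancestor, "")[[1]] == strsplit(anc, "")[[1]])
  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("dinucleotide flagging marks exactly the adjacency chains", {
  mk_call <- function(pos) {
    call <- list(ancestor = strrep("A", 40),
                 substitutions = tibble::tibble(pos = pos, anc = "A", der = "G",
                                                dinuc = FALSE),
                 excluded = integer(), n_excluded = 0L)
    class(call) <- "ancestor_call"
    flag_dinucleotides(call)
  }
  expect_equal(mk_call(c(10, 11))$substitutions$dinuc, c(TRUE, TRUE))
  expect_equal(mk_call(c(10, 12))$substitutions$dinuc, c(FALSE, FALSE))
  expect_equal(mk_call(c(10, 11, 12))$substitutions$dinuc, rep(TRUE, 3))
  expect_equal(mk_call(c(3, 10, 11, 20))$substitutions$dinuc,
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("substitution spectrum follows the opportunity convention and CpG context", {
  # ancestor with 10 C's and two C->T substitutions: rate(C->T) = 0.2
  call <- list(ancestor = strrep("CA", 10),
               substitutions = tibble::tibble(pos = c(0, 2), anc = "C", der = "T",
                                              dinuc = FALSE),
               excluded = integer(), n_excluded = 0L)
  class(call) <- "ancestor_call"
  sp <- estimate_spectrum(list(call))
  expect_equal(sp$rates["C", "T", "nonCpG"], 0.2)
  expect_equal(sum(sp$counts), 2)

  # CpG context: both bases of a CG dinucleotide count as CpG
  call2 <- call
  call2$ancestor <- "ACGTT"
  call2$substitutions <- tibble::tibble(pos = c(1, 4), anc = c("C", "T"),
                                        der = c("T", "A"), dinuc = FALSE)
  sp2 <- estimate_spectrum(list(call2))
  expect_equal(sp2$counts["C", "T", "CpG"], 1)
  expect_equal(sp2$counts["T", "A", "nonCpG"], 1)
  expect_equal(sp2$opportunities["G", "CpG"], 1)

  # no substitutions: all rates zero
  call3 <- call
  call3$substitutions <- call3$substitutions[0, ]
  sp3 <- estimate_spectrum(list(call3))
  expect_true(all(sp3$counts == 0))
  expect_true(is.na(sp3$ts_tv_ratio))
})

test_that("simulated kappa is recovered by the spectrum estimator", {
  mot <- tiny_motifs()
  calls <- lapply(1:60, function(i) {
    anc <- make_enhancer(mot, 400, 0.45, 0, 3000 + i)$seq
    tr <- evolve_triple(anc, evolution_params(
      branch_focal = 0.3, branch_sister = 0.001, branch_outgroup = 0.001,
      kappa = 3, seed = 3000 + i))
    infer_ancestor(tr)
  })
  sp <- estimate_spectrum(calls)
  n_subs <- sum(sp$counts)
  expect_gte(n_subs, 5000)
  expect_lt(abs(sp$ts_tv_ratio - 3) / 3, 0.1)
})

# reconstruct the focal sequence implied by an ancestor call
apply_focal <- function(call) {
  v <- strsplit(call$ancestor, "")[[1]]
  v[call$substitutions$pos + 1] <- call$substitutions$der
  paste(v, collapse = "")
}

test_that("deltaSVM is zero without substitutions, antisymmetric, and local", {
  m <- tiny_model()
  anc <- make_enhancer(tiny_motifs(), 150, 0.4, 1, 91)$seq
  tr <- evolve_triple(anc, evolution_params(branch_focal = 0.015, seed = 92))
  call <- infer_ancestor(tr)
  expect_gte(nrow(call$substitutions), 1)

  none <- call; none$substitutions <- call$substitutions[0, ]
  d0 <- delta_svm(m, none)
  expect_identical(as.numeric(d0), 0)
  expect_true(attr(d0, "no_substitution"))

  d <- delta_svm(m, call)
  # antisymmetry: swapping focal and ancestor negates the statistic
  swapped <- list(ancestor = apply_focal(call),
                  substitutions = tibble::tibble(
                    pos = call$substitutions$pos,
                    anc = call$substitutions$der, der = call$substitutions$anc,
                    dinuc = call$substitutions$dinuc),
                  excluded = call$excluded, n_excluded = call$n_excluded)
  class(swapped) <- "ancestor_call"
  expect_equal(as.numeric(delta_svm(m, swapped)), -as.numeric(d),
               tolerance = 1e-12)
  # locality: equals the sum over substitution-covering windows only
  expect_equal(as.numeric(d),
               oracle_delta_local(m, call$ancestor, apply_focal(call),
                                  call$substitutions$pos),
               tolerance = 1e-9)
  # a model with uniform feature weights cancels in any substitution set
  flat <- m
  flat$w <- rep(1, length(m$w))
  flat$cache <- new.env()
  expect_equal(as.numeric(delta_svm(flat, call)), 0, tolerance = 1e-9)
})

test_that("dinucleotide exclusion never increases the applied substitution count", {
  m <- tiny_model()
  mot <- tiny_motifs()
  for (i in 1:10) {
    anc <- make_enhancer(mot, 200, 0.4, 1, 700 + i)$seq
    tr <- evolve_triple(anc, evolution_params(branch_focal = 0.05,
                                              dinuc_fraction = 0.5,
                                              seed = 700 + i))
    call <- infer_ancestor(tr)
    d_all <- delta_svm(m, call, exclude_dinucleotides = FALSE)
    d_ex <- delta_svm(m, call, exclude_dinucleotides = TRUE)
    expect_lte(attr(d_ex, "n_substitutions"), attr(d_all, "n_substitutions"))
  }
})

test_that("the empirical null hits the p-value boundary and samples bases as configured", {
  m <- tiny_model()
  anc <- make_enhancer(tiny_motifs(), 200, 0.4, 1, 55)$seq
  tr <- evolve_triple(anc, evolution_params(seed = 56), n_focal_subs = 3)
  call <- infer_ancestor(tr)
  nd <- null_distribution(m, call, n_permutations = 200, seed = 9,
                          keep_deltas = TRUE)
  expect_length(nd$deltas, 200)
  # observed beyond the null maximum: exceed count 0 -> p = 1/(N+1)
  fake_obs <- max(nd$deltas) + 1
  expect_equal((sum(nd$deltas >= fake_obs) + 1) / 201, 1 / 201)
  # determinism
  nd2 <- null_distribution(m, call, n_permutations = 200, seed = 9,
                           keep_deltas = TRUE)
  expect_identical(nd$deltas, nd2$deltas)
  expect_error(null_distribution(m, infer_ancestor(triple_of("ACGTAC", "ACGTAC", "ACGTAC")),
                                 n_permutations = 10, seed = 1),
               "at least two")
})

test_that("ts/tv-weighted null draws transitions three times as often", {
  # ancestral A: alternatives G (transition), C, T; weights 3:1:1
  w <- ehourglass:::alt_base_weights("ts_tv_weighted", kappa = 3)
  expect_equal(w[1, ], c(1 / 5, 3 / 5, 1 / 5))  # alts of A are C,G,T in order
  set.seed(4)
  draws <- sample(c("C", "G", "T"), 10000, TRUE, prob = w[1, ])
  frac_g <- mean(draws == "G")
  expect_lt(abs(frac_g - 0.6), 3 * sqrt(0.6 * 0.4 / 10000) + 0.001)
  # uniform mode
  wu <- ehourglass:::alt_base_weights("uniform")
  expect_true(all(wu == 1 / 3))
  # spectrum mode follows the estimated row
  call <- list(ancestor = strrep("A", 100),
               substitutions = tibble::tibble(pos = 0:9, anc = "A",
                                              der = rep(c("G", "C"), c(8, 2)),
                                              dinuc = FALSE),
               excluded = integer(), n_excluded = 0L)
  class(call) <- "ancestor_call"
  sp <- estimate_spectrum(list(call))
  ws <- ehourglass:::alt_base_weights("spectrum", spectrum = sp)
  expect_equal(ws[1, ], c(0.2, 0.8, 0))  # C:G:T = 2:8:0
})

test_that("the enhancer-level test filters, corrects and reproduces deterministically", {
  m <- tiny_model()
  mot <- tiny_motifs()
  calls <- list()
  for (i in 1:12) {
    anc <- make_enhancer(mot, 200, 0.4, 1, 880 + i)$seq
    n_subs <- if (i <= 3) 1 else 4     # first three fall below the minimum
    tr <- evolve_triple(anc, evolution_params(branch_sister = 1e-9,
                                              branch_outgroup = 1e-9,
                                              seed = 880 + i),
                        n_focal_subs = n_subs)
    calls[[sprintf("e%02d", i)]] <- infer_ancestor(tr)
  }
  res <- test_enhancers(m, calls, n_permutations = 100, seed = 12)
  expect_equal(nrow(res), 9)
  expect_equal(attr(res, "n_dropped") + nrow(res), 12)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_equal(res$positive_call, res$q_value < 0.05)
  res2 <- test_enhancers(m, calls, n_permutations = 100, seed = 12)
  expect_identical(res, res2)
  # tails: upper + lower exceed counts relate through the shared null
  res_lo <- test_enhancers(m, calls, n_permutations = 100, tail = "lower",
                           seed = 12)
  expect_true(all(res$p_value + res_lo$p_value >= 1))  # overlap at ties only
})

test_that("positive proportions by group delegate to Fisher comparisons", {
  res <- tibble::tibble(enhancer_id = sprintf("e%02d", 1:40),
                        positive_call = rep(c(TRUE, FALSE), c(10, 30)))
  class(res) <- c("selection_test_result", class(res))
  groups <- tibble::tibble(enhancer_id = res$enhancer_id,
                           group = rep(c("conserved", "nonconserved"), 20))
  out <- positive_proportion_by_group(res, groups, reference = "conserved")
  expect_equal(sum(out$n), 40)
  expect_true(all(out$n_positive <= out$n))
  expect_equal(out$proportion, out$n_positive / out$n)
  expect_true(is.na(out$fisher_p[out$group == "conserved"]))
  # empty-group proportion is missing
  out2 <- positive_proportion_by_group(res[0, ], groups[0, ])
  expect_equal(nrow(out2), 0)
})
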