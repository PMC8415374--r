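#' Configuration for the synthetic two-species world
#'
#' Defaults describe the emulated study design: two species, five embryonic
#' stages (`TP1`..`TP5`), stage-specific enhancers with planted motifs, a
#' conserved fraction peaking at the mid-embryogenesis stage (TP3) and a
#' positively selected fraction depleted there (the hourglass configuration),
#' focal/sister/outgroup divergence at the low (within-group) level the
#' selection test requires, with a 3:1 transition:transversion bias, and
#' sweep-reduced polymorphism on selected enhancers.
#'
#' @param n_enhancers per-stage count of focal-species stage-specific
#'   enhancers (length 5 or scalar).
#' @param conserved_fraction per-stage fraction of those enhancers conserved
#'   by overlap with a partner-species stage-specific enhancer.
#' @param near_fraction per-stage fraction additionally conserved only under
#'   the <1 kb proximity definition (placed 100-900 bp away).
#' @param selected_fraction per-stage fraction evolving under directional
#'   selection on accessibility.
#' @param selection_mode,selection_strength direction and strength of that
#'   selection (see [evolution_params()]).
#' @param sel_noncons_weight relative weight with which selection is assigned
#'   to nonconserved versus conserved enhancers.
#' @param extra_partner per-stage count of partner-species-only stage-specific
#'   enhancers.
#' @param enhancer_length,gc,n_sites enhancer geometry and planted-motif count.
#' @param n_motifs,motif_width,ic_target per-stage motif set parameters
#'   (motif sets are disjoint between stages unless `shared_motifs`).
#' @param shared_motifs use one motif library for all five stages (stage
#'   specificity stays positional).  Useful for recovery experiments where
#'   between-stage differences in motif learnability would act as a nuisance
#'   factor on per-stage power.
#' @param branch_focal,branch_sister,branch_outgroup,kappa evolutionary
#'   parameters of the focal/sister/outgroup triple.
#' @param dinuc_fraction fraction of focal-branch substitutions injected as
#'   adjacent pairs.
#' @param theta,sweep_factor polymorphism model (see [make_polymorphisms()]).
#' @param n_pleiotropic per-species count of multi-stage (pleiotropic) peaks.
#' @param n_proximal per-species count of TSS-proximal peaks.
#' @param split_block_fraction fraction of conserved-enhancer alignment blocks
#'   split by a partner-side insertion (makes translation nontrivial).
#' @param flank aligned flank around conserved enhancers (bp).
#' @param mask_prob probability that an unaligned spacer is repeat-masked
#'   (lowercased).
#' @param seed root seed; every component draws from a named substream of it.
#' @return List of class `world_config`.
#' @export
world_config <- function(n_enhancers = 60, conserved_fraction = c(0.25, 0.25, 0.5, 0.25, 0.25),
                         near_fraction = 0.05,
                         selected_fraction = c(0.25, 0.25, 0.05, 0.25, 0.25),
                         selection_mode = "up", selection_strength = 8,
                         sel_noncons_weight = 3, extra_partner = 10,
                         enhancer_length = 300, gc = 0.4, n_sites = 4,
                         n_motifs = 3, motif_width = 8, ic_target = 1.3,
                         shared_motifs = FALSE,
                         branch_focal = 0.05, branch_sister = 0.05,
                         branch_outgroup = 0.12, kappa = 3,
                         dinuc_fraction = 0, theta = 0.01, sweep_factor = 0.3,
                         n_pleiotropic = 12, n_proximal = 8,
                         split_block_fraction = 0.3, flank = 150,
                         mask_prob = 0.2, seed = 1L) {
  rep5 <- function(x) if (length(x) == 1) rep(x, 5) else x
  cfg <- list(
    stages = STAGES,
    n_enhancers = rep5(n_enhancers),
    conserved_fraction = rep5(conserved_fraction),
    near_fraction = rep5(near_fraction),
    selected_fraction = rep5(selected_fraction),
    selection_mode = selection_mode,
    selection_strength = selection_strength,
    sel_noncons_weight = sel_noncons_weight,
    extra_partner = rep5(extra_partner),
    enhancer_length = enhancer_length, gc = gc, n_sites = n_sites,
    n_motifs = n_motifs, motif_width = motif_width, ic_target = ic_target,
    shared_motifs = shared_motifs,
    branch_focal = branch_focal, branch_sister = branch_sister,
    branch_outgroup = branch_outgroup, kappa = kappa,
    dinuc_fraction = dinuc_fraction, theta = theta,
    sweep_factor = sweep_factor, n_pleiotropic = n_pleiotropic,
    n_proximal = n_proximal, split_block_fraction = split_block_fraction,
    flank = flank, mask_prob = mask_prob, seed = as.integer(seed),
    species = c(A = "spA", B = "spB"))
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

#' @keywords internal
validate_world_config <- function(cfg) {
  stopifnot(length(cfg$n_enhancers) == 5)
  if (any(cfg$conserved_fraction < 0 | cfg$conserved_fraction > 1))
    stop("conserved_fraction must be in [0, 1]")
  if (any(cfg$conserved_fraction + cfg$near_fraction > 1))
    stop("conserved_fraction + near_fraction must be <= 1")
  if (any(cfg$selected_fraction < 0 | cfg$selected_fraction > 1))
    stop("selected_fraction must be in [0, 1]")
  if (cfg$selection_mode != "neutral" && cfg$selection_strength <= 0)
    stop("non-neutral selection_mode needs positive selection_strength")
  invisible(cfg)
}

#' Generate a synthetic two-species, five-stage world with known ground truth
#'
#' Emits every input the pipeline consumes - genomes, per-stage peak sets for
#' both species, a cross-species alignment block map (with unaligned gaps and
#' partner-side insertions so coordinate translation is nontrivial), a TSS
#' annotation, per-enhancer focal/sister/outgroup aligned triples, a
#' polymorphism table - together with complete per-enhancer truth labels.
#' Regeneration with the same configuration is bit-identical.
#'
#' @param config a [world_config()].
#' @return List of class `synthetic_world` with elements `genomes`, `peaks`,
#'   `block_map`, `tss`, `triples`, `snp_table`, `truth`, `motifs`, `config`.
#' @export
make_two_species_world <- function(config = world_config()) {
  validate_world_config(config)
  cfg <- config
  root <- cfg$seed
  len <- cfg$enhancer_length
  flank <- cfg$flank

  motifs <- if (isTRUE(cfg$shared_motifs)) {
    shared <- make_motifs(cfg$n_motifs, cfg$motif_width, cfg$ic_target,
                          substream_seed(root, "motifs_shared"))
    rep(list(shared), length(cfg$stages))
  } else {
    lapply(seq_along(cfg$stages), function(i) {
      make_motifs(cfg$n_motifs, cfg$motif_width, cfg$ic_target,
                  substream_seed(root, paste0("motifs_", cfg$stages[i])))
    })
  }
  names(motifs) <- cfg$stages

  # --- unit roster -----------------------------------------------------------
  units <- list()
  truth <- list()
  with_seed(substream_seed(root, "roster"), {
    for (i in seq_along(cfg$stages)) {
      st <- cfg$stages[i]
      n <- cfg$n_enhancers[i]
      n_ov <- round(n * cfg$conserved_fraction[i])
      n_near <- round(n * cfg$near_fraction[i])
      cons <- rep("none", n)
      cons[sample.int(n, n_ov + n_near)] <- c(rep("overlap", n_ov),
                                              rep("near", n_near))
      # nonconserved split between aligned-but-unpartnered and unalignable
      noncons <- which(cons == "none")
      kind_nc <- sample(c("ortholog_only", "no_ortholog"), length(noncons),
                        replace = TRUE)
      n_sel <- round(n * cfg$selected_fraction[i])
      wts <- ifelse(cons == "none", cfg$sel_noncons_weight, 1)
      sel_idx <- if (n_sel > 0) sample.int(n, n_sel, prob = wts) else integer()
      for (e in seq_len(n)) {
        id <- sprintf("enhA_%s_%03d", st, e)
        units[[length(units) + 1]] <- list(
          type = "enhancer", id = id, stage = st,
          cons = cons[e],
          nc_kind = if (cons[e] == "none") kind_nc[match(e, noncons)] else NA,
          selected = e %in% sel_idx)
      }
      for (e in seq_len(cfg$extra_partner[i])) {
        units[[length(units) + 1]] <- list(
          type = "partner_only", id = sprintf("enhB_%s_x%02d", st, e),
          stage = st)
      }
    }
    for (sp in c("A", "B")) {
      for (e in seq_len(cfg$n_pleiotropic)) {
        k <- sample(2:5, 1)
        units[[length(units) + 1]] <- list(
          type = "pleiotropic", species = sp,
          id = sprintf("pleio%s_%02d", sp, e),
          stages = sort(sample(cfg$stages, k)))
      }
      for (e in seq_len(cfg$n_proximal)) {
        k <- sample(1:5, 1)
        units[[length(units) + 1]] <- list(
          type = "proximal", species = sp,
          id = sprintf("prox%s_%02d", sp, e),
          stages = sort(sample(cfg$stages, k)))
      }
    }
    units <- units[sample.int(length(units))]
  })

  # --- layout ----------------------------------------------------------------
  chromA <- "chrA1"; chromB <- "chrB1"
  curA <- 0L; curB <- 0L
  blocks <- list(); peaks <- list(); tss <- list()
  maskA <- list(); maskB <- list()
  enh_pos <- list()       # A-side positions of focal enhancers
  partner_pos <- list()   # B-side positions of partner enhancers
  with_seed(substream_seed(root, "layout"), {
    gap <- function(a, b, maskable = TRUE) {
      if (maskable && a > 0 && runif(1) < cfg$mask_prob)
        maskA[[length(maskA) + 1]] <<- c(curA, curA + a)
      if (maskable && b > 0 && runif(1) < cfg$mask_prob)
        maskB[[length(maskB) + 1]] <<- c(curB, curB + b)
      curA <<- curA + as.integer(a); curB <<- curB + as.integer(b)
    }
    spacer_block <- function() {
      sl <- sample(120:200, 1)
      strand <- sample(c("+", "-"), 1, prob = c(0.8, 0.2))
      blocks[[length(blocks) + 1]] <<- tibble(
        chromA = chromA, startA = curA, endA = curA + sl,
        chromB = chromB, startB = curB, endB = curB + sl, strand = strand)
      curA <<- curA + sl; curB <<- curB + sl
    }
    for (u in units) {
      # partner-side spacing stays > 1 kb so proximity conservation is
      # decided by partner placement, not by neighboring units
      gap(sample(80:250, 1), sample(950:1250, 1))
      if (runif(1) < 0.25) { spacer_block(); gap(sample(80:250, 1), sample(150:300, 1)) }
      if (u$type == "enhancer") {
        Lb <- len + 2L * flank
        aligned <- !(identical(u$nc_kind, "no_ortholog"))
        enh_startA <- curA + flank
        enh_pos[[u$id]] <- c(enh_startA, enh_startA + len)
        b_extent <- 0L
        if (aligned) {
          split <- runif(1) < cfg$split_block_fraction
          if (split) {
            h <- flank + sample.int(len - 20L, 1)  # split inside the enhancer
            ins <- sample(20:60, 1)
            blocks[[length(blocks) + 1]] <- tibble(
              chromA = chromA, startA = curA, endA = curA + h,
              chromB = chromB, startB = curB, endB = curB + h, strand = "+")
            blocks[[length(blocks) + 1]] <- tibble(
              chromA = chromA, startA = curA + h, endA = curA + Lb,
              chromB = chromB, startB = curB + h + ins, endB = curB + Lb + ins,
              strand = "+")
            bmap <- function(o) o + ifelse(o >= h, ins, 0L)
            b_extent <- Lb + ins
          } else {
            blocks[[length(blocks) + 1]] <- tibble(
              chromA = chromA, startA = curA, endA = curA + Lb,
              chromB = chromB, startB = curB, endB = curB + Lb, strand = "+")
            bmap <- function(o) o
            b_extent <- Lb
          }
          if (u$cons != "none") {
            d <- if (u$cons == "overlap") sample(-50:50, 1) else
              len + sample(100:900, 1)
            pstart <- curB + bmap(flank) + d
            partner_pos[[u$id]] <- c(pstart, pstart + len)
            peaks[[length(peaks) + 1]] <- tibble(
              species = "B", stage = u$stage, chrom = chromB,
              start = as.integer(pstart), end = as.integer(pstart + len),
              id = paste0(u$id, "_partner"))
            truth[[length(truth) + 1]] <- tibble(
              id = paste0(u$id, "_partner"), species = "B", kind = "partner",
              stage = u$stage, n_stages_active = 1L,
              conserved = u$cons, selection = "neutral")
            b_extent <- max(b_extent, pstart + len + flank - curB)
          }
        } else {
          b_extent <- 0L
        }
        peaks[[length(peaks) + 1]] <- tibble(
          species = "A", stage = u$stage, chrom = chromA,
          start = as.integer(enh_startA), end = as.integer(enh_startA + len),
          id = u$id)
        truth[[length(truth) + 1]] <- tibble(
          id = u$id, species = "A", kind = "enhancer", stage = u$stage,
          n_stages_active = 1L, conserved = u$cons,
          selection = if (u$selected) cfg$selection_mode else "neutral")
        curA <- curA + Lb
        curB <- curB + as.integer(b_extent)
      } else if (u$type == "partner_only") {
        pstart <- curB + flank
        peaks[[length(peaks) + 1]] <- tibble(
          species = "B", stage = u$stage, chrom = chromB,
          start = as.integer(pstart), end = as.integer(pstart + len), id = u$id)
        truth[[length(truth) + 1]] <- tibble(
          id = u$id, species = "B", kind = "partner_only", stage = u$stage,
          n_stages_active = 1L, conserved = "none", selection = "neutral")
        partner_pos[[u$id]] <- c(pstart, pstart + len)
        curB <- curB + len + 2L * flank
      } else if (u$type == "pleiotropic") {
        if (u$species == "A") {
          pstart <- curA + flank
          for (st in u$stages)
            peaks[[length(peaks) + 1]] <- tibble(
              species = "A", stage = st, chrom = chromA,
              start = as.integer(pstart), end = as.integer(pstart + len), id = u$id)
          curA <- curA + len + 2L * flank
        } else {
          pstart <- curB + flank
          for (st in u$stages)
            peaks[[length(peaks) + 1]] <- tibble(
              species = "B", stage = st, chrom = chromB,
              start = as.integer(pstart), end = as.integer(pstart + len), id = u$id)
          curB <- curB + len + 2L * flank
        }
        truth[[length(truth) + 1]] <- tibble(
          id = u$id, species = u$species, kind = "pleiotropic",
          stage = NA_character_, n_stages_active = length(u$stages),
          conserved = NA_character_, selection = "neutral")
      } else if (u$type == "proximal") {
        # a peak with a TSS inside it, plus clearance so true enhancers stay
        # >500 bp from every TSS
        gap(600, 600, maskable = FALSE)
        if (u$species == "A") {
          pstart <- curA
          for (st in u$stages)
            peaks[[length(peaks) + 1]] <- tibble(
              species = "A", stage = st, chrom = chromA,
              start = as.integer(pstart), end = as.integer(pstart + len), id = u$id)
          tss[[length(tss) + 1]] <- tibble(species = "A", chrom = chromA,
                                           pos = as.integer(pstart + len %/% 2))
          curA <- curA + len
        } else {
          pstart <- curB
          for (st in u$stages)
            peaks[[length(peaks) + 1]] <- tibble(
              species = "B", stage = st, chrom = chromB,
              start = as.integer(pstart), end = as.integer(pstart + len), id = u$id)
          tss[[length(tss) + 1]] <- tibble(species = "B", chrom = chromB,
                                           pos = as.integer(pstart + len %/% 2))
          curB <- curB + len
        }
        truth[[length(truth) + 1]] <- tibble(
          id = u$id, species = u$species, kind = "proximal",
          stage = NA_character_, n_stages_active = length(u$stages),
          conserved = NA_character_, selection = "neutral")
        gap(600, 600, maskable = FALSE)
      }
    }
    gap(sample(200:400, 1), sample(200:400, 1))
  })
  lenA <- curA; lenB <- curB
  peaks <- dplyr::bind_rows(peaks)
  truth <- dplyr::bind_rows(truth)
  blocks <- validate_block_map(dplyr::bind_rows(blocks))
  tss <- if (length(tss)) dplyr::bind_rows(tss) else
    tibble(species = character(), chrom = character(), pos = integer())

  # --- sequences -------------------------------------------------------------
  p_bg <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  genomeA <- with_seed(substream_seed(root, "background_A"),
                       paste(DNA_BASES[sample.int(4, lenA, TRUE, p_bg)], collapse = ""))
  genomeB <- with_seed(substream_seed(root, "background_B"),
                       paste(DNA_BASES[sample.int(4, lenB, TRUE, p_bg)], collapse = ""))

  triples <- list()
  enh_truth <- truth[truth$kind == "enhancer", ]
  for (j in seq_len(nrow(enh_truth))) {
    id <- enh_truth$id[j]
    st <- enh_truth$stage[j]
    anc <- make_enhancer(motifs[[st]], len, cfg$gc, cfg$n_sites,
                         substream_seed(root, paste0("anc_", id)))
    sel <- enh_truth$selection[j]
    params <- evolution_params(
      branch_focal = cfg$branch_focal, branch_sister = cfg$branch_sister,
      branch_outgroup = cfg$branch_outgroup, kappa = cfg$kappa,
      selection_mode = sel,
      selection_strength = if (sel == "neutral") 0 else cfg$selection_strength,
      dinuc_fraction = cfg$dinuc_fraction,
      seed = substream_seed(root, paste0("evo_", id)))
    scorer <- if (sel == "neutral") NULL else
      function(s) true_score(s, motifs[[st]])
    triples[[id]] <- evolve_triple(anc$seq, params, true_scorer = scorer)
    pos <- enh_pos[[id]]
    substr(genomeA, pos[1] + 1, pos[2]) <- triples[[id]]$focal
  }
  for (id in names(partner_pos)) {
    st <- truth$stage[truth$id == id | truth$id == paste0(id, "_partner")][1]
    if (is.na(st)) st <- truth$stage[match(paste0(id, "_partner"), truth$id)]
    pseq <- make_enhancer(motifs[[st]], len, cfg$gc, cfg$n_sites,
                          substream_seed(root, paste0("partner_", id)))
    pos <- partner_pos[[id]]
    substr(genomeB, pos[1] + 1, pos[2]) <- pseq$seq
  }
  lower_ranges <- function(genome, ranges) {
    for (r in ranges)
      substr(genome, r[1] + 1, r[2]) <- tolower(substr(genome, r[1] + 1, r[2]))
    genome
  }
  genomeA <- lower_ranges(genomeA, maskA)
  genomeB <- lower_ranges(genomeB, maskB)

  snp_table <- make_polymorphisms(
    triples, truth, cfg$theta, cfg$sweep_factor,
    seed = substream_seed(root, "polymorphisms"))

  world <- list(
    genomes = setNames(list(setNames(genomeA, chromA), setNames(genomeB, chromB)),
                       c("A", "B")),
    peaks = peaks, block_map = blocks, tss = tss, triples = triples,
    snp_table = snp_table, truth = truth, motifs = motifs, config = cfg)
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d peaks | %d triples | genomes %s bp / %s bp\n",
              nrow(x$peaks), length(x$triples),
              format(nchar(x$genomes$A), big.mark = ","),
              format(nchar(x$genomes$B), big.mark = ",")))
  invisible(x)
}

#' Write a synthetic world's inputs to disk in the pipeline's formats
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "triples"), showWarnings = FALSE)
  write_fasta(world$genomes$A, file.path(dir, "genome_A.fa"))
  write_fasta(world$genomes$B, file.path(dir, "genome_B.fa"))
  for (sp in c("A", "B")) {
    for (st in world$config$stages) {
      sub <- world$peaks[world$peaks$species == sp & world$peaks$stage == st, ]
      write_bed(sub, file.path(dir, sprintf("peaks_%s_%s.bed", sp, st)))
    }
    sub <- world$tss[world$tss$species == sp, ]
    write_bed(tibble(chrom = sub$chrom, start = sub$pos, end = sub$pos + 1L,
                     id = paste0("tss", seq_len(nrow(sub)))),
              file.path(dir, sprintf("tss_%s.bed", sp)))
  }
  write_block_map(world$block_map, file.path(dir, "block_map.tsv"))
  for (id in names(world$triples))
    write_aligned_triple(world$triples[[id]],
                         file.path(dir, "triples", paste0(id, ".fa")), id = id)
  write_snp_table(world$snp_table, file.path(dir, "snps.tsv"))
  write.table(as.data.frame(world$truth), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read back the world inputs written by [write_world()]
#'
#' @param dir directory written by [write_world()].
#' @return List with the on-disk components (`genomes`, `peaks`, `tss`,
#'   `block_map`, `triples`, `snp_table`, `truth`).
#' @export
read_world <- function(dir) {
  peaks <- list(); tss <- list()
  for (sp in c("A", "B")) {
    for (st in STAGES) {
      f <- file.path(dir, sprintf("peaks_%s_%s.bed", sp, st))
      if (file.exists(f)) peaks[[length(peaks) + 1]] <-
          dplyr::mutate(read_bed(f, species = sp, stage = st))
    }
    f <- file.path(dir, sprintf("tss_%s.bed", sp))
    if (file.exists(f)) {
      b <- read_bed(f, species = sp)
      tss[[length(tss) + 1]] <- tibble(species = sp, chrom = b$chrom,
                                       pos = b$start)
    }
  }
  tfiles <- list.files(file.path(dir, "triples"), full.names = TRUE)
  triples <- lapply(tfiles, read_aligned_triple)
  names(triples) <- sub("\\.fa$", "", basename(tfiles))
  list(
    genomes = list(A = read_fasta(file.path(dir, "genome_A.fa")),
                   B = read_fasta(file.path(dir, "genome_B.fa"))),
    peaks = dplyr::bind_rows(peaks),
    tss = dplyr::bind_rows(tss),
    block_map = read_block_map(file.path(dir, "block_map.tsv")),
    triples = triples,
    snp_table = read_snp_table(file.path(dir, "snps.tsv")),
    truth = as_tibble(read.table(file.path(dir, "truth.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)))
}
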