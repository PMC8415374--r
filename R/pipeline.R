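#' Build a pipeline run configuration
#'
#' @param simulate list of [world_config()] arguments (the synthetic-data
#'   route), or NULL when `paths` is given.
#' @param paths named list of on-disk inputs (a directory written by
#'   [write_world()]), or NULL.
#' @param n_permutations permutations per enhancer for the empirical null.
#' @param base_sampling null base-sampling mode (`"uniform"`,
#'   `"ts_tv_weighted"`, `"spectrum"`).
#' @param tail test tail (`"upper"`, `"lower"`, `"two_sided"`).
#' @param q_threshold q-value threshold for positive calls (default 0.05).
#' @param min_substitutions minimum substitutions per tested enhancer
#'   (default 2).
#' @param tss_distance distal-element TSS clearance in bp (default 500).
#' @param conservation_mode `"overlap"` or `"within_1kb"` for the
#'   conserved/nonconserved split of the selection analysis.
#' @param exclude_dinucleotides dinucleotide-substitution exclusion control.
#' @param gkm list of [gkm_config()] arguments.
#' @param seed root seed fanned out to named substreams per module.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = list(), paths = NULL, n_permutations = 1000,
                       base_sampling = "uniform", tail = "upper",
                       q_threshold = 0.05, min_substitutions = 2,
                       tss_distance = 500, conservation_mode = "overlap",
                       exclude_dinucleotides = FALSE, gkm = list(),
                       seed = 1L) {
  cfg <- list(simulate = simulate, paths = paths,
              n_permutations = n_permutations, base_sampling = base_sampling,
              tail = tail, q_threshold = q_threshold,
              min_substitutions = min_substitutions,
              tss_distance = tss_distance,
              conservation_mode = conservation_mode,
              exclude_dinucleotides = exclude_dinucleotides,
              gkm = gkm, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Validate a run configuration
#'
#' @param config a `run_config`.
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(inherits(config, "run_config"), "not a run_config object")
  chk(config$n_permutations >= 1, "n_permutations must be positive")
  chk(config$q_threshold > 0 && config$q_threshold < 1,
      "q_threshold must be in (0, 1)")
  chk(config$min_substitutions >= 1, "min_substitutions must be >= 1")
  chk(config$tss_distance > 0, "tss_distance must be positive")
  chk(config$base_sampling %in% c("uniform", "ts_tv_weighted", "spectrum"),
      paste0("unknown base_sampling: ", config$base_sampling))
  chk(config$tail %in% c("upper", "lower", "two_sided"),
      paste0("unknown tail: ", config$tail))
  chk(config$conservation_mode %in% c("overlap", "within_1kb"),
      paste0("unknown conservation_mode: ", config$conservation_mode))
  if (!is.null(config$simulate$stages)) {
    bad <- setdiff(config$simulate$stages, STAGES)
    if (length(bad))
      problems <- c(problems, paste0("unknown stage label: ",
                                     paste(bad, collapse = ", ")))
    missing <- setdiff(STAGES, config$simulate$stages)
    if (length(missing))
      problems <- c(problems, paste0("missing stage: ",
                                     paste(missing, collapse = ", ")))
  }
  if (is.null(config$simulate) && is.null(config$paths))
    problems <- c(problems, "either simulate or paths must be given")
  if (!is.null(config$paths)) {
    for (p in unlist(config$paths))
      if (!file.exists(p)) problems <- c(problems, paste0("no such path: ", p))
  }
  problems
}

#' Package and format versions
#' @return Named list of versions.
#' @export
pipeline_version <- function() {
  list(package = as.character(utils::packageVersion("ehourglass")),
       model_format = "ehourglass_kmer_model v1",
       block_map_format = "tsv v1",
       r = R.version.string)
}

log_kv <- function(...) {
  kv <- list(...)
  message(paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " "))
}

#' Run the full analysis end to end
#'
#' Simulates (or loads) the two-species world, calls distal and
#' stage-specific enhancers, computes cross-species conservation, trains a
#' per-stage gapped k-mer model, runs the in-silico-mutagenesis selection
#' test, the substitution/polymorphism excess validation, and writes
#' conservation/selection/MK tables plus an "hourglass report" and a JSON run
#' manifest under `out_dir`.  Deterministic under the configuration's root
#' seed.
#'
#' @param config a `run_config` (or path to a YAML one).
#' @param out_dir output directory.
#' @return List with `report` (per-stage hourglass tibble), `conservation`,
#'   `selection`, `mk`, the per-stage cross-fitting `models`, and the
#'   simulated `world`, invisibly written to `out_dir`.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(step, t_start) {
    timings[[step]] <<- round(as.numeric(Sys.time() - t_start, units = "secs"), 2)
  }

  # --- inputs ---------------------------------------------------------------
  t <- Sys.time()
  if (!is.null(config$simulate)) {
    wargs <- config$simulate
    wargs$stages <- NULL
    wargs$seed <- substream_seed(config$seed, "world")
    world <- make_two_species_world(do.call(world_config, wargs))
    log_kv(step = "simulate", peaks = nrow(world$peaks),
           triples = length(world$triples))
  } else {
    stop("path-mode inputs: point `simulate = NULL, paths = list(dir = ...)` ",
         "at a directory written by write_world()")
  }
  tick("inputs", t)

  # --- conservation ---------------------------------------------------------
  t <- Sys.time()
  tssA <- world$tss[world$tss$species == "A", ]
  tssB <- world$tss[world$tss$species == "B", ]
  distal_A <- classify_distal(world$peaks[world$peaks$species == "A", ], tssA,
                              min_tss_distance = config$tss_distance)
  distal_B <- classify_distal(world$peaks[world$peaks$species == "B", ], tssB,
                              min_tss_distance = config$tss_distance)
  cons <- conservation_summary(distal_A, distal_B, world$block_map)
  log_kv(step = "conservation",
         n_specific_A = sum(cons$summary$n_specific_A),
         n_conserved = sum(cons$summary$n_conserved_overlap))
  tick("conservation", t)

  # --- per-stage models and selection test ----------------------------------
  t <- Sys.time()
  gkm_cfg <- do.call(gkm_config, config$gkm)
  models <- list(); sel <- list(); groups <- list()
  pleio <- temporal_pleiotropy(distal_A)
  for (st in STAGES) {
    sa <- cons$specific_A[cons$specific_A$specific &
                            cons$specific_A$stage == st, ]
    if (!nrow(sa)) next
    ts <- sample_matched_negatives(
      sa, world$genomes$A,
      seed = substream_seed(config$seed, paste0("negatives_", st)))
    calls <- lapply(world$triples[sa$id], infer_ancestor)
    # cross-fitted: each enhancer is scored by a model trained without it,
    # avoiding the self-training inflation of deltaSVM
    sel[[st]] <- cross_fit_test(
      ts$positives, ts$negatives, calls, gkm_cfg,
      n_permutations = config$n_permutations,
      min_substitutions = config$min_substitutions, tail = config$tail,
      base_sampling = config$base_sampling,
      exclude_dinucleotides = config$exclude_dinucleotides,
      q_threshold = config$q_threshold,
      seed = substream_seed(config$seed, paste0("null_", st)))
    models[[st]] <- attr(sel[[st]], "models")
    attr(sel[[st]], "models") <- NULL
    sel[[st]]$stage <- st
    cons_flag <- if (config$conservation_mode == "overlap")
      cons$calls_A[[st]]$conserved_overlap else cons$calls_A[[st]]$conserved_1kb
    groups[[st]] <- tibble(enhancer_id = cons$calls_A[[st]]$enhancer_A,
                           stage = st,
                           conserved = cons_flag)
    log_kv(step = "selscan", stage = st, tested = nrow(sel[[st]]),
           positive = sum(sel[[st]]$positive_call))
  }
  selection <- dplyr::bind_rows(sel)
  groups <- dplyr::bind_rows(groups)
  # one family for the whole scan: q-values pooled across stages
  if (nrow(selection)) {
    selection$q_value <- p.adjust(selection$p_value, method = "BH")
    selection$positive_call <- selection$q_value < config$q_threshold
  }
  tick("selection", t)

  # --- MK validation --------------------------------------------------------
  t <- Sys.time()
  mk <- mk_by_stage(selection, world$snp_table)
  rec <- div_poly_records(selection, world$snp_table)
  mk_pooled <- if (any(rec$positive_call) && any(!rec$positive_call)) {
    mk_excess_test(mk_tabulate(rec)$table)
  } else {
    list(odds_ratio = NA_real_, p_value = NA_real_, zero_margin = TRUE)
  }
  tick("mk", t)

  # --- hourglass report -----------------------------------------------------
  merged <- dplyr::inner_join(selection, groups,
                              by = c("enhancer_id", "stage"))
  by_cons <- dplyr::summarise(
    dplyr::group_by(merged, .data$stage, .data$conserved),
    n = dplyr::n(), n_positive = sum(.data$positive_call), .groups = "drop")
  report <- dplyr::bind_rows(lapply(STAGES, function(st) {
    cs <- cons$summary[cons$summary$stage == st, ]
    ss <- merged[merged$stage == st, ]
    bc <- by_cons[by_cons$stage == st, ]
    pc <- function(flag) {
      r <- bc[bc$conserved == flag, ]
      if (!nrow(r) || r$n == 0) NA_real_ else r$n_positive / r$n
    }
    mks <- mk[mk$stage == st, ]
    tibble(stage = st,
           n_enhancers = sum(distal_A$stage == st),
           n_specific = cs$n_specific_A,
           conserved_prop_overlap = cs$prop_A_overlap,
           conserved_prop_1kb = cs$prop_A_1kb,
           jaccard = cs$jaccard_overlap,
           n_tested = nrow(ss),
           n_positive = sum(ss$positive_call),
           positive_prop = if (nrow(ss)) mean(ss$positive_call) else NA_real_,
           positive_prop_conserved = pc(TRUE),
           positive_prop_nonconserved = pc(FALSE),
           mk_odds_ratio = if (nrow(mks)) mks$odds_ratio else NA_real_,
           mk_p = if (nrow(mks)) mks$p_value else NA_real_)
  }))

  # --- outputs --------------------------------------------------------------
  hdr <- c(sprintf("q_threshold=%g min_substitutions=%d tss_distance=%d",
                   config$q_threshold, config$min_substitutions,
                   as.integer(config$tss_distance)),
           sprintf("conservation_mode=%s null=%s tail=%s n_permutations=%d seed=%d",
                   config$conservation_mode, config$base_sampling, config$tail,
                   as.integer(config$n_permutations), config$seed))
  files <- c(
    conservation = write_tsv_report(cons$summary,
                                    file.path(out_dir, "conservation.tsv"), hdr),
    pleiotropy = write_tsv_report(pleio$usage,
                                  file.path(out_dir, "pleiotropy.tsv"), hdr),
    selection = write_tsv_report(selection,
                                 file.path(out_dir, "selection.tsv"), hdr),
    mk = write_tsv_report(mk, file.path(out_dir, "mk.tsv"), hdr),
    report = write_tsv_report(report,
                              file.path(out_dir, "hourglass_report.tsv"), hdr))
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    versions = pipeline_version(),
    thresholds = config[c("q_threshold", "min_substitutions", "tss_distance",
                          "conservation_mode", "base_sampling", "tail",
                          "n_permutations")],
    timings_sec = timings,
    outputs = lapply(as.list(files), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_kv(step = "done",
         elapsed_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 1))
  invisible(list(report = report, conservation = cons, selection = selection,
                 groups = groups, mk = mk, mk_pooled = mk_pooled,
                 models = models, world = world, manifest = manifest))
}
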