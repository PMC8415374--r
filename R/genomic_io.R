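#' @title Readers and writers for the pipeline's on-disk formats
#'
#' @description
#' All coordinates are 0-based half-open internally (BED convention),
#' regardless of on-disk dialect.  Every reader/writer pair is a lossless
#' round trip on its accepted dialect, and writers emit deterministic order.
#' FASTA case is preserved: lowercase marks repeat-masked bases and is used
#' for repeat-fraction matching.
#' @name genomic_io
NULL

#' Read a FASTA file into a named character vector
#'
#' @param path path to a FASTA file.
#' @param allow_gaps accept `-` characters (aligned FASTA dialect).
#' @return Named character vector of sequences (case preserved).
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty record in ", path)
  pattern <- if (allow_gaps) "[^ACGTNacgtn-]" else "[^ACGTNacgtn]"
  bad <- regexpr(pattern, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a BED3-BED6 file as a tibble of 0-based half-open intervals
#'
#' @param path path to a BED file.
#' @param species optional species label attached to every interval.
#' @param stage optional stage label (`TP1`..`TP5`) attached to every interval.
#' @return Tibble with columns `chrom, start, end, id, score, strand, species,
#'   stage` in stable input order.
#' @export
read_bed <- function(path, species = NA_character_, stage = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.na(stage)) assert_stage(stage)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  id = character(), score = numeric(), strand = character(),
                  species = character(), stage = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3 | nf > 6))
    stop("BED line ", which(nf < 3 | nf > 6)[1], ": expected 3-6 fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end))
    stop("BED line ", which(is.na(start) | is.na(end))[1], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("BED line ", bad[1], ": invalid interval [", start[bad[1]], ", ",
         end[bad[1]], ")")
  strand <- get(6, ".")
  if (!all(strand %in% c("+", "-", ".")))
    stop("BED line ", which(!strand %in% c("+", "-", "."))[1], ": bad strand")
  tibble(
    chrom = get(1, NA_character_),
    start = start, end = end,
    id = get(4, NA_character_),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = strand,
    species = species, stage = stage
  )
}

#' Write intervals as BED6
#'
#' @param intervals tibble with at least `chrom, start, end`; `id`, `score`
#'   and `strand` are used when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("start >= end in intervals")
  n <- nrow(intervals)
  df <- data.frame(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    id = if ("id" %in% names(intervals)) ifelse(is.na(intervals$id), ".", intervals$id) else rep(".", n),
    score = if ("score" %in% names(intervals)) ifelse(is.na(intervals$score), 0, intervals$score) else rep(0, n),
    strand = if ("strand" %in% names(intervals)) ifelse(is.na(intervals$strand), ".", intervals$strand) else rep(".", n)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a cross-species alignment block map
#'
#' The block map is a headered TSV with columns `chromA, startA, endA, chromB,
#' startB, endB, strand` (0-based half-open).  Blocks must pair equal-length
#' intervals, be sorted by A coordinates, and not overlap in A.
#'
#' @param path path to the TSV.
#' @return Tibble of class `block_map`.
#' @export
read_block_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB", "strand")
  if (!all(need %in% names(df)))
    stop("block map must have columns: ", paste(need, collapse = ", "))
  validate_block_map(as_tibble(df[need]))
}

#' @keywords internal
validate_block_map <- function(bm) {
  if (nrow(bm)) {
    if (any(bm$startA >= bm$endA) || any(bm$startB >= bm$endB))
      stop("block map: empty or inverted block")
    if (any((bm$endA - bm$startA) != (bm$endB - bm$startB)))
      stop("block map: paired intervals of unequal length at row ",
           which((bm$endA - bm$startA) != (bm$endB - bm$startB))[1])
    if (!all(bm$strand %in% c("+", "-"))) stop("block map: strand must be + or -")
    for (ch in unique(bm$chromA)) {
      sub <- bm[bm$chromA == ch, ]
      if (is.unsorted(sub$startA, strictly = FALSE))
        stop("block map: blocks out of order on ", ch)
      if (nrow(sub) > 1 && any(sub$startA[-1] < sub$endA[-nrow(sub)]))
        stop("block map: overlapping blocks on ", ch)
    }
  }
  class(bm) <- c("block_map", class(bm))
  bm
}

#' Write a block map TSV
#' @param bm block map tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_map <- function(bm, path) {
  write.table(as.data.frame(bm), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-enhancer three-way alignment (focal, sister, outgroup)
#'
#' @param path aligned multi-FASTA with exactly three equal-length records in
#'   the order focal, sister, outgroup.
#' @return List of class `aligned_triple` with elements `focal`, `sister`,
#'   `outgroup`.
#' @export
read_aligned_triple <- function(path) {
  seqs <- read_fasta(path, allow_gaps = TRUE)
  as_aligned_triple(seqs)
}

#' Construct an aligned triple from three aligned sequences
#' @param seqs character vector of length 3 (focal, sister, outgroup).
#' @return List of class `aligned_triple`.
#' @export
as_aligned_triple <- function(seqs) {
  if (length(seqs) != 3)
    stop("expected 3 aligned records (focal, sister, outgroup), got ", length(seqs))
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned records have unequal lengths: ",
         paste(nchar(seqs), collapse = ", "))
  out <- list(focal = unname(seqs[1]), sister = unname(seqs[2]),
              outgroup = unname(seqs[3]))
  class(out) <- "aligned_triple"
  out
}

#' Write an aligned triple as a 3-record aligned multi-FASTA
#' @param triple an `aligned_triple`.
#' @param path output path.
#' @param id record name prefix.
#' @return `path`, invisibly.
#' @export
write_aligned_triple <- function(triple, path, id = "enh") {
  seqs <- c(triple$focal, triple$sister, triple$outgroup)
  names(seqs) <- paste0(id, c("_focal", "_sister", "_outgroup"))
  write_fasta(seqs, path)
}

#' Read a polymorphism table
#'
#' Accepts either per-enhancer counts (columns `enhancer_id`, `n_snps`) or
#' site records (columns `chrom`, `pos`, `ref`, `alt`).
#'
#' @param path path to the TSV.
#' @return Tibble of class `snp_table`; attribute `granularity` is `"counts"`
#'   or `"sites"`.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#"))
  if (all(c("enhancer_id", "n_snps") %in% names(df))) {
    if (any(df$n_snps < 0)) stop("snp table: negative count")
    attr(df, "granularity") <- "counts"
  } else if (all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    attr(df, "granularity") <- "sites"
  } else {
    stop("snp table must have (enhancer_id, n_snps) or (chrom, pos, ref, alt)")
  }
  class(df) <- c("snp_table", class(df))
  df
}

#' Write a polymorphism table TSV
#' @param snps tibble of SNP counts or sites.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Count site-level SNPs per enhancer
#' @param snps site-granularity `snp_table`.
#' @param enhancers interval tibble with `chrom, start, end, id`.
#' @return Counts-granularity tibble (`enhancer_id`, `n_snps`).
#' @export
count_snps <- function(snps, enhancers) {
  stopifnot(identical(attr(snps, "granularity"), "sites"))
  n <- vapply(seq_len(nrow(enhancers)), function(i) {
    sum(snps$chrom == enhancers$chrom[i] &
          snps$pos >= enhancers$start[i] & snps$pos < enhancers$end[i])
  }, integer(1))
  out <- tibble(enhancer_id = enhancers$id, n_snps = n)
  attr(out, "granularity") <- "counts"
  class(out) <- c("snp_table", class(out))
  out
}

#' Write a TSV with commented header lines declaring parameters used
#' @param df data frame.
#' @param path output path.
#' @param header_lines character vector written as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#' @param path path.
#' @return Tibble.
#' @export
read_tsv_report <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#"))
}
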