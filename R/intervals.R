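## Genomic-interval computations for ATAC-seq peaks. All coordinates are
## 0-based half-open internally and in BED files; the 1-based closed
## convention of GRanges is confined to the conversion helpers below.

#' Construct an interval set (peaks or features)
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome Named numeric vector of chromosome lengths.
#' @param name Set label.
#' @return An `interval_set`: sorted, bounds-checked.
#' @export
interval_set <- function(intervals, genome, name = "intervals") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)),
            is.numeric(genome), !is.null(names(genome)))
  iv <- data.frame(chrom = as.character(intervals$chrom),
                   start = as.numeric(intervals$start),
                   end = as.numeric(intervals$end),
                   stringsAsFactors = FALSE)
  if (nrow(iv)) {
    if (any(iv$end <= iv$start)) stop("intervals must satisfy end > start")
    if (any(iv$start < 0)) stop("negative interval start")
    bad <- !iv$chrom %in% names(genome)
    if (any(bad)) stop("interval on unknown chromosome: ",
                       paste(unique(iv$chrom[bad]), collapse = ", "))
    if (any(iv$end > genome[iv$chrom]))
      stop("interval exceeds chromosome length")
    iv <- iv[order(match(iv$chrom, names(genome)), iv$start, iv$end), ,
             drop = FALSE]
    rownames(iv) <- NULL
  }
  structure(list(name = name, intervals = iv, genome = genome),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set '", x$name, "': ", nrow(x$intervals), " intervals on ",
      length(x$genome), " chromosome(s)\n", sep = "")
  invisible(x)
}

.as_granges <- function(set) {
  iv <- set$intervals
  GenomicRanges::GRanges(
    seqnames = factor(iv$chrom, levels = names(set$genome)),
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end),
    seqlengths = setNames(as.integer(set$genome), names(set$genome)))
}

.from_granges <- function(gr, genome, name) {
  interval_set(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1,
                          end = GenomicRanges::end(gr),
                          stringsAsFactors = FALSE),
               genome, name)
}

.same_genome <- function(a, b) {
  identical(names(a$genome), names(b$genome)) &&
    isTRUE(all.equal(unname(a$genome), unname(b$genome)))
}

#' Merge peak sets
#'
#' Union of all intervals with overlapping or bookended intervals
#' coalesced; the result is sorted and non-overlapping, the convention for
#' pooling replicate peak calls within a condition.
#'
#' @param sets List of `interval_set` objects on the same genome (a single
#'   set is accepted and self-merged).
#' @param name Label of the merged set.
#' @return A merged `interval_set`.
#' @export
merge_peaks <- function(sets, name = "merged") {
  if (inherits(sets, "interval_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  for (s in sets[-1L]) {
    if (!.same_genome(sets[[1L]], s))
      stop("cannot merge interval sets on different genomes")
  }
  pooled <- do.call(rbind, lapply(sets, `[[`, "intervals"))
  pooled_set <- interval_set(pooled, sets[[1L]]$genome, name)
  gr <- GenomicRanges::reduce(.as_granges(pooled_set))
  .from_granges(gr, sets[[1L]]$genome, name)
}

#' Intersect two peak sets
#'
#' Returns the overlapping portions of the two sets, the convention for
#' retaining peaks shared between conditions.
#'
#' @param a,b `interval_set` objects on the same genome.
#' @param name Label of the result.
#' @return An `interval_set` of intersection segments.
#' @export
intersect_peaks <- function(a, b, name = "intersection") {
  if (!.same_genome(a, b))
    stop("cannot intersect interval sets on different genomes")
  gr <- GenomicRanges::intersect(.as_granges(a), .as_granges(b))
  .from_granges(gr, a$genome, name)
}

#' Windows around transcription start sites
#'
#' One interval `[pos - flank, pos + flank)` per TSS, clipped to chromosome
#' bounds. All TSSs are retained, including multiple TSSs of one gene.
#'
#' @param tss Data frame with columns `chrom`, `pos` (0-based), `strand`;
#'   extra columns are ignored.
#' @param genome Named chromosome lengths.
#' @param flank Half-window in bp (default 1000).
#' @param name Label.
#' @return An `interval_set` of TSS windows.
#' @export
tss_windows <- function(tss, genome, flank = 1000, name = "tss") {
  stopifnot(flank > 0, all(c("chrom", "pos") %in% names(tss)))
  bad <- !tss$chrom %in% names(genome)
  if (any(bad)) stop("TSS on unknown chromosome: ",
                     paste(unique(tss$chrom[bad]), collapse = ", "))
  if (any(tss$pos < 0 | tss$pos >= genome[tss$chrom]))
    stop("TSS position outside chromosome bounds")
  interval_set(data.frame(chrom = tss$chrom,
                          start = pmax(0, tss$pos - flank),
                          end = pmin(unname(genome[tss$chrom]), tss$pos + flank),
                          stringsAsFactors = FALSE),
               genome, name)
}

#' Genomic-feature enrichment of a peak set
#'
#' The reported statistic is `(a/b) / (c/d)`: `a` peaks overlapping the
#' feature (>= 1 bp), `b` total peaks, `c` feature regions, and `d` the
#' estimated number of discrete genome slots where a peak and a feature
#' could overlap, `d = G / (mean peak size + mean feature size)` with `G`
#' the total genome length. `d` is kept real-valued.
#'
#' @param peaks,features `interval_set` objects on the same genome.
#' @return An `enrichment_result` list with fields `feature`, `a`, `b`,
#'   `c`, `d`, `enrichment`.
#' @export
feature_enrichment <- function(peaks, features) {
  if (!.same_genome(peaks, features))
    stop("peaks and features are on different genomes")
  b <- nrow(peaks$intervals); cc <- nrow(features$intervals)
  if (b == 0L || cc == 0L)
    stop("undefined enrichment: empty peak or feature set")
  hits <- GenomicRanges::countOverlaps(.as_granges(peaks), .as_granges(features))
  a <- sum(hits > 0)
  G <- sum(peaks$genome)
  mean_peak <- mean(peaks$intervals$end - peaks$intervals$start)
  mean_feat <- mean(features$intervals$end - features$intervals$start)
  d <- G / (mean_peak + mean_feat)
  structure(list(feature = features$name, a = a, b = b, c = cc, d = d,
                 enrichment = (a / b) / (cc / d)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment of '%s': (a/b)/(c/d) = (%d/%d)/(%d/%.4g) = %.4g\n",
              x$feature, x$a, x$b, x$c, x$d, x$enrichment))
  invisible(x)
}

#' Count Tn5 cut sites per peak and sample
#'
#' A cut site is derived from a read's 5' end by the Tn5 offset (+4 on the
#' forward strand, -5 on the reverse); pass `shift = FALSE` when positions
#' are already cut sites. Positions on chromosomes absent from the peak
#' set's genome are skipped and tallied per sample in the `skipped` field.
#'
#' @param cuts Named list, one data frame per sample with columns `chrom`,
#'   `pos` (0-based 5'-end position) and `strand` ("+"/"-").
#' @param peaks An `interval_set` of peak regions.
#' @param shift Apply the Tn5 +4/-5 shift (default `TRUE`).
#' @return A `cut_count_matrix`: list with integer `counts`
#'   (peaks x samples), `cpm` (`NULL` until [cpm_normalize()]), `skipped`,
#'   and `peak_id`.
#' @export
count_cut_sites <- function(cuts, peaks, shift = TRUE) {
  stopifnot(is.list(cuts), length(names(cuts)) == length(cuts))
  pk <- peaks$intervals
  peak_id <- if (nrow(pk)) paste0(pk$chrom, ":", pk$start, "-", pk$end)
             else character(0)
  counts <- matrix(0L, nrow = nrow(pk), ncol = length(cuts),
                   dimnames = list(peak_id, names(cuts)))
  skipped <- setNames(integer(length(cuts)), names(cuts))
  if (nrow(pk) == 0L)
    return(structure(list(counts = counts, cpm = NULL, skipped = skipped,
                          peak_id = peak_id), class = "cut_count_matrix"))
  pgr <- .as_granges(peaks)
  for (s in names(cuts)) {
    df <- cuts[[s]]
    stopifnot(all(c("chrom", "pos", "strand") %in% names(df)))
    known <- df$chrom %in% names(peaks$genome)
    skipped[s] <- sum(!known)
    df <- df[known, , drop = FALSE]
    pos <- if (shift) df$pos + ifelse(df$strand == "-", -5, 4) else df$pos
    keep <- pos >= 0 & pos < peaks$genome[df$chrom]
    skipped[s] <- skipped[s] + sum(!keep)
    pos <- pos[keep]
    cgr <- GenomicRanges::GRanges(
      seqnames = factor(df$chrom[keep], levels = names(peaks$genome)),
      ranges = IRanges::IRanges(start = pos + 1, width = 1),
      seqlengths = setNames(as.integer(peaks$genome), names(peaks$genome)))
    counts[, s] <- GenomicRanges::countOverlaps(pgr, cgr)
  }
  structure(list(counts = counts, cpm = NULL, skipped = skipped,
                 peak_id = peak_id), class = "cut_count_matrix")
}

#' Counts-per-million normalization of a cut-count matrix
#'
#' Each entry becomes `count / column_total * 1e6`; all-zero samples stay
#' zero.
#'
#' @param m A `cut_count_matrix` (or bare counts matrix).
#' @return The input with the `cpm` field filled (a matrix when a bare
#'   matrix was given).
#' @export
cpm_normalize <- function(m) {
  cc <- if (inherits(m, "cut_count_matrix")) m$counts else m
  tot <- colSums(cc)
  cpm <- sweep(cc, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  cpm[, tot == 0] <- 0
  if (inherits(m, "cut_count_matrix")) { m$cpm <- cpm; m } else cpm
}

#' Read a genome table
#'
#' Two-column TSV (`chrom`, `length`) without header, the chrom.sizes
#' convention.
#'
#' @param path TSV path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome table not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read intervals from a BED file
#'
#' @param path BED3+ path.
#' @param genome Named chromosome lengths.
#' @param name Set label (defaults to the file stem).
#' @return An `interval_set`.
#' @export
read_bed <- function(path, genome, name = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  gr <- rtracklayer::import(path, format = "BED")
  interval_set(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1,
                          end = GenomicRanges::end(gr),
                          stringsAsFactors = FALSE),
               genome, name)
}

#' Write an interval set as BED3
#'
#' @param set An `interval_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path) {
  write.table(set$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
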