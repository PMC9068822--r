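toy_genome <- c(chrA = 5000, chrB = 3000)

test_that("merge coalesces overlapping and bookended intervals", {
  s <- interval_set(data.frame(chrom = "chrA",
                               start = c(10, 15), end = c(20, 30)),
                    toy_genome)
  m <- merge_peaks(list(s))
  expect_equal(m$intervals, data.frame(chrom = "chrA", start = 10, end = 30))

  # bookended [0,5) + [5,10) coalesce; disjoint intervals stay
  s2 <- interval_set(data.frame(chrom = "chrA",
                                start = c(0, 5, 100), end = c(5, 10, 115)),
                     toy_genome)
  m2 <- merge_peaks(list(s2))
  expect_equal(m2$intervals,
               data.frame(chrom = "chrA", start = c(0, 100), end = c(10, 115)))
})

test_that("intersect returns overlapping portions only", {
  a <- interval_set(data.frame(chrom = "chrA", start = 10, end = 20),
                    toy_genome)
  b <- interval_set(data.frame(chrom = "chrA", start = 15, end = 30),
                    toy_genome)
  expect_equal(intersect_peaks(a, b)$intervals,
               data.frame(chrom = "chrA", start = 15, end = 20))
  d <- interval_set(data.frame(chrom = "chrB", start = 0, end = 10),
                    toy_genome)
  expect_equal(nrow(intersect_peaks(a, d)$intervals), 0L)
})

test_that("merge and intersect match the coverage oracle on random sets", {
  set.seed(202)
  for (i in 1:100) {
    a <- random_interval_df(sample(5:40, 1), toy_genome)
    b <- random_interval_df(sample(5:40, 1), toy_genome)
    sa <- interval_set(a, toy_genome); sb <- interval_set(b, toy_genome)
    got_m <- merge_peaks(list(sa, sb))$intervals
    want_m <- oracle_merge(rbind(a, b), toy_genome)
    expect_equal(got_m, want_m, info = paste("merge case", i))
    got_i <- intersect_peaks(sa, sb)$intervals
    want_i <- oracle_intersect(a, b, toy_genome)
    expect_equal(got_i, want_i, info = paste("intersect case", i))
  }
})

test_that("genome mismatches are refused", {
  a <- interval_set(data.frame(chrom = "chrA", start = 0, end = 10),
                    toy_genome)
  b <- interval_set(data.frame(chrom = "chrA", start = 0, end = 10),
                    c(chrA = 4000))
  expect_error(merge_peaks(list(a, b)), "different genomes")
  expect_error(intersect_peaks(a, b), "different genomes")
})

test_that("TSS windows are symmetric, clipped and one per TSS", {
  tss <- data.frame(chrom = c("chrA", "chrA", "chrA"),
                    pos = c(2500, 300, 2500),
                    strand = c("+", "-", "-"),
                    gene_id = c("g1", "g2", "g1"))
  w <- tss_windows(tss, toy_genome, flank = 1000)
  expect_equal(nrow(w$intervals), 3L)   # multiple TSSs per gene all kept
  expect_true(all(w$intervals$start[w$intervals$start > 0] ==
                    w$intervals$end[w$intervals$start > 0] - 2000))
  expect_equal(w$intervals$start[1], 0)  # clipped at chromosome start
  expect_equal(w$intervals$end[1], 1300)
  expect_error(tss_windows(data.frame(chrom = "chrA", pos = 6000,
                                      strand = "+"),
                           toy_genome), "outside")
})

test_that("enrichment reproduces the worked arithmetic example", {
  # G = 1e6; 100 peaks of mean 500 bp; 10 features of mean 1500 bp;
  # 50 peaks overlap -> d = 1e6/2000 = 500, enrichment = (50/100)/(10/500)
  genome <- c(chr1 = 1e6)
  # 50 peaks on features, 50 peaks far away, features spaced out
  feat_starts <- seq(0, by = 10000, length.out = 10)
  features <- interval_set(data.frame(chrom = "chr1", start = feat_starts,
                                      end = feat_starts + 1500), genome,
                           name = "feat")
  on_starts <- feat_starts[rep(1:10, 5)] + 100
  off_starts <- seq(500000, by = 5000, length.out = 50)
  peaks <- interval_set(data.frame(chrom = "chr1",
                                   start = c(on_starts, off_starts),
                                   end = c(on_starts, off_starts) + 500),
                        genome, name = "peaks")
  er <- feature_enrichment(peaks, features)
  expect_equal(er$a, 50L)
  expect_equal(er$b, 100L)
  expect_equal(er$c, 10L)
  expect_equal(er$d, 500)
  expect_equal(er$enrichment, 25.0)
})

test_that("enrichment obeys its algebraic reductions", {
  genome <- c(chr1 = 1e5)
  starts <- seq(0, by = 2000, length.out = 10)
  f <- interval_set(data.frame(chrom = "chr1", start = starts,
                               end = starts + 500), genome)
  # peaks identical to features: a = b, enrichment = d/c
  er <- feature_enrichment(f, f)
  expect_equal(er$enrichment, er$d / er$c)
  # single whole-genome feature, all peaks overlap: enrichment = d
  whole <- interval_set(data.frame(chrom = "chr1", start = 0, end = 1e5),
                        genome)
  er2 <- feature_enrichment(f, whole)
  expect_equal(er2$enrichment, er2$d)
  # empty sets are undefined
  empty <- interval_set(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)), genome)
  expect_error(feature_enrichment(empty, f), "undefined enrichment")
  expect_error(feature_enrichment(f, empty), "undefined enrichment")
})

test_that("enrichment is invariant to relabeling and coordinate shifts", {
  set.seed(7)
  genome <- c(chrA = 5000, chrB = 3000)
  pk <- random_interval_df(30, genome - 50)   # leave room for a shift
  ft <- random_interval_df(8, genome - 50)
  base <- feature_enrichment(interval_set(pk, genome),
                             interval_set(ft, genome))$enrichment
  # chromosome relabeling
  relabel <- c(chrA = "chrX", chrB = "chrY")
  g2 <- setNames(unname(genome), relabel[names(genome)])
  pk2 <- transform(pk, chrom = relabel[chrom])
  ft2 <- transform(ft, chrom = relabel[chrom])
  expect_equal(feature_enrichment(interval_set(pk2, g2),
                                  interval_set(ft2, g2))$enrichment, base)
  # uniform shift that stays in bounds (same genome, so same G and d)
  shift <- 37
  pk3 <- transform(pk, start = start + shift, end = end + shift)
  ft3 <- transform(ft, start = start + shift, end = end + shift)
  expect_equal(feature_enrichment(interval_set(pk3, genome),
                                  interval_set(ft3, genome))$enrichment, base)
})

test_that("cut-site counting applies the Tn5 shift and skips unknowns", {
  genome <- c(chrA = 1000)
  peaks <- interval_set(data.frame(chrom = "chrA", start = 100, end = 200),
                        genome, name = "pk")
  cuts <- list(s1 = data.frame(
    chrom = c("chrA", "chrA", "chrA", "chrA", "chrZ"),
    pos = c(146, 146, 204, 500, 10),
    strand = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE))
  m <- count_cut_sites(cuts, peaks)
  # shifted: 146+4=150 (twice, in), 204-5=199 (in), 504 (out), chrZ skipped
  expect_equal(unname(m$counts[1, "s1"]), 3)
  expect_equal(unname(m$skipped["s1"]), 1L)
  m2 <- count_cut_sites(cuts, peaks, shift = FALSE)
  expect_equal(unname(m2$counts[1, "s1"]), 2)  # 146,146 in; 204,500 out

  empty <- interval_set(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)), genome)
  m0 <- count_cut_sites(cuts, empty)
  expect_equal(nrow(m0$counts), 0L)
})

test_that("CPM columns sum to one million (nonzero columns)", {
  m <- matrix(c(10, 90, 0, 0), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  cpm <- cpm_normalize(m)
  expect_equal(cpm[, "s1"], c(p1 = 1e5, p2 = 9e5))
  expect_equal(unname(cpm[, "s2"]), c(0, 0))
  expect_equal(sum(cpm[, "s1"]), 1e6)
})

test_that("BED and genome files round-trip through the readers", {
  genome <- c(chrA = 5000, chrB = 3000)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(names(genome), unname(genome)), gpath, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_equal(read_genome(gpath), c(chrA = 5000, chrB = 3000))

  s <- interval_set(random_interval_df(20, genome), genome, "pk")
  bpath <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, bpath)
  back <- read_bed(bpath, genome)
  expect_equal(back$intervals, s$intervals)
})
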