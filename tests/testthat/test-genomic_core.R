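# Interval algebra, coordinate conventions and annotation parsing.

test_that("read_bed parses canonical records and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50", "chr1\t300\t1000"), f)
  bed <- read_bed(f)
  expect_equal(bed$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(bed$start, c(100L, 0L, 300L))
  expect_equal(bed$end, c(200L, 50L, 1000L))

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "line 1.*start >= end")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), f)
  expect_error(read_bed(f), "line 2.*non-integer")
})

test_that("read_bed/write_bed round-trip is byte-identical for BED3 and BED6", {
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t900", "chr2\t7\t8"), f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  writeLines(c("chr1\t100\t200\tpeakA\t5\t+", "chr2\t7\t8\tpeakB\t0\t-"), f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene table parsing converts GTF coordinates by strand", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "G1"; gene_name "A"; gene_biotype "protein_coding";',
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t-\t.\tgene_id "G2"; gene_name "B"; gene_biotype "protein_coding";',
    'chr1\tsrc\ttranscript\t5001\t6000\t.\t+\t.\tgene_id "G3"; gene_biotype "lincRNA";',
    'chr1\tsrc\ttranscript\t7001\t8000\t.\t+\t.\tgene_id "G3"; gene_biotype "lincRNA";'),
    f)
  g <- read_gene_table(f)
  expect_equal(g$tss[[which(g$gene_id == "G1")]], 1000L)  # + strand: start-1
  expect_equal(g$tss[[which(g$gene_id == "G2")]], 1999L)  # - strand: end-1
  expect_length(g$tss[[which(g$gene_id == "G3")]], 2)     # two TSS, one gene
  # TSV dialect round-trips (1-based tss_csv on disk, 0-based in memory)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g, f2)
  g2 <- read_gene_table(f2)
  expect_equal(g2$tss, g$tss, ignore_attr = TRUE)
})

test_that("promoter windows follow strand and clip at chromosome edges", {
  g <- gene_table(c("P", "M", "L"), c("P", "M", "L"), rep("chr1", 3),
                  c("+", "-", "+"), list(10000L, 10000L, 1000L),
                  rep("protein_coding", 3))
  w <- promoter_windows(g)
  expect_equal(unlist(w[w$gene_id == "P", c("start", "end")]),
               c(start = 8500, end = 10500))
  expect_equal(unlist(w[w$gene_id == "M", c("start", "end")]),
               c(start = 9500, end = 11500))
  expect_equal(unlist(w[w$gene_id == "L", c("start", "end")]),
               c(start = 0, end = 1500))              # left-clipped
  # strand-insensitive mode treats both strands like plus
  w2 <- promoter_windows(g, strand_aware = FALSE)
  expect_equal(unlist(w2[w2$gene_id == "M", c("start", "end")]),
               c(start = 8500, end = 10500))
})

test_that("promoter windows are 2000 bp unless clipped and contain the TSS", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 30
    g <- gene_table(sprintf("G%02d", 1:n), sprintf("G%02d", 1:n),
                    rep("chr1", n), sample(c("+", "-"), n, TRUE),
                    as.list(sample.int(50000, n)), rep("pc", n))
    w <- promoter_windows(g, c(chr1 = 50000L))
    expect_true(all(w$end - w$start <= 2000))
    clipped <- w$start == 0 | w$end == 50000
    expect_true(all((w$end - w$start == 2000) | clipped))
    expect_true(all(w$tss >= w$start & w$tss < w$end))
  }
})

test_that("half-open interval intersection matches boundary semantics", {
  a <- genomic_intervals("chr1", 10, 20)
  expect_equal(nrow(intersect_intervals(a, genomic_intervals("chr1", 20, 30))), 0)
  expect_equal(nrow(intersect_intervals(a, genomic_intervals("chr1", 19, 30))), 1)
  expect_equal(nrow(intersect_intervals(a, genomic_intervals("chr2", 10, 20))), 0)
})

test_that("intersection equals the O(n*m) oracle and is symmetric", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:60, 1); m <- sample(5:60, 1)
    mk <- function(k) {
      s <- sample.int(5000, k)
      df <- data.frame(chrom = sample(c("chr1", "chr2"), k, TRUE),
                       start = s, end = s + sample.int(300, k))
      df[order(df$chrom, df$start), ]
    }
    a <- mk(n); b <- mk(m)
    got <- intersect_intervals(a, b)
    want <- oracle_intersect(a, b)
    expect_equal(got[order(got$a_idx, got$b_idx), ],
                 want[order(want$a_idx, want$b_idx), ], ignore_attr = TRUE)
    # symmetry: swapped inputs give the same pair set with indices flipped
    rev <- intersect_intervals(b, a)
    expect_setequal(paste(got$a_idx, got$b_idx),
                    paste(rev$b_idx, rev$a_idx))
  }
})

test_that("unsorted intersection input warns but gives identical pairs", {
  a <- data.frame(chrom = "chr1", start = c(50, 10), end = c(60, 30))
  b <- data.frame(chrom = "chr1", start = 25, end = 55)
  expect_warning(got <- intersect_intervals(a, b), "not sorted")
  expect_equal(got, oracle_intersect(a, b), ignore_attr = TRUE)
})

test_that("TSS distance and nearest gene follow the min/tie rules", {
  g <- gene_table(c("B", "A"), c("B", "A"), c("chr1", "chr1"), c("+", "+"),
                  list(c(1000L, 4000L), c(300L, 9900L)), c("pc", "pc"))
  expect_equal(distance_to_tss(5000, "chr1", g[1, ]), 1000)
  expect_equal(distance_to_tss(4000, "chr1", g[1, ]), 0)
  expect_error(distance_to_tss(5000, "chr2", g[1, ]), "mismatch")
  expect_equal(nearest_gene(350, "chr1", g), "A")
  # equidistant: pos 650 is 350 from A's TSS 300 and 350 from B's TSS 1000
  expect_equal(nearest_gene(650, "chr1", g), "A")  # lexicographic tie-break
  expect_error(nearest_gene(1, "chrX", g), "no genes")
  # random fixtures against exhaustive scan
  set.seed(9)
  for (rep in 1:20) {
    n <- 15
    gg <- gene_table(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n),
                     rep("chr1", n), rep("+", n),
                     lapply(1:n, function(i) sample.int(1e5, sample(1:3, 1))),
                     rep("pc", n))
    pos <- sample.int(1e5, 1)
    d <- vapply(seq_len(n), function(i) min(abs(pos - gg$tss[[i]])), 0)
    best <- sort(gg$gene_id[d == min(d)])[1]
    expect_equal(nearest_gene(pos, "chr1", gg), best)
  }
})

test_that("chromosome prefix normalization covers both dialects", {
  expect_equal(normalize_chrom(c("1", "chrX"), "add"), c("chr1", "chrX"))
  expect_equal(normalize_chrom(c("1", "chrX"), "strip"), c("1", "X"))
  expect_equal(normalize_chrom(c("1", "chrX")), c("1", "chrX"))
})
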