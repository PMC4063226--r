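toy_path <- function(name) system.file("extdata", name, package = "pvtplan")

test_that("fai weights read sequence lengths", {
  w <- weights_from_fai(toy_path("toy.fai"))
  expect_equal(w$chrom, c("chrA", "chrB"))
  expect_equal(w$weight, c(1000, 500))

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(weights_from_fai(empty)), 0L)

  # a larger synthetic index: the weight total must equal the length total
  prof <- data.frame(name = paste0("chr", c(1:22, "X", "Y")),
                     length = round(seq(250e6, 50e6, length.out = 24)))
  fai <- withr::local_tempfile(fileext = ".fai")
  generate_fai(prof, fai)
  w <- weights_from_fai(fai)
  expect_equal(nrow(w), 24L)
  expect_equal(sum(w$weight), sum(prof$length))

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t1000\t6\t60\t61", "chr2\toops"), bad)
  expect_error(weights_from_fai(bad), "line 2")
})

test_that("sam weights count mapped records per reference", {
  w <- weights_from_sam(toy_path("toy.sam"))
  expect_equal(stats::setNames(w$weight, w$chrom), c(chrA = 4, chrB = 2))
  expect_equal(attr(w, "unmapped"), 1L)

  allun <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chrA\tLN:100",
               sprintf("r%d\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", 1:6)), allun)
  w <- weights_from_sam(allun)
  expect_equal(nrow(w), 0L)
  expect_equal(attr(w, "unmapped"), 6L)

  undeclared <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chrA\tLN:100",
               "r1\t0\tchrZ\t1\t255\t50M\t*\t0\t0\t*\t*"), undeclared)
  expect_error(weights_from_sam(undeclared), "chrZ")
  expect_warning(weights_from_sam(undeclared, strict = FALSE), "chrZ")

  # conservation on a 1,000-record synthetic stream
  spec <- synth_spec(11, 1000, data.frame(name = c("c1", "c2", "c3"),
                                          length = c(5e4, 3e4, 1e4),
                                          abundance = c(0.6, 0.3, 0.1)),
                     unmapped_frac = 0.1)
  sam <- withr::local_tempfile(fileext = ".sam")
  generate_sam(spec, sam)
  w <- weights_from_sam(sam)
  expect_equal(sum(w$weight) + attr(w, "unmapped"), 1000)
})

test_that("LPT partition is deterministic, covering, and near-optimal", {
  p <- balance_partition(c(a = 2, b = 2, c = 2, d = 2), k = 2)
  expect_equal(p$loads, c(4, 4))
  expect_equal(lengths(p$groups), c(2L, 2L))

  p <- balance_partition(c(a = 5, b = 4, c = 3, d = 3, e = 3), k = 2)
  expect_equal(p$loads, c(8, 10))  # LPT lands one above the optimum of 9
  expect_equal(oracle_opt_maxload(c(5, 4, 3, 3, 3), 2), 9)

  p1 <- balance_partition(c(x = 1, y = 2), k = 1)
  expect_equal(p1$loads, 3)
  expect_setequal(p1$groups[[1]], c("x", "y"))

  expect_error(balance_partition(c(a = 1), k = 2), "exceeds")
  expect_error(balance_partition(c(a = 1), k = 0), "positive")

  # exhaustive check of the 4/3 - 1/(3k) guarantee on small instances
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    k <- sample(2:4, 1)
    if (k > n) k <- n
    wts <- stats::setNames(round(runif(n, 0, 20)), paste0("chr", seq_len(n)))
    plan <- balance_partition(wts, k)
    expect_setequal(unlist(plan$groups), names(wts))
    expect_equal(sum(lengths(plan$groups)), n)  # disjoint + covering
    expect_equal(sort(plan$loads),
                 sort(vapply(plan$groups, function(g) sum(wts[g]), numeric(1))))
    opt <- oracle_opt_maxload(unname(wts), k)
    expect_lte(max(plan$loads), (4 / 3 - 1 / (3 * k)) * opt + 1e-9)
  }
})

test_that("split_records routes by group, replicates headers, conserves records", {
  plan <- balance_partition(weights_from_sam(toy_path("toy.sam")), k = 2)
  prefix <- file.path(withr::local_tempdir(), "part_")
  counts <- split_records(toy_path("toy.sam"), plan, prefix)
  expect_equal(sum(counts), 6L)
  expect_equal(attr(counts, "unmapped"), 1L)
  for (path in names(counts)) {
    lines <- readLines(path)
    expect_equal(sum(startsWith(lines, "@")), 3L)  # full header everywhere
  }

  # only unmapped records: every sink is header-only
  allun <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chrA\tLN:100",
               "r1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), allun)
  plan1 <- balance_partition(c(chrA = 1), k = 1)
  counts <- split_records(allun, plan1, file.path(withr::local_tempdir(), "u_"))
  expect_equal(sum(counts), 0L)
  expect_equal(length(readLines(names(counts)[1])), 1L)

  # unknown reference: strict error, lenient reroute
  stray <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chrA\tLN:100", "@SQ\tSN:chrZ\tLN:50",
               "r1\t0\tchrZ\t1\t255\t50M\t*\t0\t0\t*\t*"), stray)
  expect_error(split_records(stray, plan1, file.path(tempdir(), "s_")), "chrZ")
  expect_warning(
    counts <- split_records(stray, plan1, file.path(withr::local_tempdir(), "s_"),
                            lenient = TRUE),
    "group 1")
  expect_equal(sum(counts), 1L)
})

test_that("scatter then gather reproduces the mapped-record multiset", {
  spec <- synth_spec(21, 1000, data.frame(name = paste0("chr", 1:6),
                                          length = rep(1e5, 6),
                                          abundance = c(.3, .25, .2, .1, .1, .05)),
                     unmapped_frac = 0.05)
  sam <- withr::local_tempfile(fileext = ".sam")
  n_by_chrom <- generate_sam(spec, sam)
  plan <- balance_partition(weights_from_sam(sam), k = 3)
  prefix <- file.path(withr::local_tempdir(), "part_")
  counts <- split_records(sam, plan, prefix)
  expect_equal(sum(counts) + attr(counts, "unmapped"), 1000)

  gathered <- unlist(lapply(names(counts), function(p) {
    lines <- readLines(p)
    lines[!startsWith(lines, "@")]
  }))
  original <- readLines(sam)
  original <- original[!startsWith(original, "@")]
  mapped <- original[vapply(strsplit(original, "\t"), `[`, character(1), 3L) != "*"]
  expect_setequal(gathered, mapped)
  expect_equal(length(gathered), length(mapped))  # multiset: names are unique
})

test_that("merge_junctions sorts, deduplicates on first occurrence, idempotent", {
  merged <- merge_junctions(c(toy_path("toy_junc1.bed"), toy_path("toy_junc2.bed")))
  expect_equal(nrow(merged), 4L)
  expect_false(is.unsorted(order(merged$chrom, merged$start)))
  # first-seen record wins: JUNC1 keeps score 5, not 9
  expect_match(merged$line[merged$chrom == "chrA" & merged$start == 100], "JUNC1\t5")

  # identical streams collapse to one record each
  one <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tj\t1\t+", one)
  expect_equal(nrow(merge_junctions(c(one, one))), 1L)

  # disjoint streams are conserved and sorted
  a <- withr::local_tempfile(fileext = ".bed")
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t5\t9\tx\t1\t+", "chr1\t7\t9\ty\t1\t-", "chr1\t2\t4\tz\t1\t+"), a)
  writeLines(c("chr3\t1\t2\tu\t1\t.", "chr1\t2\t4\tv\t1\t-"), b)
  m <- merge_junctions(c(a, b))
  expect_equal(nrow(m), 5L)
  expect_equal(m$chrom, sort(m$chrom))

  # randomized planted duplicates agree with an independent set oracle
  set.seed(31)
  for (rep in 1:10) {
    keys <- data.frame(chrom = sample(paste0("chr", 1:3), 40, TRUE),
                       start = sample(0:20, 40, TRUE))
    keys$end <- keys$start + sample(1:10, 40, TRUE)
    keys$strand <- sample(c("+", "-"), 40, TRUE)
    lines <- sprintf("%s\t%d\t%d\tj%d\t0\t%s", keys$chrom, keys$start, keys$end,
                     seq_len(40), keys$strand)
    f1 <- withr::local_tempfile(fileext = ".bed")
    f2 <- withr::local_tempfile(fileext = ".bed")
    writeLines(lines[1:20], f1)
    writeLines(lines[c(21:40, sample(1:20, 5))], f2)  # planted cross-file dups
    m <- merge_junctions(c(f1, f2))
    n_distinct <- length(unique(paste(keys$chrom, keys$start, keys$end, keys$strand)))
    expect_equal(nrow(m), n_distinct)

    # idempotence: merging the merged output with itself changes nothing
    out <- withr::local_tempfile(fileext = ".bed")
    merge_junctions(c(f1, f2), out = out)
    expect_equal(merge_junctions(c(out, out))$line, m$line)
  }
})

test_that("malformed BED lines are reported with stream and line number", {
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tj\t1\t+", "chr1\t30\t20\tj2\t1\t+"), bad)
  expect_error(merge_junctions(c(bad)), "stream 1, line 2")
  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", short)
  expect_error(merge_junctions(c(short)), "line 1")
})

test_that("parallel-degree cap is half the cores, at least one", {
  expect_equal(max_parallel(8), 4L)
  expect_equal(max_parallel(1), 1L)
  expect_equal(max_parallel(16), 8L)
})
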