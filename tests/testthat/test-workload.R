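test_that("the bundled worked-example config loads with the published durations", {
  w <- load_workload(system.file("extdata", "table1.yaml", package = "pvtplan"))
  expect_s3_class(w, "pvt_workload")
  expect_true(w$paired)
  expect_equal(unname(w$host_steps["filter_reads"]), 21)
  expect_equal(unname(w$host_steps["find_juncs"]), 9)
  expect_equal(unname(w$host_steps["report"]), 41)
  expect_equal(unname(w$serial_steps["filter_reads"]), 22)
  # derived blocks: remote path sums and transfers
  b1 <- w$blocks[[1]]
  expect_equal(b1$exec_remote_min, 6 + 37 + 41)
  expect_equal(b1$exec_host_min, 6 + 42 + 39)
  expect_equal(b1$transfer_in$minutes, 5)
  expect_equal(b1$transfer_out$minutes, 3)
  b2 <- w$blocks[[2]]
  expect_true(b2$transfer_in$negligible && b2$transfer_out$negligible)
  expect_equal(b2$exec_remote_min, 5)
  expect_equal(b2$exec_host_min, 5)
})

test_that("an all-zero workload is valid and totals to zero in both modes", {
  zero <- stats::setNames(rep(0, 8),
                          c("filter_reads", "build_index", "gene_align",
                            "genome_align", "find_juncs", "junc_align",
                            "span_reads", "report"))
  w <- workload("zero", paired = TRUE, reads_left = 0, reads_right = 0,
                serial_steps = zero, host_steps = zero, remote_steps = zero)
  expect_equal(total_time(w, "serial")$total_min, 0)
  expect_equal(total_time(w, "pvt")$total_min, 0)
})

test_that("invalid configs are rejected with named errors", {
  write_cfg <- function(text) {
    path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    writeLines(text, path)
    path
  }
  base <- c("dataset_id: x", "paired: true", "reads: {left: 1, right: 2}")

  expect_error(load_workload(write_cfg(c(base, "serial: {filter_reads: -3}"))),
               "non-negative")
  expect_error(load_workload(write_cfg(c(base, "frobnicate: 1"))), "frobnicate")
  expect_error(load_workload(write_cfg(c(base, "serial: {warp_drive: 3}"))),
               "warp_drive")
  expect_error(load_workload(write_cfg(c("paired: true", "reads: {left: 1, right: 2}"))),
               "dataset_id")
  expect_error(
    load_workload(write_cfg(c(base, "transfers:", "- {block: 1, direction: sideways}"))),
    "direction")
  expect_error(load_workload(file.path(tempdir(), "no-such-file.yaml")),
               "not found")
})

test_that("workloads round-trip through write_workload/load_workload", {
  for (seed in 1:5) {
    w <- generate_workload(seed)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_workload(w, path)
    expect_equal(load_workload(path), w)
  }
  # the worked example round-trips too (negligible flags survive)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_workload(workload_table1(), path)
  expect_equal(load_workload(path), workload_table1())
})

test_that("assign_sides sends the smaller mate file remote, left on ties", {
  expect_equal(assign_sides(10e6, 12e6), c(RLow = "left", RHigh = "right"))
  expect_equal(assign_sides(12e6, 10e6), c(RLow = "right", RHigh = "left"))
  expect_equal(assign_sides(5, 5), c(RLow = "left", RHigh = "right"))
  expect_equal(assign_sides(0, 7), c(RLow = "left", RHigh = "right"))
  # antisymmetric under swapping, except at ties
  set.seed(42)
  for (i in 1:50) {
    a <- sample(0:20, 1)
    b <- sample(0:20, 1)
    fwd <- assign_sides(a, b)
    rev <- assign_sides(b, a)
    if (a != b) {
      expect_equal(unname(fwd["RLow"] == "left"), unname(rev["RLow"] == "right"))
    } else {
      expect_equal(unname(fwd["RLow"]), "left")
      expect_equal(unname(rev["RLow"]), "left")
    }
  }
})

test_that("constructor contracts hold for reads, transfers, and step names", {
  expect_error(workload("x", paired = FALSE, reads_left = 5, reads_right = 3),
               "single-end")
  expect_error(workload("x", paired = TRUE, reads_left = -1), "non-negative")
  expect_error(workload("x", paired = TRUE, reads_left = 1,
                        serial_steps = c(bogus_step = 3)), "bogus_step")
  expect_error(workload("x", paired = TRUE, reads_left = 1,
                        transfers = list(sideways = transfer_spec(1))), "named")
  expect_error(transfer_spec(-2), "non-negative")
  expect_error(block_spec(3), "1 or 2")
  # machine specs validate their resources
  expect_error(machine_spec("m", cores = 0, memory_gb = 16), "positive")
  expect_error(machine_spec("m", cores = 8, memory_gb = 0), "> 0")
  expect_equal(machine_spec("m", 8, 16)$role, "host")
})
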