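## Workload data model: step kinds, machines, transfers, independent blocks,
## and the YAML config round-trip.

#' Workflow step kinds
#'
#' The vocabulary of spliced-alignment workflow steps understood by the
#' timing model and the pipeline simulator.  `"transfer"` labels host/remote
#' file movement and never carries a duration in the per-step columns (its
#' durations live in the block transfer specs).
#'
#' @return Character vector of step identifiers.
#' @export
#' @examples
#' step_kinds()
step_kinds <- function() {
  c("filter_reads", "build_index", "gene_align", "genome_align",
    "split_by_chrom", "find_juncs", "concat_segments", "junc_align",
    "span_reads", "report", "transfer")
}

## step kinds that may carry a duration in a serial/host/remote column
.duration_steps <- function() setdiff(step_kinds(), "transfer")

## membership of the two independent host/remote blocks: index building is
## counted once per machine inside block 1 (indices are built only once per
## experiment on each machine, so the cost sits with the first alignment block)
.block_steps <- list(
  c("build_index", "gene_align", "genome_align"),
  c("junc_align", "span_reads")
)

#' Machine description
#'
#' @param machine_id Identifier string.
#' @param cores Positive integer core count.
#' @param memory_gb Positive RAM size in GiB.
#' @param role `"host"` or `"remote"`.
#'
#' @return An object of class `machine_spec`.
#' @export
#' @examples
#' machine_spec("xeon-host", cores = 8, memory_gb = 16, role = "host")
machine_spec <- function(machine_id, cores, memory_gb, role = c("host", "remote")) {
  role <- match.arg(role)
  cores <- as.integer(cores)
  if (is.na(cores) || cores < 1L) stop("`cores` must be a positive integer", call. = FALSE)
  if (!is.numeric(memory_gb) || is.na(memory_gb) || memory_gb <= 0)
    stop("`memory_gb` must be > 0", call. = FALSE)
  structure(list(machine_id = as.character(machine_id), cores = cores,
                 memory_gb = as.numeric(memory_gb), role = role),
            class = "machine_spec")
}

#' Transfer description
#'
#' A host/remote file transfer.  Transfers flagged `negligible` keep their raw
#' sub-minute duration for reporting but contribute exactly 0 to every total,
#' matching how printed per-step tables aggregate whole minutes.
#'
#' @param minutes Non-negative duration in minutes.
#' @param negligible Logical; if `TRUE` the transfer counts as 0 in totals.
#'
#' @return An object of class `transfer_spec`.
#' @export
#' @examples
#' transfer_spec(5)
#' transfer_spec(22 / 60, negligible = TRUE)
transfer_spec <- function(minutes = 0, negligible = FALSE) {
  if (!is.numeric(minutes) || length(minutes) != 1L || is.na(minutes) || minutes < 0)
    stop("transfer `minutes` must be a single non-negative number", call. = FALSE)
  if (!is.logical(negligible) || length(negligible) != 1L || is.na(negligible))
    stop("`negligible` must be TRUE or FALSE", call. = FALSE)
  structure(list(minutes = as.numeric(minutes), negligible = negligible),
            class = "transfer_spec")
}

## duration a transfer contributes to totals
transfer_minutes <- function(x) {
  stopifnot(inherits(x, "transfer_spec"))
  if (x$negligible) 0 else x$minutes
}

#' Independent step block
#'
#' One of the two sets of consecutive steps that run simultaneously on the
#' host and the remote machine for paired-end reads: block 1 is index
#' building plus `gene_align` and `genome_align`; block 2 is `junc_align`
#' plus `span_reads`.  `exec_remote_min`/`exec_host_min` are the summed
#' durations of the block's steps on each side; `transfer_in`/`transfer_out`
#' bracket the remote path.
#'
#' @param block_index 1 or 2.
#' @param transfer_in,transfer_out [transfer_spec()] objects (numbers are
#'   promoted to non-negligible transfers).
#' @param exec_remote_min,exec_host_min Non-negative minutes.
#'
#' @return An object of class `block_spec`.
#' @export
#' @examples
#' block_spec(1, transfer_in = 5, exec_remote_min = 84,
#'            transfer_out = 3, exec_host_min = 87)
block_spec <- function(block_index, transfer_in = 0, exec_remote_min = 0,
                       transfer_out = 0, exec_host_min = 0) {
  block_index <- as.integer(block_index)
  if (!block_index %in% c(1L, 2L)) stop("`block_index` must be 1 or 2", call. = FALSE)
  if (is.numeric(transfer_in)) transfer_in <- transfer_spec(transfer_in)
  if (is.numeric(transfer_out)) transfer_out <- transfer_spec(transfer_out)
  stopifnot(inherits(transfer_in, "transfer_spec"), inherits(transfer_out, "transfer_spec"))
  for (d in list(exec_remote_min, exec_host_min))
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
      stop("block execution durations must be single non-negative numbers", call. = FALSE)
  structure(list(block_index = block_index,
                 steps = .block_steps[[block_index]],
                 transfer_in = transfer_in,
                 exec_remote_min = as.numeric(exec_remote_min),
                 transfer_out = transfer_out,
                 exec_host_min = as.numeric(exec_host_min)),
            class = "block_spec")
}

## validate and normalise a named step -> minutes mapping
.check_steps <- function(x, column) {
  if (is.null(x)) return(NULL)
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("every entry of the `", column, "` column must be named by a step", call. = FALSE)
  unknown <- setdiff(names(x), .duration_steps())
  if (length(unknown) > 0L)
    stop("unknown step kind(s) in `", column, "`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicated step kind(s) in `", column, "` column", call. = FALSE)
  x <- vapply(x, as.numeric, numeric(1))
  if (any(is.na(x) | x < 0))
    stop("durations in `", column, "` must be non-negative minutes", call. = FALSE)
  x
}

## sum the durations of `steps` present in a step column (absent steps are 0)
.steps_sum <- function(column, steps) {
  if (is.null(column)) return(0)
  sum(column[intersect(steps, names(column))])
}

#' Construct a workload
#'
#' A workload bundles everything the timing model needs for one dataset: the
#' filtered-read counts of the two mates, the per-step duration column of a
#' serial run, and the host/remote per-step columns plus transfer times of the
#' split (pipelined) run.  The two independent blocks are derived from the
#' host/remote columns; the filter/junction-discovery/report contributions of
#' the split run are taken from the host column, where those steps execute.
#'
#' @param dataset_id Identifier string.
#' @param paired Logical; paired-end library?
#' @param reads_left,reads_right Non-negative filtered-read counts of the left
#'   and right mates (`reads_right` must be 0 for single-end workloads).
#' @param serial_steps Named numeric vector, step -> minutes, for the serial
#'   run (may be `NULL` when only the split run is of interest).
#' @param host_steps,remote_steps Named numeric vectors for the split run's
#'   host-side and remote-side durations.
#' @param transfers List of up to four [transfer_spec()] entries named
#'   `"1_in"`, `"1_out"`, `"2_in"`, `"2_out"`; missing entries default to a
#'   zero transfer.
#'
#' @return An object of class `pvt_workload`.
#' @seealso [load_workload()] for the YAML interface, [workload_table1()] for
#'   the bundled paired-end worked example, [total_time()] for evaluation.
#' @export
#' @examples
#' w <- workload("toy", paired = TRUE, reads_left = 10, reads_right = 12,
#'               serial_steps = c(filter_reads = 2, build_index = 1,
#'                                gene_align = 8, genome_align = 9,
#'                                find_juncs = 1, junc_align = 2,
#'                                span_reads = 1, report = 4),
#'               host_steps = c(filter_reads = 2, build_index = 1,
#'                              gene_align = 4, genome_align = 5,
#'                              find_juncs = 1, junc_align = 1,
#'                              span_reads = 1, report = 4),
#'               remote_steps = c(build_index = 1, gene_align = 4,
#'                                genome_align = 4, junc_align = 1,
#'                                span_reads = 0.5),
#'               transfers = list("1_in" = transfer_spec(1),
#'                                "1_out" = transfer_spec(0.5)))
#' total_time(w, "serial")$total_min
workload <- function(dataset_id, paired, reads_left, reads_right = 0,
                     serial_steps = NULL, host_steps = NULL,
                     remote_steps = NULL, transfers = list()) {
  if (!is.logical(paired) || length(paired) != 1L || is.na(paired))
    stop("`paired` must be TRUE or FALSE", call. = FALSE)
  for (r in list(reads_left, reads_right))
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
      stop("read counts must be single non-negative numbers", call. = FALSE)
  if (!paired && reads_right != 0)
    stop("single-end workloads must have `reads_right` = 0", call. = FALSE)

  serial_steps <- .check_steps(serial_steps, "serial")
  host_steps <- .check_steps(host_steps, "host")
  remote_steps <- .check_steps(remote_steps, "remote")

  tr <- list("1_in" = transfer_spec(0), "1_out" = transfer_spec(0),
             "2_in" = transfer_spec(0), "2_out" = transfer_spec(0))
  if (length(transfers) > 0L) {
    unknown <- setdiff(names(transfers), names(tr))
    if (is.null(names(transfers)) || length(unknown) > 0L)
      stop("transfers must be named among ", paste(names(tr), collapse = ", "),
           call. = FALSE)
    for (nm in names(transfers)) {
      x <- transfers[[nm]]
      if (is.numeric(x)) x <- transfer_spec(x)
      if (!inherits(x, "transfer_spec"))
        stop("transfer `", nm, "` must be a transfer_spec or a number", call. = FALSE)
      tr[[nm]] <- x
    }
  }

  blocks <- lapply(1:2, function(i) {
    block_spec(i,
               transfer_in = tr[[paste0(i, "_in")]],
               exec_remote_min = .steps_sum(remote_steps, .block_steps[[i]]),
               transfer_out = tr[[paste0(i, "_out")]],
               exec_host_min = .steps_sum(host_steps, .block_steps[[i]]))
  })

  structure(list(dataset_id = as.character(dataset_id),
                 paired = paired,
                 reads_left = as.numeric(reads_left),
                 reads_right = as.numeric(reads_right),
                 serial_steps = serial_steps,
                 host_steps = host_steps,
                 remote_steps = remote_steps,
                 transfers = tr,
                 blocks = blocks),
            class = "pvt_workload")
}

#' @export
print.pvt_workload <- function(x, ...) {
  cat("Workload:", x$dataset_id,
      if (x$paired) "(paired-end)" else "(single-end)", "\n")
  cat("  filtered reads: left",
      format(x$reads_left, big.mark = ",", scientific = FALSE),
      "/ right", format(x$reads_right, big.mark = ",", scientific = FALSE), "\n")
  if (!is.null(x$serial_steps))
    cat("  serial column:", length(x$serial_steps), "steps,",
        sum(x$serial_steps), "min total\n")
  if (!is.null(x$host_steps)) {
    for (b in x$blocks)
      cat(sprintf("  block %d: remote %g min (+%g/+%g transfer), host %g min\n",
                  b$block_index, b$exec_remote_min,
                  transfer_minutes(b$transfer_in), transfer_minutes(b$transfer_out),
                  b$exec_host_min))
  }
  invisible(x)
}

#' Assign mate sides to the host and remote machines
#'
#' After quality filtering, the mate file with the strictly smaller
#' filtered-read count ("RLow") is offloaded to the remote machine — its
#' transfer and execution finish while the larger file ("RHigh") runs on the
#' host.  Ties assign the left mate to the remote side.
#'
#' @param reads_left,reads_right Non-negative filtered-read counts.
#'
#' @return Named character vector with entries `RLow` and `RHigh`, each
#'   `"left"` or `"right"`.
#' @export
#' @examples
#' assign_sides(10e6, 12e6)
#' assign_sides(5, 5)   # tie: left goes remote
assign_sides <- function(reads_left, reads_right) {
  for (r in list(reads_left, reads_right))
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
      stop("read counts must be single non-negative numbers", call. = FALSE)
  if (reads_right < reads_left) c(RLow = "right", RHigh = "left")
  else c(RLow = "left", RHigh = "right")
}

## ---- YAML config interface -------------------------------------------------

.config_keys <- c("dataset_id", "paired", "reads", "serial", "host", "remote",
                  "transfers")

#' Read a workload from a YAML config
#'
#' The config has top-level keys `dataset_id`, `paired`, `reads: {left,
#' right}`, per-step duration columns `serial:`, `host:`, `remote:` (step
#' name -> minutes), and `transfers:` as a list of `{block, direction,
#' minutes, negligible}` entries.  Unknown keys and negative durations are
#' rejected with a named error.
#'
#' @param path Path to the YAML file.
#'
#' @return A validated [workload()].
#' @seealso [write_workload()] for the inverse; the bundled worked example at
#'   `system.file("extdata", "table1.yaml", package = "pvtplan")`.
#' @export
#' @examples
#' cfg <- system.file("extdata", "table1.yaml", package = "pvtplan")
#' load_workload(cfg)
load_workload <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (key in c("dataset_id", "paired", "reads"))
    if (is.null(cfg[[key]]))
      stop("missing required config key: ", key, call. = FALSE)
  if (!all(c("left", "right") %in% names(cfg$reads)))
    stop("missing required config key: reads.left / reads.right", call. = FALSE)

  transfers <- list()
  for (t in cfg$transfers) {
    unknown <- setdiff(names(t), c("block", "direction", "minutes", "negligible"))
    if (length(unknown) > 0L)
      stop("unknown transfer key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    if (is.null(t$block) || is.null(t$direction))
      stop("each transfer needs `block` and `direction`", call. = FALSE)
    if (!t$direction %in% c("in", "out"))
      stop("transfer direction must be \"in\" or \"out\"", call. = FALSE)
    transfers[[paste0(t$block, "_", t$direction)]] <-
      transfer_spec(minutes = if (is.null(t$minutes)) 0 else t$minutes,
                    negligible = isTRUE(t$negligible))
  }

  workload(dataset_id = cfg$dataset_id,
           paired = cfg$paired,
           reads_left = cfg$reads$left,
           reads_right = cfg$reads$right,
           serial_steps = cfg$serial,
           host_steps = cfg$host,
           remote_steps = cfg$remote,
           transfers = transfers)
}

#' Write a workload to a YAML config
#'
#' Inverse of [load_workload()]: re-loading the written file reproduces the
#' workload.
#'
#' @param x A [workload()] object.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_workload <- function(x, path) {
  stopifnot(inherits(x, "pvt_workload"))
  transfers <- list()
  for (nm in names(x$transfers)) {
    tr <- x$transfers[[nm]]
    if (tr$minutes == 0 && !tr$negligible) next
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    transfers[[length(transfers) + 1L]] <-
      list(block = as.integer(parts[1]), direction = parts[2],
           minutes = tr$minutes, negligible = tr$negligible)
  }
  cfg <- list(dataset_id = x$dataset_id,
              paired = x$paired,
              reads = list(left = x$reads_left, right = x$reads_right))
  if (!is.null(x$serial_steps)) cfg$serial <- as.list(x$serial_steps)
  if (!is.null(x$host_steps)) cfg$host <- as.list(x$host_steps)
  if (!is.null(x$remote_steps)) cfg$remote <- as.list(x$remote_steps)
  if (length(transfers) > 0L) cfg$transfers <- transfers
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}
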