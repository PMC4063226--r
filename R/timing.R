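## Timing model: effective block times (max-of-paths), serial and pipelined
## totals, and percentage improvement.

#' Effective execution time of an independent block
#'
#' In the split (pipelined) run the two mate files execute a block's steps
#' simultaneously: the smaller file travels to the remote machine, runs
#' there, and travels back, while the larger file runs on the host.  The
#' block's effective duration is the slower of the two paths,
#'
#' \deqn{T_i = \max(t_{T\rightarrow} + t_{E,\mathrm{remote}} +
#'   t_{T\leftarrow},\; t_{E,\mathrm{host}}),}
#'
#' with transfers flagged negligible contributing 0.  In a serial run the two
#' sides execute back to back and the block costs their sum,
#' \eqn{t_{E,\mathrm{remote}} + t_{E,\mathrm{host}}}, with no transfers.
#'
#' @param block A [block_spec()].
#' @param mode `"pvt"` (simultaneous host/remote paths) or `"serial"`.
#'
#' @return Effective duration in minutes.
#' @export
#' @examples
#' b <- block_spec(1, transfer_in = 5, exec_remote_min = 6 + 37 + 41,
#'                 transfer_out = 3, exec_host_min = 6 + 42 + 39)
#' effective_block_time(b, "pvt")     # 92: the remote path dominates
#' effective_block_time(b, "serial")  # 171: both sides back to back
effective_block_time <- function(block, mode = c("pvt", "serial")) {
  stopifnot(inherits(block, "block_spec"))
  mode <- match.arg(mode)
  if (mode == "pvt") {
    remote_path <- transfer_minutes(block$transfer_in) + block$exec_remote_min +
      transfer_minutes(block$transfer_out)
    max(remote_path, block$exec_host_min)
  } else {
    block$exec_remote_min + block$exec_host_min
  }
}

#' Total execution time of a workload
#'
#' Composes the workflow total
#' \deqn{T_{\mathrm{total}} = T_{FR} + \sum_{i=1}^{2} T_i + T_{FJ} + T_R}
#' where \eqn{T_{FR}}, \eqn{T_{FJ}} and \eqn{T_R} are the contributions of
#' `filter_reads`, `find_juncs` and `report`, and \eqn{T_i} are the two
#' independent blocks' effective times under the mode's rule
#' ([effective_block_time()]).  Serial mode reads every contribution from the
#' workload's serial per-step column; pvt mode uses the host-side durations
#' for the three serial steps (they execute on the host) and the max-of-paths
#' rule for the blocks.  No rounding is applied.
#'
#' @param x A [workload()].
#' @param mode `"serial"` or `"pvt"`.
#'
#' @return An object of class `timing_result`: a list with
#'   `per_block_effective_min` (length 2), `components` (named contributions),
#'   `total_min`, and `mode`.
#' @export
#' @examples
#' w <- workload_table1()
#' total_time(w, "serial")$total_min  # 284
#' total_time(w, "pvt")$total_min    # 168
total_time <- function(x, mode = c("serial", "pvt")) {
  stopifnot(inherits(x, "pvt_workload"))
  mode <- match.arg(mode)

  if (mode == "serial") {
    if (is.null(x$serial_steps))
      stop("workload has no serial step column", call. = FALSE)
    col <- x$serial_steps
    per_block <- vapply(x$blocks, function(b) .steps_sum(col, b$steps), numeric(1))
  } else {
    if (is.null(x$host_steps))
      stop("workload has no host/remote step columns", call. = FALSE)
    col <- x$host_steps
    per_block <- vapply(x$blocks, effective_block_time, numeric(1), mode = "pvt")
  }
  components <- c(filter_reads = .steps_sum(col, "filter_reads"),
                  block_1 = per_block[1], block_2 = per_block[2],
                  find_juncs = .steps_sum(col, "find_juncs"),
                  report = .steps_sum(col, "report"))
  structure(list(per_block_effective_min = unname(per_block),
                 components = components,
                 total_min = sum(components),
                 mode = mode),
            class = "timing_result")
}

#' @export
print.timing_result <- function(x, ...) {
  cat(sprintf("Total %s execution time: %g min (%s)\n",
              if (x$mode == "pvt") "pipelined" else "serial",
              x$total_min, format_hm(x$total_min)))
  comp <- x$components
  for (nm in names(comp)) cat(sprintf("  %-12s %8g min\n", nm, comp[[nm]]))
  invisible(x)
}

#' Percentage improvement of the pipelined total over the serial total
#'
#' \deqn{100 \times (T_{\mathrm{serial}} - T_{\mathrm{pvt}}) /
#'   T_{\mathrm{serial}}}
#'
#' Returned unrounded; use [format_improvement()] for the conventional
#' nearest-percent display.
#'
#' @param total_serial Serial total in minutes; must be positive.
#' @param total_pvt Pipelined total in minutes.
#'
#' @return Percentage (can be negative if the pipelined run is slower; never
#'   exceeds 100).
#' @export
#' @examples
#' improvement_pct(284, 168)                     # 40.845...
#' format_improvement(improvement_pct(284, 168)) # "~41%"
improvement_pct <- function(total_serial, total_pvt) {
  if (!is.numeric(total_serial) || length(total_serial) != 1L ||
      is.na(total_serial) || total_serial <= 0)
    stop("`total_serial` must be a single positive number", call. = FALSE)
  if (!is.numeric(total_pvt) || length(total_pvt) != 1L || is.na(total_pvt) ||
      total_pvt < 0)
    stop("`total_pvt` must be a single non-negative number", call. = FALSE)
  (total_serial - total_pvt) / total_serial * 100
}

#' @rdname improvement_pct
#' @param pct Unrounded percentage.
#' @export
format_improvement <- function(pct) {
  sprintf("~%d%%", as.integer(round(pct)))
}

#' Format minutes as hours and minutes
#'
#' @param minutes Non-negative duration in minutes.
#'
#' @return A string like `"4 hrs 44 mins"`.
#' @export
#' @examples
#' format_hm(284)
format_hm <- function(minutes) {
  stopifnot(is.numeric(minutes), length(minutes) == 1L, minutes >= 0)
  h <- floor(minutes / 60)
  m <- minutes - 60 * h
  if (h == 0) sprintf("%g mins", m) else sprintf("%d hrs %g mins", as.integer(h), m)
}

#' Theoretical improvement under an equal left/right split
#'
#' Estimates what the split-run improvement would be if it were computed from
#' the serial per-step column alone: each block step's serial duration is
#' split equally between the two mates (index building is charged in full on
#' each machine, since each machine builds its indices once), the workload's
#' measured transfer times bracket the remote path, and the max-of-paths rule
#' gives each block's effective time.  Per-side durations are rarely equal in
#' practice, so this is an approximation — typically a few points below the
#' improvement computed from measured host/remote columns — and is intended
#' for what-if planning when only a serial profile is available.
#'
#' @param x A [workload()] with a serial step column.
#'
#' @return Unrounded percentage improvement.
#' @export
#' @examples
#' theoretical_improvement_equal_split(workload_table1())  # about 33
theoretical_improvement_equal_split <- function(x) {
  stopifnot(inherits(x, "pvt_workload"))
  if (is.null(x$serial_steps))
    stop("workload has no serial step column", call. = FALSE)
  col <- x$serial_steps
  serial_total <- total_time(x, "serial")$total_min

  side <- function(steps) {
    sum(vapply(steps, function(s) {
      d <- .steps_sum(col, s)
      if (s == "build_index") d else d / 2
    }, numeric(1)))
  }
  per_block <- vapply(x$blocks, function(b) {
    half <- side(b$steps)
    max(transfer_minutes(b$transfer_in) + half + transfer_minutes(b$transfer_out),
        half)
  }, numeric(1))
  pvt_total <- .steps_sum(col, "filter_reads") + sum(per_block) +
    .steps_sum(col, "find_juncs") + .steps_sum(col, "report")
  improvement_pct(serial_total, pvt_total)
}
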