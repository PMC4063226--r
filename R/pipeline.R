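## Five-stage pipeline simulator: one instance per stage, two inter-stage
## buffers mounted alternately, FIFO queue of datasets, hazard-free schedule.

#' Define a pipeline stage
#'
#' @param stage_index Position in the pipeline (contiguous from 1).
#' @param steps Character vector of [step_kinds()] executed by this stage.
#' @param instance_id Identifier of the machine/instance running the stage.
#'
#' @return An object of class `stage_def`.
#' @seealso [default_stages()]
#' @export
stage_def <- function(stage_index, steps, instance_id = paste0("instance-", stage_index)) {
  stage_index <- as.integer(stage_index)
  stopifnot(!is.na(stage_index), stage_index >= 1L)
  unknown <- setdiff(steps, .duration_steps())
  if (length(unknown) > 0L)
    stop("unknown step kind(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(stage_index = stage_index, steps = steps,
                 instance_id = as.character(instance_id)),
            class = "stage_def")
}

#' Default five-stage pipeline
#'
#' Steps are grouped into stages of comparable length so that consecutive
#' datasets overlap well.  Stage II holds `genome_align` alone because it is
#' the most time-consuming step; a larger instance (or a cluster) can then be
#' devoted to it, expressed here simply as a shorter stage-II duration.
#'
#' \tabular{ll}{
#'   I \tab filter_reads, build_index, gene_align \cr
#'   II \tab genome_align \cr
#'   III \tab split_by_chrom, find_juncs, concat_segments \cr
#'   IV \tab junc_align, span_reads \cr
#'   V \tab report \cr
#' }
#'
#' @return List of five [stage_def()] objects.
#' @export
default_stages <- function() {
  list(stage_def(1L, c("filter_reads", "build_index", "gene_align")),
       stage_def(2L, "genome_align"),
       stage_def(3L, c("split_by_chrom", "find_juncs", "concat_segments")),
       stage_def(4L, c("junc_align", "span_reads")),
       stage_def(5L, "report"))
}

#' Validate a stage list
#'
#' Stage indices must be contiguous from 1 and no step may belong to two
#' stages.
#'
#' @param stages List of [stage_def()] objects.
#'
#' @return `stages`, invisibly (errors otherwise).
#' @export
validate_stages <- function(stages) {
  stopifnot(length(stages) >= 1L, all(vapply(stages, inherits, logical(1), "stage_def")))
  idx <- vapply(stages, `[[`, integer(1), "stage_index")
  if (!identical(sort(idx), seq_along(stages)))
    stop("stage indices must be contiguous from 1", call. = FALSE)
  steps <- unlist(lapply(stages, `[[`, "steps"))
  if (anyDuplicated(steps))
    stop("step(s) assigned to more than one stage: ",
         paste(unique(steps[duplicated(steps)]), collapse = ", "), call. = FALSE)
  invisible(stages)
}

#' Per-stage durations of a workload
#'
#' Sums the workload's per-step duration column over each stage's steps.
#' The serial column is used when present (it is the only full per-step
#' mapping); otherwise the host column.
#'
#' @param x A [workload()].
#' @param stages List of [stage_def()] objects.
#'
#' @return Numeric vector of stage durations in minutes, in stage order.
#' @export
stage_durations <- function(x, stages = default_stages()) {
  stopifnot(inherits(x, "pvt_workload"))
  validate_stages(stages)
  col <- if (!is.null(x$serial_steps)) x$serial_steps else x$host_steps
  if (is.null(col)) stop("workload has no per-step duration column", call. = FALSE)
  ord <- order(vapply(stages, `[[`, integer(1), "stage_index"))
  vapply(stages[ord], function(s) .steps_sum(col, s$steps), numeric(1))
}

#' Simulate pipelined processing of a dataset queue
#'
#' One instance is devoted to each stage, so different datasets occupy
#' different stages simultaneously.  Consecutive stages communicate through a
#' pair of buffers mounted alternately (even/odd datasets), because one
#' buffer can be mounted to only one instance at a time.  Stage \eqn{s} of
#' dataset \eqn{j} starts at the earliest instant when
#' \itemize{
#'   \item stage \eqn{s-1} of dataset \eqn{j} has finished and its output
#'     buffer has been remounted (a configurable per-swap cost, default 0);
#'   \item instance \eqn{s} is free, i.e. stage \eqn{s} of dataset
#'     \eqn{j-1} has finished (FIFO queue discipline);
#'   \item a buffer of the pair between stages \eqn{s} and \eqn{s+1} is
#'     free, i.e. stage \eqn{s+1} of dataset \eqn{j - n_{buffers}} has
#'     finished (a dataset holds one buffer of that pair from the start of
#'     stage \eqn{s} until stage \eqn{s+1} finishes reading it).
#' }
#' The schedule is hazard-free by construction (no instance overlap, no
#' buffer mounted twice at once) and deterministic for a given queue order.
#' With equal stage durations \eqn{t} it reproduces the classic pipeline
#' makespan \eqn{(s + n - 1)\,t}.
#'
#' @param workloads List of [workload()] objects (the FIFO queue), or a
#'   numeric matrix of stage durations with one row per dataset and one
#'   column per stage.
#' @param stages List of [stage_def()] objects (ignored for matrix input).
#' @param n_buffers Buffers per adjacent stage pair (default 2).
#' @param remount_min Per-swap buffer remount cost in minutes (default 0).
#'
#' @return An object of class `pipeline_sim`: list with `events` (data frame
#'   of dataset_id, stage_index, start_min, end_min, instance_id, buffers),
#'   `makespan_min`, `serial_total_min`, and `speedup`.
#' @export
#' @examples
#' d <- matrix(10, nrow = 4, ncol = 5)  # 4 identical datasets, equal stages
#' sim <- simulate_pipeline(d)
#' sim$makespan_min                     # (5 + 4 - 1) * 10 = 80
#' sim$speedup                          # 200 / 80 = 2.5
simulate_pipeline <- function(workloads, stages = default_stages(),
                              n_buffers = 2L, remount_min = 0) {
  if (is.matrix(workloads)) {
    durations <- workloads
    ids <- rownames(durations)
    if (is.null(ids)) ids <- paste0("dataset-", seq_len(nrow(durations)))
    instance_ids <- paste0("instance-", seq_len(ncol(durations)))
  } else {
    stopifnot(is.list(workloads),
              all(vapply(workloads, inherits, logical(1), "pvt_workload")))
    validate_stages(stages)
    if (length(workloads) == 0L) stop("empty dataset queue", call. = FALSE)
    durations <- do.call(rbind, lapply(workloads, stage_durations, stages = stages))
    ids <- vapply(workloads, `[[`, character(1), "dataset_id")
    ord <- order(vapply(stages, `[[`, integer(1), "stage_index"))
    instance_ids <- vapply(stages[ord], `[[`, character(1), "instance_id")
  }
  n <- nrow(durations)
  S <- ncol(durations)
  if (n == 0L) stop("empty dataset queue", call. = FALSE)
  if (any(is.na(durations) | durations < 0))
    stop("stage durations must be non-negative", call. = FALSE)
  n_buffers <- as.integer(n_buffers)
  stopifnot(n_buffers >= 1L, remount_min >= 0)

  start <- end <- matrix(0, nrow = n, ncol = S)
  for (j in seq_len(n)) {
    for (s in seq_len(S)) {
      t0 <- 0
      if (s > 1L) t0 <- max(t0, end[j, s - 1L] + remount_min)
      if (j > 1L) t0 <- max(t0, end[j - 1L, s])
      if (s < S && j > n_buffers) t0 <- max(t0, end[j - n_buffers, s + 1L])
      start[j, s] <- t0
      end[j, s] <- t0 + durations[j, s]
    }
  }

  buffers <- function(j, s) {
    parity <- if (j %% 2L == 0L) "even" else "odd"
    used <- character(0)
    if (s > 1L) used <- paste0("buf", s - 1L, "-", s, ".", parity)
    if (s < S) used <- c(used, paste0("buf", s, "-", s + 1L, ".", parity))
    paste(used, collapse = ",")
  }
  events <- data.frame(
    dataset_id = rep(ids, each = S),
    stage_index = rep(seq_len(S), times = n),
    start_min = as.vector(t(start)),
    end_min = as.vector(t(end)),
    instance_id = rep(instance_ids, times = n),
    buffers = unlist(lapply(seq_len(n), function(j)
      vapply(seq_len(S), function(s) buffers(j, s), character(1))))
  )
  serial_total <- sum(durations)
  makespan <- max(events$end_min)
  structure(list(events = events,
                 makespan_min = makespan,
                 serial_total_min = serial_total,
                 speedup = speedup(serial_total, makespan),
                 n_datasets = n, n_stages = S),
            class = "pipeline_sim")
}

#' @export
print.pipeline_sim <- function(x, ...) {
  cat(sprintf("Pipeline simulation: %d dataset(s) x %d stage(s)\n",
              x$n_datasets, x$n_stages))
  cat(sprintf("  makespan     %g min\n", x$makespan_min))
  cat(sprintf("  serial total %g min\n", x$serial_total_min))
  cat(sprintf("  speedup      %.3f\n", x$speedup))
  invisible(x)
}

#' Pipeline speedup
#'
#' Ratio of the serial processing time of the whole queue to the pipelined
#' makespan.  For \eqn{n} datasets with equal stage durations over \eqn{s}
#' stages this is \eqn{sn/(s+n-1)}, approaching \eqn{s} for long queues.
#'
#' @param serial_total Total serial time in minutes.
#' @param makespan Pipelined completion time in minutes; must be positive.
#'
#' @return Dimensionless ratio.
#' @export
#' @examples
#' speedup(100, 50)  # 2
speedup <- function(serial_total, makespan) {
  if (!is.numeric(makespan) || length(makespan) != 1L || is.na(makespan) ||
      makespan <= 0)
    stop("`makespan` must be a single positive number", call. = FALSE)
  serial_total / makespan
}

#' Write the simulated schedule as TSV
#'
#' One row per (dataset, stage) event with columns `dataset`, `stage`,
#' `instance`, `start`, `end`, sorted by start time (ties keep queue order),
#' suitable for plotting as a Gantt chart.
#'
#' @param result A [simulate_pipeline()] result.
#' @param path Output TSV path.
#'
#' @return `path`, invisibly.
#' @export
gantt_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_sim"))
  ev <- result$events
  ev <- ev[order(ev$start_min), , drop = FALSE]  # stable: ties keep queue order
  out <- data.frame(dataset = ev$dataset_id, stage = ev$stage_index,
                    instance = ev$instance_id, start = ev$start_min,
                    end = ev$end_min)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
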