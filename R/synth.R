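## Seeded synthetic fixtures: SAM streams, workload configs, and the bundled
## paired-end worked example.

## run `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic SAM stream
#'
#' @param seed Integer RNG seed; the same spec always yields byte-identical
#'   output.
#' @param n_reads Number of records to emit.
#' @param chrom_profile Data frame with columns `name`, `length` (bp) and
#'   `abundance` (relative mapped-read abundance; must sum to 1 within 1e-9).
#' @param unmapped_frac Fraction of records left unmapped (RNAME `"*"`).
#' @param read_len Read length in bp (placed so reads fit their chromosome).
#'
#' @return An object of class `synth_spec`.
#' @export
#' @examples
#' synth_spec(7, 100, data.frame(name = c("chrA", "chrB"),
#'                               length = c(1000, 500),
#'                               abundance = c(0.5, 0.5)))
synth_spec <- function(seed, n_reads, chrom_profile, unmapped_frac = 0,
                       read_len = 50L) {
  stopifnot(is.data.frame(chrom_profile),
            all(c("name", "length", "abundance") %in% names(chrom_profile)))
  if (abs(sum(chrom_profile$abundance) - 1) > 1e-9)
    stop("chromosome abundances must sum to 1", call. = FALSE)
  if (any(chrom_profile$abundance < 0) || any(chrom_profile$length < 1))
    stop("abundances must be non-negative and lengths positive", call. = FALSE)
  if (!is.numeric(unmapped_frac) || unmapped_frac < 0 || unmapped_frac > 1)
    stop("`unmapped_frac` must be in [0, 1]", call. = FALSE)
  read_len <- as.integer(read_len)
  stopifnot(read_len >= 1L, all(chrom_profile$length >= read_len))
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 chrom_profile = chrom_profile,
                 unmapped_frac = as.numeric(unmapped_frac),
                 read_len = read_len),
            class = "synth_spec")
}

#' Generate a synthetic SAM stream
#'
#' Writes a minimal valid SAM text: `@HD`, one `@SQ` per chromosome, then
#' `n_reads` records.  Mapped records are assigned to chromosomes
#' multinomially with the spec's abundances and given uniform positions;
#' sequence and quality are `"*"` since downstream consumers only inspect
#' QNAME/FLAG/RNAME.  Output is byte-identical across runs for a fixed spec.
#'
#' @param spec A [synth_spec()].
#' @param path Output file path.
#'
#' @return Named numeric vector of per-chromosome mapped-record counts plus
#'   `"*"` (unmapped), invisibly.
#' @export
generate_sam <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  prof <- spec$chrom_profile
  with_seed(spec$seed, {
    n <- spec$n_reads
    unmapped <- if (spec$unmapped_frac >= 1) rep(TRUE, n)
                else if (spec$unmapped_frac <= 0) rep(FALSE, n)
                else stats::runif(n) < spec$unmapped_frac
    chrom <- rep("*", n)
    n_mapped <- sum(!unmapped)
    if (n_mapped > 0L)
      chrom[!unmapped] <- sample(prof$name, n_mapped, replace = TRUE,
                                 prob = prof$abundance)
    pos <- integer(n)
    for (i in seq_len(nrow(prof))) {
      sel <- chrom == prof$name[i]
      if (any(sel))
        pos[sel] <- sample.int(prof$length[i] - spec$read_len + 1L, sum(sel),
                               replace = TRUE)
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", prof$name, as.integer(prof$length)))
    records <- sprintf("read%06d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                       seq_len(n),
                       ifelse(unmapped, 4L, 0L),
                       chrom,
                       ifelse(unmapped, 0L, pos),
                       ifelse(unmapped, 0L, 255L),
                       ifelse(unmapped, "*", paste0(spec$read_len, "M")))
    writeLines(c(header, records), path)
    tab <- table(factor(chrom, levels = c(prof$name, "*")))
    invisible(stats::setNames(as.integer(tab), names(tab)))
  })
}

#' Generate a synthetic FASTA index
#'
#' Writes a 5-column `.fai` for the spec's chromosomes (offsets are
#' synthesised assuming 60-column FASTA lines).
#'
#' @param chrom_profile Data frame with columns `name` and `length`.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
generate_fai <- function(chrom_profile, path) {
  stopifnot(is.data.frame(chrom_profile),
            all(c("name", "length") %in% names(chrom_profile)))
  len <- as.integer(chrom_profile$length)
  nlines <- ceiling(len / 60)
  offset <- cumsum(c(0, utils::head(nchar(chrom_profile$name) + 2L + len + nlines, -1)))
  writeLines(sprintf("%s\t%d\t%.0f\t60\t61", chrom_profile$name, len,
                     offset + nchar(chrom_profile$name) + 2L),
             path)
  invisible(path)
}

#' Generate a random workload
#'
#' Emits a plausible paired-end workload for property-based exercise of the
#' timing model and the pipeline simulator.  Serial per-step durations are
#' drawn uniformly from ranges shaped like a real paired-end profile (the
#' alignment steps dominate; junction discovery and reporting are mid-sized).
#' The host/remote columns split each mate-parallel step according to the
#' two sides' read counts, charge index building in full on both machines,
#' and leave the serially executed steps slightly cheaper than the serial
#' column (one machine is otherwise idle, so there is no contention).
#'
#' @param seed Integer RNG seed.
#' @param dataset_id Identifier (default derived from the seed).
#' @param max_transfer_min Upper bound for the block-1 transfer durations in
#'   minutes; `0` produces a transfer-free workload.  Block-2 transfers are
#'   always emitted as negligible (they move only junction lists).
#'
#' @return A [workload()].
#' @export
#' @examples
#' w <- generate_workload(1)
#' total_time(w, "serial")$total_min >= total_time(w, "pvt")$total_min
generate_workload <- function(seed, dataset_id = sprintf("synth-%d", seed),
                              max_transfer_min = 5) {
  stopifnot(is.numeric(max_transfer_min), max_transfer_min >= 0)
  with_seed(seed, {
    runif1 <- function(lo, hi) stats::runif(1, lo, hi)
    serial <- c(filter_reads = runif1(10, 30),
                build_index = runif1(3, 10),
                gene_align = runif1(40, 120),
                genome_align = runif1(50, 140),
                find_juncs = runif1(5, 20),
                junc_align = runif1(5, 25),
                span_reads = runif1(3, 15),
                report = runif1(20, 60))
    reads_left <- round(runif1(5e6, 40e6))
    reads_right <- round(runif1(5e6, 40e6))
    frac_left <- reads_left / (reads_left + reads_right)
    sides <- assign_sides(reads_left, reads_right)
    frac_high <- max(frac_left, 1 - frac_left)

    split_steps <- c("gene_align", "genome_align", "junc_align", "span_reads")
    host <- remote <- numeric(0)
    for (s in split_steps) {
      host[s] <- serial[[s]] * frac_high
      remote[s] <- serial[[s]] * (1 - frac_high)
    }
    host["build_index"] <- remote["build_index"] <- serial[["build_index"]]
    for (s in c("filter_reads", "find_juncs", "report"))
      host[s] <- serial[[s]] * runif1(0.85, 1)

    transfers <- list(
      "1_in" = transfer_spec(runif1(0, 1) * max_transfer_min),
      "1_out" = transfer_spec(runif1(0, 1) * max_transfer_min),
      "2_in" = transfer_spec(runif1(0, 0.5), negligible = TRUE),
      "2_out" = transfer_spec(runif1(0, 0.5), negligible = TRUE))

    workload(dataset_id = dataset_id, paired = TRUE,
             reads_left = reads_left, reads_right = reads_right,
             serial_steps = serial, host_steps = host, remote_steps = remote,
             transfers = transfers)
  })
}

#' The bundled paired-end worked example
#'
#' The published step-duration profile of a 45 M-read paired-end RNA-seq
#' dataset (pancreatic islets, SRA run SRR1027730) measured on two identical
#' 8-core/16 GB machines: the serial column is a plain TopHat run; the
#' host/remote columns are the split run in which the right mate file (the
#' smaller after filtering) was processed remotely.  Block-1 transfers took
#' 5 and 3 minutes; block-2 transfers (~22 s and ~24 s) are flagged
#' negligible.  The same workload ships as a YAML config at
#' `system.file("extdata", "table1.yaml", package = "pvtplan")`.
#'
#' Read counts are nominal (the published per-side filtered counts round to
#' the totals used here) and only determine the side assignment.
#'
#' @return A [workload()].
#' @export
#' @examples
#' w <- workload_table1()
#' total_time(w, "serial")$total_min  # 284
#' total_time(w, "pvt")$total_min    # 168
workload_table1 <- function() {
  workload(
    dataset_id = "SRR1027730",
    paired = TRUE,
    reads_left = 23e6,
    reads_right = 22e6,
    serial_steps = c(filter_reads = 22, build_index = 6, gene_align = 83,
                     genome_align = 94, find_juncs = 12, junc_align = 17,
                     span_reads = 10, report = 40),
    host_steps = c(filter_reads = 21, build_index = 6, gene_align = 42,
                   genome_align = 39, find_juncs = 9, junc_align = 2,
                   span_reads = 3, report = 41),
    remote_steps = c(build_index = 6, gene_align = 37, genome_align = 41,
                     junc_align = 2, span_reads = 3),
    transfers = list("1_in" = transfer_spec(5),
                     "1_out" = transfer_spec(3),
                     "2_in" = transfer_spec(22 / 60, negligible = TRUE),
                     "2_out" = transfer_spec(24 / 60, negligible = TRUE))
  )
}
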