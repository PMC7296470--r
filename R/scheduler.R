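# Master-worker execution of the Welch estimator: round-robin allocation of
# segments to worker ranks, per-worker periodogram computation, and a
# deterministic reduce on the master. The master (rank 0) takes its own share
# of segments; it is not a pure coordinator. Reduction re-sorts periodograms
# into ascending segment-index order so the floating-point accumulation order
# is identical to the serial path, making the output bitwise-reproducible for
# any worker count and any result-arrival order.

#' Round-robin allocation of segments to workers
#'
#' Segment j is assigned to worker rank j mod n_workers, so worker loads
#' differ by at most one segment. With 7 segments over 4 workers the mapping
#' is 0,1,2,3,0,1,2: worker 0 holds segments 0 and 4.
#'
#' @param n_segments number of segments Ns (>= 1).
#' @param n_workers number of worker ranks ("size", >= 1).
#' @return An object of class `task_assignment`: `n_workers` and `mapping`,
#'   an integer vector where `mapping[j + 1]` is the rank of segment j.
#' @examples
#' allocate_tasks(7, 4)$mapping # 0 1 2 3 0 1 2
#' @export
allocate_tasks <- function(n_segments, n_workers) {
  n_segments <- as.integer(n_segments)
  n_workers <- as.integer(n_workers)
  if (is.na(n_segments) || n_segments < 1L) {
    stop("'n_segments' must be a positive integer")
  }
  if (is.na(n_workers) || n_workers < 1L) {
    stop("'n_workers' must be a positive integer")
  }
  structure(
    list(
      n_workers = n_workers,
      mapping = (seq_len(n_segments) - 1L) %% n_workers
    ),
    class = "task_assignment"
  )
}

#' Segments assigned to one rank
#'
#' @param assignment a [allocate_tasks()] result.
#' @param rank worker rank in 0..n_workers-1.
#' @return 0-based segment indices held by `rank`, ascending.
#' @export
assigned_segments <- function(assignment, rank) {
  stopifnot(inherits(assignment, "task_assignment"))
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 0L || rank >= assignment$n_workers) {
    stop(sprintf(
      "rank %d out of range (n_workers = %d)", rank, assignment$n_workers
    ))
  }
  which(assignment$mapping == rank) - 1L
}

#' One worker's share of the map stage
#'
#' Computes the windowed periodogram of every assigned segment via
#' [segment_periodogram()], in ascending segment-index order. An empty
#' assignment (idle worker, when n_workers > Ns) yields an empty result.
#'
#' @param channel a [signal_channel()].
#' @param plan the [plan_segments()] result.
#' @param window the [make_window()] result.
#' @param config the [welch_config()].
#' @param assigned 0-based segment indices for this worker.
#' @param rank worker rank (carried into error messages and the result).
#' @return An object of class `worker_result`: `rank` and `periodograms`, a
#'   list of `periodogram` objects.
#' @export
worker_compute <- function(channel, plan, window, config, assigned,
                           rank = 0L) {
  assigned <- sort(as.integer(assigned))
  pgs <- lapply(assigned, function(i) {
    tryCatch(
      segment_periodogram(channel, plan, i, window, config),
      error = function(e) {
        stop(sprintf("worker rank %d: %s", rank, conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
  structure(
    list(rank = as.integer(rank), periodograms = pgs),
    class = "worker_result"
  )
}

#' Deterministic reduce of worker results into a PSD
#'
#' Verifies that the union of segment indices across all worker results is
#' exactly 0..Ns-1 with no duplicates (a missing or repeated index signals a
#' lost or duplicated worker message), re-sorts the periodograms into
#' ascending segment-index order, and averages them. Because the accumulation
#' order is forced, the output is bitwise-identical to [welch_psd()] no matter
#' in which order worker results arrive.
#'
#' @param results list of `worker_result` objects.
#' @param plan the [plan_segments()] result.
#' @param config the [welch_config()].
#' @param label channel identifier for the output.
#' @param fs sampling rate in Hz (for the frequency axis).
#' @return A `psd_result`.
#' @export
reduce_psd <- function(results, plan, config, label, fs) {
  stopifnot(inherits(plan, "segment_plan"), inherits(config, "welch_config"))
  pgs <- unlist(lapply(results, function(r) r$periodograms),
                recursive = FALSE)
  idx <- vapply(pgs, function(p) p$segment_index, integer(1L))
  expected <- seq_len(plan$n_segments) - 1L
  dup <- idx[duplicated(idx)]
  if (length(dup)) {
    stop(sprintf(
      "duplicate periodogram for segment index %d in worker results", dup[1L]
    ))
  }
  missing <- setdiff(expected, idx)
  if (length(missing)) {
    stop(sprintf(
      "missing periodogram for segment index %d in worker results",
      missing[1L]
    ))
  }
  extra <- setdiff(idx, expected)
  if (length(extra)) {
    stop(sprintf(
      "unexpected segment index %d in worker results (Ns = %d)",
      extra[1L], plan$n_segments
    ))
  }
  ord <- order(idx)
  acc <- NULL
  for (j in ord) {
    v <- pgs[[j]]$values
    acc <- if (is.null(acc)) v else acc + v
  }
  psd_result(
    label = label,
    freqs = frequency_axis(config$seg_len, fs, config$sided),
    psd = acc / plan$n_segments,
    n_segments_used = plan$n_segments,
    config = config
  )
}

backend_names <- c("serial", "process", "cluster", "message-passing")

run_ranks <- function(backend, n_workers, rank_fun) {
  ranks <- seq_len(n_workers) - 1L
  if (backend == "serial" || n_workers == 1L) {
    return(lapply(ranks, rank_fun))
  }
  if (backend == "process") {
    res <- parallel::mclapply(ranks, rank_fun, mc.cores = n_workers)
    bad <- vapply(res, inherits, logical(1L), what = "try-error")
    if (any(bad)) {
      stop("worker process failed: ",
           conditionMessage(attr(res[[which(bad)[1L]]], "condition")))
    }
    return(res)
  }
  # socket cluster: master broadcasts the task closure, workers attach the
  # installed namespace, results are gathered tagged by rank
  cl <- parallel::makePSOCKcluster(n_workers)
  on.exit(parallel::stopCluster(cl), add = TRUE)
  parallel::clusterCall(cl, function(lp) .libPaths(lp), .libPaths())
  parallel::clusterEvalQ(cl, loadNamespace("eegwelch"))
  parallel::parLapply(cl, ranks, rank_fun)
}

#' Parallel Welch estimate (split / map / reduce)
#'
#' Runs the full master-worker pipeline on one channel: plan the segments,
#' allocate them round-robin over `n_workers` ranks, compute each rank's
#' periodograms on the selected backend, and reduce on the master in forced
#' segment order. For every backend and worker count the result is
#' bitwise-identical to the serial [welch_psd()].
#'
#' Backends: `"serial"` runs the ranks sequentially in-process (the reference
#' emulation, always available); `"process"` uses a forked local process pool;
#' `"cluster"` (alias `"message-passing"`) uses a socket-connected worker pool
#' in which the master broadcasts tasks and gathers tagged results.
#'
#' @param channel a [signal_channel()].
#' @param config a [welch_config()].
#' @param backend one of "serial", "process", "cluster", "message-passing".
#' @param n_workers number of worker ranks (>= 1).
#' @return A `psd_result`, bitwise-equal to `welch_psd(channel, config)`.
#' @examples
#' ch <- signal_channel(rnorm(256), fs = 256)
#' identical(parallel_welch(ch, n_workers = 4)$psd, welch_psd(ch)$psd) # TRUE
#' @export
parallel_welch <- function(channel, config = welch_config(),
                           backend = "serial", n_workers = 1L) {
  stopifnot(inherits(channel, "signal_channel"))
  backend <- match.arg(backend, backend_names)
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) {
    stop("'n_workers' must be a positive integer")
  }
  plan <- plan_segments(length(channel$samples), config)
  win <- make_window(config$window, config$convention, config$seg_len)
  assignment <- allocate_tasks(plan$n_segments, n_workers)
  rank_fun <- function(rank) {
    worker_compute(
      channel, plan, win, config,
      assigned = assigned_segments(assignment, rank), rank = rank
    )
  }
  results <- run_ranks(backend, n_workers, rank_fun)
  reduce_psd(results, plan, config, label = channel$label, fs = channel$fs)
}

#' Measure speedup of the parallel estimator
#'
#' Times the same workload (Welch PSD of one or more channels) serially and
#' at each requested worker count, and reports speedup = Ts/Tp, the serial
#' wall time divided by the parallel wall time. The serial baseline is
#' measured first with the sequential emulation backend and is always the
#' first row, with speedup exactly 1. Wall times are measured (minimum over
#' `repetitions` runs) and reported, never asserted: observed speedup depends
#' entirely on the host.
#'
#' @param channels a [signal_channel()] or list of them (the workload).
#' @param config a [welch_config()].
#' @param worker_counts integer vector of worker counts to measure.
#' @param repetitions timing repetitions per row (>= 1); the minimum is kept.
#' @param backend backend used for the parallel rows.
#' @return A data.frame with columns `n_workers`, `time_s`, `speedup`.
#' @export
benchmark_speedup <- function(channels, config = welch_config(),
                              worker_counts = c(2L, 4L), repetitions = 3L,
                              backend = "process") {
  if (inherits(channels, "signal_channel")) channels <- list(channels)
  backend <- match.arg(backend, backend_names)
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1L) {
    stop("'repetitions' must be a positive integer")
  }
  worker_counts <- as.integer(worker_counts)
  if (any(is.na(worker_counts)) || any(worker_counts < 1L)) {
    stop("'worker_counts' must be positive integers")
  }
  time_once <- function(bk, w) {
    min(vapply(seq_len(repetitions), function(r) {
      unname(system.time(
        for (ch in channels) parallel_welch(ch, config, bk, w)
      )[["elapsed"]])
    }, numeric(1L)))
  }
  ts <- time_once("serial", 1L)
  rows <- data.frame(n_workers = 1L, time_s = ts, speedup = 1.0)
  for (w in setdiff(worker_counts, 1L)) {
    tp <- time_once(backend, w)
    rows <- rbind(rows, data.frame(
      n_workers = w, time_s = tp, speedup = ts / tp
    ))
  }
  rownames(rows) <- NULL
  rows
}

#' Write a speedup table as tab-separated text
#'
#' @param bench the [benchmark_speedup()] data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_speedup_table <- function(bench, path) {
  stopifnot(is.data.frame(bench),
            all(c("n_workers", "time_s", "speedup") %in% names(bench)))
  utils::write.table(
    bench[c("n_workers", "time_s", "speedup")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
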