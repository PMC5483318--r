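#' A worker pool for co-run execution
#'
#' Generalizes the heterogeneous CPU/GPU pair to two configurable CPU
#' worker pools. `task_cost` is a testing hook: when set, capability
#' measurement uses a fake clock charging `task_cost` time units per task
#' instead of wall time, making [estimate_ratio()] deterministic.
#'
#' @param workers number of parallel workers (0 = pool disabled)
#' @param task_cost optional simulated per-task duration (fake clock)
#' @param name label used in reports
#' @return an object of class `"worker_pool"`
#' @export
worker_pool <- function(workers = 1L, task_cost = NULL, name = "pool") {
  workers <- as.integer(workers)
  stopifnot(workers >= 0L, is.null(task_cost) || task_cost > 0)
  structure(list(workers = workers, task_cost = task_cost, name = name),
            class = "worker_pool")
}

#' Split n tasks between two pools by capability ratio
#'
#' Pool 1 receives `n1 = round(n / (R + 1))` tasks and pool 2 the
#' remaining `n2 = n - n1`, where `R = t1 / t2` is pool 2's capability
#' relative to pool 1 (pool 1 slower means larger `R`, fewer tasks for
#' pool 1). Rounding is round-half-even; `|n1 - n/(R+1)| <= 1` always
#' holds and `n2` is non-decreasing in `R` at fixed `n`.
#'
#' @param n total task count (>= 0)
#' @param ratio_R positive capability ratio `t1 / t2`
#' @return integer vector `c(n1, n2)` with `n1 + n2 == n`
#' @export
#' @examples
#' partition_tasks(100, 1.0)     # 50 50
#' partition_tasks(100, 1.423)   # 41 59
partition_tasks <- function(n, ratio_R) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (!is.numeric(ratio_R) || length(ratio_R) != 1L || ratio_R <= 0)
    stop("capability ratio R must be a positive number")
  n1 <- as.integer(round(n / (ratio_R + 1)))
  c(n1 = n1, n2 = n - n1)
}

# fake or wall clock for one pool aligning `tasks` center/other pairs
pool_elapsed <- function(pool, center, others, scheme, band) {
  if (!is.null(pool$task_cost)) return(pool$task_cost * length(others))
  t0 <- proc.time()[["elapsed"]]
  pool_lapply(pool, others, function(o) align_one(center, o, scheme, band))
  max(proc.time()[["elapsed"]] - t0, .Machine$double.eps)
}

#' Measure the capability ratio of two pools
#'
#' Pre-computation step: both pools align the same small sample of
#' center/other tasks; the ratio `R = t1 / t2` of their elapsed times
#' drives [partition_tasks()]. The default sample size is
#' `min(max(32, 1% of n), floor(n/2))` (at least 1). A pool with 0
#' workers is treated as zero-capacity: all tasks go to the other pool
#' (`R = 0` when pool 2 is absent, `R = Inf` when pool 1 is).
#'
#' @param data an `msa_dataset`
#' @param center_index 0-based center index
#' @param pool1,pool2 [worker_pool()]s
#' @param scheme a [scoring_scheme()]
#' @param band optional k-band half-width passed to the aligner
#' @param sample_size number of sample tasks (default as above)
#' @return list with `t1`, `t2`, `ratio_R`, `sample_size`
#' @export
estimate_ratio <- function(data, center_index, pool1, pool2,
                           scheme = scoring_scheme(), band = NULL,
                           sample_size = NULL) {
  stopifnot(inherits(data, "msa_dataset"),
            inherits(pool1, "worker_pool"), inherits(pool2, "worker_pool"))
  ci <- as.integer(center_index)
  others <- data$seq[-(ci + 1L)]
  n <- length(others)
  if (n == 0L) stop("no alignment tasks to sample")
  if (pool1$workers == 0L && pool2$workers == 0L)
    stop("both worker pools are disabled")
  if (pool2$workers == 0L)
    return(list(t1 = NA_real_, t2 = NA_real_, ratio_R = 0, sample_size = 0L))
  if (pool1$workers == 0L)
    return(list(t1 = NA_real_, t2 = NA_real_, ratio_R = Inf,
                sample_size = 0L))
  if (is.null(sample_size))
    sample_size <- max(min(max(32L, ceiling(0.01 * n)), n %/% 2L), 1L)
  sample_size <- min(as.integer(sample_size), n)
  sample <- others[seq_len(sample_size)]
  center <- data$seq[ci + 1L]
  t1 <- pool_elapsed(pool1, center, sample, scheme, band)
  t2 <- pool_elapsed(pool2, center, sample, scheme, band)
  list(t1 = t1, t2 = t2, ratio_R = t1 / t2, sample_size = sample_size)
}

align_one <- function(center, other, scheme, band) {
  if (is.null(band)) nw_align(center, other, scheme)
  else kband_align(center, other, scheme, k = band)
}

# run fun over items on one pool; order-preserving
pool_lapply <- function(pool, items, fun) {
  if (length(items) == 0L) return(list())
  if (pool$workers <= 1L) return(lapply(items, fun))
  parallel::mclapply(items, fun, mc.cores = pool$workers,
                     mc.preschedule = TRUE)
}

#' Align every non-center sequence to the center on two pools
#'
#' Tasks are split between the pools with [partition_tasks()] (the ratio
#' is measured with [estimate_ratio()] unless supplied) and executed in
#' parallel. Workers share no mutable state and results are collected in
#' dataset order, so the output is bit-identical to a serial run
#' regardless of pool counts, split, or completion order.
#'
#' @inheritParams estimate_ratio
#' @param ratio optional fixed capability ratio `R` (skips measurement)
#' @param align_fun alignment function `(center, other) -> pairwise
#'   alignment`; the default uses `scheme` and `band`. Exposed for fault
#'   injection in tests.
#' @return list with `alignments` (one `"pairwise_alignment"` per
#'   non-center sequence, dataset order), `n1`, `n2`, `ratio`
#' @export
run_corun <- function(data, center_index, scheme = scoring_scheme(),
                      band = NULL, pool1 = worker_pool(1L),
                      pool2 = worker_pool(0L), ratio = NULL,
                      align_fun = NULL) {
  stopifnot(inherits(data, "msa_dataset"), n_seq(data) >= 2L,
            inherits(pool1, "worker_pool"), inherits(pool2, "worker_pool"))
  ci <- as.integer(center_index)
  if (ci < 0L || ci >= n_seq(data)) stop("center index out of range")
  center <- data$seq[ci + 1L]
  others <- setdiff(seq_len(n_seq(data)), ci + 1L)
  n <- length(others)
  if (is.null(align_fun))
    align_fun <- function(center, other) align_one(center, other, scheme,
                                                   band)
  if (pool1$workers == 0L && pool2$workers == 0L)
    stop("both worker pools are disabled")
  if (is.null(ratio)) {
    if (pool1$workers == 0L) ratio <- Inf
    else if (pool2$workers == 0L) ratio <- 0
    else ratio <- estimate_ratio(data, ci, pool1, pool2, scheme,
                                 band)$ratio_R
  }
  if ((is.finite(ratio) && ratio == 0) || pool2$workers == 0L) {
    split <- c(n1 = n, n2 = 0L)
  } else if (is.infinite(ratio) || pool1$workers == 0L) {
    split <- c(n1 = 0L, n2 = n)
  } else {
    split <- partition_tasks(n, ratio)
  }
  idx1 <- others[seq_len(split[["n1"]])]
  idx2 <- setdiff(others, idx1)
  worker <- function(i) {
    tryCatch(align_fun(center, data$seq[i]),
             error = function(e) structure(list(index = i,
                                                message = conditionMessage(e)),
                                           class = "starmsa_task_error"))
  }
  res <- c(pool_lapply(pool1, idx1, worker),
           pool_lapply(pool2, idx2, worker))
  ord <- order(c(idx1, idx2))
  res <- res[ord]
  for (r in res) {
    if (inherits(r, "starmsa_task_error") || inherits(r, "try-error"))
      stop(sprintf("alignment of sequence '%s' failed: %s",
                   data$id[r$index], r$message))
    if (!inherits(r, "pairwise_alignment"))
      stop("worker returned an unexpected object")
  }
  list(alignments = res, n1 = split[["n1"]], n2 = split[["n2"]],
       ratio = ratio)
}
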