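#' Ring partition of cells over gap kernels
#'
#' Splits the cells over `K` gap kernels arranged in a ring, emulating the
#' systolic multi-accelerator layout.  Blocks are contiguous, equally sized
#' cell-index ranges; when `K` does not divide the cell count the last block
#' is padded with phantom cells carrying zero weights, whose currents are
#' discarded on output.
#'
#' @param n_cells number of real cells (`>= 1`).
#' @param K number of gap kernels (`>= 1`).
#' @return An object of class `partition_plan` with fields `K`,
#'   `block_size`, `n_real`, `n_padded`, `n_phantom`, and `blocks` (a list of
#'   integer index vectors into the padded cell range).
#' @export
make_partition <- function(n_cells, K) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("'n_cells' must be >= 1", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K < 1)
    stop("'K' must be >= 1", call. = FALSE)
  n_cells <- as.integer(n_cells); K <- as.integer(K)
  block_size <- as.integer(ceiling(n_cells / K))
  n_padded <- block_size * K
  blocks <- lapply(seq_len(K), function(k)
    seq.int((k - 1L) * block_size + 1L, k * block_size))
  structure(
    list(K = K, block_size = block_size, n_real = n_cells,
         n_padded = n_padded, n_phantom = n_padded - n_cells, blocks = blocks),
    class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("<partition_plan>", x$K, "kernel(s) x block size", x$block_size,
      "=", x$n_padded, "cells (", x$n_phantom, "phantom )\n")
  invisible(x)
}

#' Three-phase ring schedule
#'
#' The systolic schedule over which voltage blocks circulate: at stage `s`
#' (0-based), kernel `k` consumes block `((k - s - 1) mod K) + 1` and, except
#' in the final stage, forwards it to kernel `k + 1` on the ring.  Stage 0 is
#' the `start` phase (each kernel uses its own block), stages
#' `1 .. K - 2` are `middle` phases (use the received block), and stage
#' `K - 1` is the `end` phase (use the final block and update voltages).
#' After `K` stages every kernel has consumed every block exactly once.
#' `K = 1` collapses to a single local stage and `K = 2` to start + end.
#'
#' @param plan a [make_partition()] plan.
#' @return A data frame with one row per (stage, kernel): columns `stage`
#'   (0-based), `phase`, `kernel`, `block` (1-based), and `forwards`
#'   (logical: does the kernel send the consumed block on this stage).
#' @export
ring_schedule <- function(plan) {
  stopifnot(inherits(plan, "partition_plan"))
  K <- plan$K
  stages <- rep(seq_len(K) - 1L, each = K)
  kernels <- rep(seq_len(K), times = K)
  blocks <- ((kernels - 1L - stages) %% K) + 1L
  phase <- ifelse(stages == 0L, "start",
                  ifelse(stages == K - 1L, "end", "middle"))
  if (K == 1L) phase <- "start"        # single local stage, no transfers
  data.frame(stage = stages, phase = phase, kernel = kernels, block = blocks,
             forwards = stages < K - 1L, stringsAsFactors = FALSE)
}

# Flat scalar accumulation of gap terms for the cells of one block, over
# source blocks in the given order.  Plain double accumulation (no long
# double) so that identical orders give bit-identical results.
.gap_accumulate <- function(w, v, c0, c1, c2, targets, source_blocks) {
  out <- numeric(length(targets))
  for (ti in seq_along(targets)) {
    i <- targets[ti]
    acc <- 0
    for (blk in source_blocks) {
      for (j in blk) {
        if (j == i) next
        vij <- v[i] - v[j]
        acc <- acc + w[i, j] * (c0 * exp(c1 * vij * vij) + c2) * vij
      }
    }
    out[ti] <- acc
  }
  out
}

#' Ring-partitioned gap-junction currents
#'
#' Computes the same per-cell gap currents as [gap_current_dense()] by
#' executing the three-phase ring schedule: each kernel holds one block of
#' gap-compartment voltages, accumulates its cells' partial sums block by
#' block as voltage blocks circulate, and discards phantom-cell output.
#'
#' With `order = "ascending"` (default) each kernel accumulates its partial
#' sums over source blocks in ascending block index, which makes the result
#' a flat ascending-index summation: bit-identical for every `K` and to the
#' dense oracle.  With `order = "schedule"` the accumulation follows the
#' ring arrival order (local block first, then received blocks), as the
#' hardware pipeline does; that differs from the dense oracle only by
#' floating-point reassociation (relative error around 1e-16 per term,
#' bounded well below 1e-10 in total).
#'
#' @param model a [network_model()] with gap constants and weights, or a
#'   plain weight matrix (then pass `c0`, `c1`, `c2`).
#' @param v_gap gap-compartment voltages of the real cells.
#' @param plan a [make_partition()] plan for `length(v_gap)` cells.
#' @param order `"ascending"` or `"schedule"` (see Details).
#' @param c0,c1,c2 gap constants when `model` is a bare matrix.
#' @return Numeric vector of per-cell gap currents (real cells only).
#' @export
compute_gap_partitioned <- function(model, v_gap, plan,
                                    order = c("ascending", "schedule"),
                                    c0 = NULL, c1 = NULL, c2 = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(plan, "partition_plan"))
  if (inherits(model, "network_model")) {
    w <- realized_weights(model)
    c0 <- model$c0; c1 <- model$c1; c2 <- model$c2
  } else {
    w <- as.matrix(model)
    stopifnot(!is.null(c0), !is.null(c1), !is.null(c2))
  }
  n <- length(v_gap)
  if (n != plan$n_real)
    stop("plan was made for ", plan$n_real, " cells but ", n,
         " voltages were supplied", call. = FALSE)
  if (nrow(w) != n || ncol(w) != n)
    stop("weight matrix shape does not match the number of voltages",
         call. = FALSE)
  # pad with phantom cells: zero weights, zero voltage
  np <- plan$n_padded
  if (np > n) {
    wp <- matrix(0, np, np); wp[seq_len(n), seq_len(n)] <- w
    vp <- c(v_gap, numeric(np - n))
  } else {
    wp <- w; vp <- v_gap
  }
  sched <- ring_schedule(plan)
  out <- numeric(np)
  for (k in seq_len(plan$K)) {
    visit <- sched$block[sched$kernel == k][order(sched$stage[sched$kernel == k])]
    if (order == "ascending") visit <- sort(visit)
    out[plan$blocks[[k]]] <- .gap_accumulate(
      wp, vp, c0, c1, c2, plan$blocks[[k]], plan$blocks[visit])
  }
  out[seq_len(n)]
}
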