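# Monte-Carlo simulator for the average-case recursion-cost law.  Each
# composite call of size N splits uniformly at random into sub-chains of
# sizes m and N - m and adds N to the cost (loop walk plus the final
# Boolean operation); the recursion bottoms out at single widgets of
# cost 1.  The expectation of the simulated cost-per-widget is exactly
# 1 + 2 (H_N - 1), the harmonic-sum closed form 1 + 2 (ln N + 0.577 - 1)
# of the average-case analysis (quicksort-like recurrence).

#' Simulate the average-case recursion cost
#'
#' Draws `reps` independent realizations of the cost recurrence
#' `T(1) = 1`, `T(N) = T(m) + T(N - m) + N` with the split position `m`
#' uniform on `1..N-1`, and returns the mean cost per widget
#' `mean(T(N)) / N`.  As `reps` grows this converges to
#' `1 + 2 (ln N + 0.577 - 1)`.
#'
#' @param n Number of widgets (N >= 1).
#' @param reps Number of Monte-Carlo repetitions.
#' @param seed Optional integer seed; the RNG state is restored on exit.
#' @return Mean simulated cost per widget (a single number).
#' @examples
#' simulate_average_recurrence(1000, reps = 50, seed = 1)
#' 1 + 2 * (log(1000) + 0.577 - 1)
#' @export
simulate_average_recurrence <- function(n, reps, seed = NULL) {
  stopifnot(n >= 1L, reps >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  if (n == 1L) return(1)
  totals <- vapply(seq_len(reps), function(r) .sim_one(n), numeric(1L))
  mean(totals) / n
}

.sim_one <- function(n) {
  stack <- integer(64L)
  stack[1L] <- n
  top <- 1L
  total <- 0
  while (top > 0L) {
    sz <- stack[top]
    top <- top - 1L
    if (sz == 1L) {
      total <- total + 1
    } else {
      m <- sample.int(sz - 1L, 1L)
      total <- total + sz
      if (top + 2L > length(stack)) stack <- c(stack, integer(length(stack)))
      stack[top + 1L] <- m
      stack[top + 2L] <- sz - m
      top <- top + 2L
    }
  }
  total
}
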