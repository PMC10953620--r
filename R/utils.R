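# Small internal helpers shared across modules.

# All permutations of 1..k as a list of integer vectors. Used for cluster
# matching and kappa alignment; k is the number of clusters, so factorial
# growth is acceptable for the sizes this package meets (k <= 7 enforced).
perms <- function(k) {
  stopifnot(k >= 1)
  if (k > 7) stop("permutation enumeration supported only for k <= 7")
  if (k == 1) return(list(1L))
  sub <- perms(k - 1L)
  out <- list()
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (p in sub) out[[length(out) + 1L]] <- c(first, rest[p])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ac <- function(...) stop(..., call. = FALSE)

# check a scalar probability
check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop_ac(sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(x)
}
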