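# Marker-ordering engines. All work on a symmetric cost matrix S (two-point
# recombination fractions, with zero-information pairs set to a large
# penalty) and minimize the open-path objective sum_{adjacent} S, i.e. the
# expected two-point map length of the order.

path_objective <- function(S, ord) {
  n <- length(ord)
  if (n < 2) return(0)
  sum(S[cbind(ord[-n], ord[-1])])
}

# orient so that the first locus name sorts before the last; makes an order
# and its reversal (same objective) produce one canonical output
canonicalize_order <- function(ord, names) {
  if (length(ord) > 1 && names[ord[1]] > names[ord[length(ord)]]) rev(ord) else ord
}

# exact minimum-length open path by dynamic programming over subsets
# (Held-Karp). Guaranteed optimal; feasible for n <= 15.
order_exact <- function(S) {
  n <- nrow(S)
  if (n > 15) abort_bad_arg("exact ordering supports at most 15 loci (got %d)", n)
  if (n <= 2) return(seq_len(n))
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, nrow = full, ncol = n)
  parent <- matrix(NA_integer_, nrow = full, ncol = n)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  for (j in seq_len(n)) dp[bits[j], j] <- 0
  members_cache <- vector("list", full)
  for (mask in seq_len(full)) {
    mem <- which(bitwAnd(mask, bits) != 0L)
    members_cache[[mask]] <- mem
    if (length(mem) < 2) next
    for (j in mem) {
      prev_mask <- mask - bits[j]
      prev_mem <- members_cache[[prev_mask]]
      cand <- dp[prev_mask, prev_mem] + S[prev_mem, j]
      b <- which.min(cand)
      dp[mask, j] <- cand[b]
      parent[mask, j] <- prev_mem[b]
    }
  }
  j <- which.min(dp[full, ])
  ord <- integer(n)
  mask <- full
  for (k in n:1) {
    ord[k] <- j
    pj <- parent[mask, j]
    mask <- mask - bits[j]
    j <- pj
  }
  ord
}

# delta of reversing ord[i..j] in place (symmetric S: only boundary edges
# change)
reversal_delta <- function(S, ord, i, j) {
  n <- length(ord)
  d <- 0
  if (i > 1) d <- d + S[ord[i - 1], ord[j]] - S[ord[i - 1], ord[i]]
  if (j < n) d <- d + S[ord[i], ord[j + 1]] - S[ord[j], ord[j + 1]]
  d
}

apply_reinsertion <- function(ord, i, k) {
  x <- ord[i]
  rest <- ord[-i]
  append(rest, x, after = k - 1L)
}

reinsertion_delta <- function(S, ord, i, k) {
  # move element at position i so that it ends up at position k of the new
  # order (k indexes the order after removal-and-insertion)
  n <- length(ord)
  b <- ord[i]
  d <- 0
  if (i > 1) d <- d - S[ord[i - 1], b]
  if (i < n) d <- d - S[b, ord[i + 1]]
  if (i > 1 && i < n) d <- d + S[ord[i - 1], ord[i + 1]]
  rest <- ord[-i]
  m <- length(rest)
  if (k > 1) d <- d + S[rest[k - 1], b]
  if (k <= m) d <- d + S[b, rest[k]]
  if (k > 1 && k <= m) d <- d - S[rest[k - 1], rest[k]]
  d
}

# simulated annealing: geometric cooling, reversal + reinsertion moves,
# all deltas O(1)
order_anneal <- function(S, init, t0 = 1, cooling = 0.95, moves_per_t = 300,
                         t_min = 1e-3) {
  n <- length(init)
  if (n <= 2) return(init)
  ord <- init
  best <- ord
  obj <- path_objective(S, ord)
  best_obj <- obj
  temp <- t0
  while (temp > t_min) {
    # draw the whole block of random numbers at once
    kind <- runif(moves_per_t) < 0.7
    ii <- sample.int(n, moves_per_t, replace = TRUE)
    jj <- sample.int(n, moves_per_t, replace = TRUE)
    uu <- runif(moves_per_t)
    for (m in seq_len(moves_per_t)) {
      if (kind[m]) {
        i <- min(ii[m], jj[m]); j <- max(ii[m], jj[m])
        if (i == j) next
        d <- reversal_delta(S, ord, i, j)
        if (d <= 0 || uu[m] < exp(-d / temp)) {
          ord[i:j] <- ord[j:i]
          obj <- obj + d
        }
      } else {
        i <- ii[m]
        k <- jj[m]
        if (i == k) next
        d <- reinsertion_delta(S, ord, i, k)
        if (d <= 0 || uu[m] < exp(-d / temp)) {
          ord <- apply_reinsertion(ord, i, k)
          obj <- obj + d
        }
      }
      if (obj < best_obj) {
        best_obj <- obj
        best <- ord
      }
    }
    temp <- temp * cooling
  }
  best
}

# taboo (tabu) search: steepest descent over all segment reversals with a
# recency-based tabu list on the endpoint locus pair; aspiration admits any
# move that improves the incumbent best
order_taboo <- function(S, init, tenure = 15, max_iter = NULL,
                        patience = 25) {
  n <- length(init)
  if (n <= 2) return(init)
  max_iter <- max_iter %||% (40L * n)
  ord <- init
  obj <- path_objective(S, ord)
  best <- ord
  best_obj <- obj
  last_used <- matrix(-Inf, n, n)
  stall <- 0L
  for (iter in seq_len(max_iter)) {
    best_d <- Inf
    bi <- bj <- NA_integer_
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- reversal_delta(S, ord, i, j)
        a <- ord[i]; b <- ord[j]
        tabu <- (iter - last_used[a, b]) < tenure
        if (tabu && obj + d >= best_obj) next
        if (d < best_d) {
          best_d <- d; bi <- i; bj <- j
        }
      }
    }
    if (is.na(bi)) break
    a <- ord[bi]; b <- ord[bj]
    last_used[a, b] <- last_used[b, a] <- iter
    ord[bi:bj] <- ord[bj:bi]
    obj <- obj + best_d
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- ord
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  best
}

# all permutations of 1..k (k <= 5), cached
permutations_of <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    perm <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      }
      out
    }
    res <- perm(seq_len(k))
    cache[[key]] <<- res
    res
  }
})

# greedy double-ended nearest-neighbour chain; a sound deterministic start
# for local polishing methods, which cannot relocate a badly misplaced
# locus across the group
greedy_chain <- function(S) {
  n <- nrow(S)
  if (n <= 2) return(seq_len(n))
  Su <- S
  Su[!upper.tri(Su)] <- Inf
  start <- which(Su == min(Su), arr.ind = TRUE)[1, ]
  ord <- as.integer(start)
  free <- setdiff(seq_len(n), ord)
  while (length(free) > 0) {
    head_cost <- S[ord[1], free]
    tail_cost <- S[ord[length(ord)], free]
    if (min(head_cost) < min(tail_cost)) {
      ord <- c(free[which.min(head_cost)], ord)
    } else {
      ord <- c(ord, free[which.min(tail_cost)])
    }
    free <- setdiff(seq_len(n), ord)
  }
  ord
}

# sliding-window exhaustive permutation ("flips"): every window of `width`
# consecutive loci is tried in all orders; sweeps repeat until none improves
order_flips <- function(S, init, width = 5) {
  n <- length(init)
  if (n <= 2) return(init)
  width <- min(width, n)
  perms <- permutations_of(width)
  ord <- init
  repeat {
    improved <- FALSE
    for (w in seq_len(n - width + 1)) {
      idx <- w:(w + width - 1)
      seg <- ord[idx]
      lo <- if (w > 1) ord[w - 1] else NA_integer_
      hi <- if (w + width - 1 < n) ord[w + width] else NA_integer_
      seg_cost <- function(s) {
        cost <- sum(S[cbind(s[-width], s[-1])])
        if (!is.na(lo)) cost <- cost + S[lo, s[1]]
        if (!is.na(hi)) cost <- cost + S[s[width], hi]
        cost
      }
      base <- seg_cost(seg)
      best_cost <- base
      best_seg <- seg
      for (p in perms) {
        s <- seg[p]
        cst <- seg_cost(s)
        if (cst < best_cost - 1e-12) {
          best_cost <- cst
          best_seg <- s
        }
      }
      if (best_cost < base - 1e-12) {
        ord[idx] <- best_seg
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

# connected components of the "informative pair" graph (adjacency where
# n_informative > 0); simple BFS, loci indexed 1..n
informative_components <- function(informative) {
  n <- nrow(informative)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(informative[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}
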