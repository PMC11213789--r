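# Ford-Johnson (merge-insertion) comparison sort driven by an external
# forced-choice oracle. This is the comparison-minimizing engine behind the
# pairwise-comparison rating protocol: items are paired off, winners are
# ranked recursively, and losers are binary-inserted into the main chain in
# Jacobsthal-number group order so every search window stays one short of a
# power of two.

#' Number of exhaustive pairwise comparisons
#'
#' The round-robin baseline the merge-insertion schedule improves on: ranking
#' `n` items by comparing every pair requires `n(n-1)/2` forced choices
#' (1225 for a 50-scan dataset).
#'
#' @param n Number of items (positive integer).
#' @return Integer, `n(n-1)/2`.
#' @export
#' @examples
#' pair_count(50)
pair_count <- function(n) {
  n <- check_count(n, "n")
  as.integer(n * (n - 1) / 2)
}

#' Worst-case comparison count of merge-insertion sort
#'
#' Closed form for the maximum number of forced choices the Ford-Johnson
#' schedule needs to rank `n` items with a consistent oracle:
#' `sum_{k=1..n} ceiling(log2(3k/4))`. Evaluated in integer arithmetic
#' (smallest `t` with `2^(t+2) >= 3k`), so no floating-point log is involved.
#' For `n = 50` the value is 219.
#'
#' @param n Number of items (positive integer).
#' @return Integer comparison bound.
#' @export
#' @examples
#' fj_worst_case(50)
fj_worst_case <- function(n) {
  n <- check_count(n, "n")
  total <- 0L
  for (k in seq_len(n)) {
    t <- 0L
    while (2^(t + 2L) < 3 * k) t <- t + 1L
    total <- total + t
  }
  total
}

# Jacobsthal insertion-group endpoints 3, 5, 11, 21, 43, ... for k >= 2.
jacobsthal_end <- function(k) {
  as.integer((2^(k + 1) + (-1)^k) / 3)
}

new_ranking <- function(ids_ascending) {
  structure(
    list(
      item_ids = as.character(ids_ascending),
      rank_of = stats::setNames(seq_along(ids_ascending), as.character(ids_ascending))
    ),
    class = "iq_ranking"
  )
}

#' @export
print.iq_ranking <- function(x, ...) {
  n <- length(x$item_ids)
  cat(sprintf("<iq_ranking> %d items (rank 1 = lowest IQ)\n", n))
  show <- min(n, 8L)
  cat("  ", paste(sprintf("%s=%d", x$item_ids[seq_len(show)], seq_len(show)),
                  collapse = " "),
      if (n > show) "..." else "", "\n")
  invisible(x)
}

# Core engine shared by the batch ranker and the interactive session replay.
# `answer(k, left_id, right_id)` must return one of the two offered ids; the
# replay driver signals an `iqrank_need_input` condition instead when the
# session log is exhausted.
fj_run <- function(item_ids, seed, answer) {
  item_ids <- as.character(item_ids)
  n <- length(item_ids)
  if (n < 1L) validation_error("at least one item is required")
  if (anyDuplicated(item_ids)) {
    validation_error("item identifiers must be distinct")
  }

  cap <- pair_count(max(n, 2L))
  st <- new.env(parent = emptyenv())
  st$k <- 0L
  st$left <- character(cap)
  st$right <- character(cap)
  st$chosen <- character(cap)
  st$seen <- matrix(FALSE, n, n)

  # less(i, j): TRUE iff item i is ranked below item j by the oracle.
  # Presentation side is a seeded coin flip per comparison so replays are
  # exact; the unordered pair is recorded and may never repeat.
  less <- function(i, j) {
    if (st$seen[i, j]) {
      state_error(sprintf(
        "internal error: pair {%s, %s} queried twice", item_ids[i], item_ids[j]
      ))
    }
    k <- st$k + 1L
    flip <- mix_bits(seed, k) %% 2 == 1
    l <- if (flip) j else i
    r <- if (flip) i else j
    ch <- answer(k, item_ids[l], item_ids[r])
    if (length(ch) != 1L || !(ch %in% c(item_ids[l], item_ids[r]))) {
      protocol_error(
        sprintf(
          "record %d: oracle chose %s, which is not in the offered pair {%s, %s}",
          k, deparse(ch), item_ids[l], item_ids[r]
        ),
        index = k
      )
    }
    st$k <- k
    st$left[k] <- item_ids[l]
    st$right[k] <- item_ids[r]
    st$chosen[k] <- ch
    st$seen[i, j] <- TRUE
    st$seen[j, i] <- TRUE
    ch == item_ids[j]
  }

  chain <- fj_sort(seq_len(n), less)

  idx <- seq_len(st$k)
  list(
    ranking = new_ranking(item_ids[chain]),
    records = data.frame(
      index = idx,
      left = st$left[idx],
      right = st$right[idx],
      chosen = st$chosen[idx],
      stringsAsFactors = FALSE
    )
  )
}

# Recursive merge-insertion on integer indices. `less` performs one oracle
# comparison. Returns indices in ascending order (lowest quality first).
fj_sort <- function(items, less) {
  n <- length(items)
  if (n == 1L) return(items)
  if (n == 2L) {
    return(if (less(items[1L], items[2L])) items else items[2:1])
  }

  half <- n %/% 2L
  winners <- integer(half)
  losers <- integer(half)
  for (i in seq_len(half)) {
    a <- items[2L * i - 1L]
    b <- items[2L * i]
    if (less(a, b)) {
      winners[i] <- b
      losers[i] <- a
    } else {
      winners[i] <- a
      losers[i] <- b
    }
  }

  sorted_w <- fj_sort(winners, less)
  loser_of <- losers[match(sorted_w, winners)]

  # The loser paired with the smallest winner precedes the whole chain; it is
  # placed without a comparison.
  chain <- c(loser_of[1L], sorted_w)

  # Remaining pending elements are indexed 2..m by the position of their
  # winner in the sorted chain; for odd n the unpaired straggler takes index
  # half+1 and its search window is the entire chain. Groups are delimited by
  # Jacobsthal numbers and processed in descending index order, which keeps
  # each binary-search window at most 2^k - 1 elements wide.
  m <- half + (n %% 2L)
  if (m >= 2L) {
    prev <- 1L
    g <- 2L
    while (prev < m) {
      hi <- min(jacobsthal_end(g), m)
      for (j in seq.int(hi, prev + 1L)) {
        if (j > half) {
          u <- items[n]
          limit <- length(chain)
        } else {
          u <- loser_of[j]
          limit <- match(sorted_w[j], chain) - 1L
        }
        chain <- binary_insert(chain, u, limit, less)
      }
      prev <- hi
      g <- g + 1L
    }
  }
  chain
}

# Binary insertion of u into chain[1..limit]; positions after `limit` are
# known to exceed u (they include u's own pair winner), so they are never
# queried and no pair repeats.
binary_insert <- function(chain, u, limit, less) {
  lo <- 1L
  hi <- limit
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (less(u, chain[mid])) hi <- mid - 1L else lo <- mid + 1L
  }
  append(chain, u, after = lo - 1L)
}

#' Rank items by forced-choice pairwise comparisons
#'
#' Runs the Ford-Johnson merge-insertion schedule against a comparison
#' oracle until a complete ranking (rank 1 = lowest image quality, rank n =
#' highest) is determined. With a consistent (transitive, strict) oracle the
#' result is the oracle's true total order and the number of comparisons
#' never exceeds [fj_worst_case()]; no unordered pair is ever offered twice.
#' Intransitive answers (human or noisy observers) are accepted as given —
#' because no redundant pair is asked, intransitivity is undetectable within
#' a session and the ranking is whatever the insertion sequence produces.
#'
#' @param item_ids Character vector of distinct item identifiers.
#' @param oracle Function `(left_id, right_id) -> chosen_id`; must return one
#'   of the two offered identifiers (the one with the higher perceived
#'   quality). No abstain or tie option exists.
#' @param seed Integer seed controlling which item of each pair is presented
#'   on the left (presentation-order bias control). The same `item_ids`,
#'   `seed` and answers reproduce the identical pair sequence.
#' @return A list with components `ranking` (an `iq_ranking`: `item_ids` in
#'   ascending quality order and a `rank_of` map) and `records` (data frame
#'   of the full comparison log: `index`, `left`, `right`, `chosen`).
#' @export
#' @examples
#' truth <- c(b = 1, c = 2, a = 3) # latent quality
#' oracle <- function(l, r) if (truth[l] > truth[r]) l else r
#' fj_rank(c("a", "b", "c"), oracle, seed = 7)$ranking$item_ids
fj_rank <- function(item_ids, oracle, seed = 1L) {
  if (!is.function(oracle)) validation_error("`oracle` must be a function")
  fj_run(item_ids, as.integer(seed), function(k, l, r) oracle(l, r))
}

#' Adversarial comparison oracle
#'
#' A lazy adversary for measuring the comparison budget of the ranking
#' engine. It commits to as little as possible: answers already forced by the
#' transitive closure of its previous answers are returned consistently;
#' free choices are resolved so that the item with fewer committed relations
#' (the one currently being inserted) is pushed toward the side with more
#' remaining candidate positions, driving every binary search to its deepest
#' leaf. All answers remain mutually consistent, so the final ranking is a
#' valid total order.
#'
#' @param item_ids Character vector of distinct item identifiers.
#' @return An oracle function suitable for [fj_rank()].
#' @export
#' @examples
#' ids <- sprintf("s%02d", 1:10)
#' nrow(fj_rank(ids, adversarial_oracle(ids), seed = 1)$records) <= fj_worst_case(10)
adversarial_oracle <- function(item_ids) {
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids)) validation_error("item identifiers must be distinct")
  n <- length(item_ids)
  env <- new.env(parent = emptyenv())
  env$lt <- matrix(FALSE, n, n) # lt[i, j]: i below j, committed

  function(left, right) {
    i <- match(left, item_ids)
    j <- match(right, item_ids)
    if (is.na(i) || is.na(j)) {
      validation_error("oracle offered an unknown item identifier")
    }
    lt <- env$lt
    if (lt[i, j]) return(right)
    if (lt[j, i]) return(left)

    # Free choice. Identify the sparser item (binary-search subject).
    deg_i <- sum(lt[i, ]) + sum(lt[, i])
    deg_j <- sum(lt[j, ]) + sum(lt[, j])
    if (deg_i <= deg_j) {
      u <- i
      v <- j
    } else {
      u <- j
      v <- i
    }
    free_u <- !(lt[, u] | lt[u, ])
    below <- sum(lt[, v] & free_u)
    above <- sum(lt[v, ] & free_u)
    u_below_v <- below >= above

    a <- if (u_below_v) u else v
    b <- if (u_below_v) v else u
    # commit a < b plus transitive closure
    anc <- c(a, which(lt[, a]))
    dec <- c(b, which(lt[b, ]))
    env$lt[anc, dec] <- TRUE
    if (env$lt[a, b] && env$lt[b, a]) {
      state_error("adversary committed an inconsistent relation")
    }
    if (b == j) right else left
  }
}
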