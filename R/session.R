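# Interactive, resumable comparison sessions. The comparison log is the
# source of truth: algorithm state is reconstructed by replaying the log
# against a fresh merge-insertion run, so serialized sessions survive
# internal refactors and replays are exact (same items + seed + answers =>
# same pair sequence).

#' Start a pairwise-comparison session
#'
#' Creates a pending session over `item_ids`. Pairs are obtained one at a
#' time with [next_pair()] and answered with [submit_choice()]; driving the
#' loop to completion is observationally equivalent to [fj_rank()] with the
#' same oracle and seed.
#'
#' @param item_ids Character vector of distinct item identifiers.
#' @param seed Integer seed controlling presentation-side randomization.
#' @return A `comparison_session` object with fields `item_ids`, `seed`,
#'   `records` (the comparison log) and `status` (`"pending"` or
#'   `"complete"`).
#' @export
#' @examples
#' s <- comparison_session(c("a", "b"), seed = 1)
#' p <- next_pair(s)
#' s <- submit_choice(s, p[1])
#' session_ranking(s)$rank_of
comparison_session <- function(item_ids, seed = 1L) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) < 1L) validation_error("at least one item is required")
  if (anyDuplicated(item_ids)) validation_error("item identifiers must be distinct")
  s <- structure(
    list(
      item_ids = item_ids,
      seed = as.integer(seed),
      records = empty_records(),
      status = "pending"
    ),
    class = "comparison_session"
  )
  refresh_session(s)
}

empty_records <- function() {
  data.frame(
    index = integer(), left = character(), right = character(),
    chosen = character(), stringsAsFactors = FALSE
  )
}

# Replay the log. Returns either
#   list(status = "complete", ranking =, records =) or
#   list(status = "pending", left =, right =, index =).
replay_session <- function(session) {
  records <- session$records
  n_rec <- nrow(records)
  answer <- function(k, left, right) {
    if (k <= n_rec) {
      if (records$left[k] != left || records$right[k] != right) {
        state_error(sprintf(
          "corrupt session: record %d logs pair (%s, %s) but replay expects (%s, %s)",
          k, records$left[k], records$right[k], left, right
        ))
      }
      return(records$chosen[k])
    }
    stop(structure(
      class = c("iqrank_need_input", "condition"),
      list(message = "comparison needed", call = NULL,
           left = left, right = right, index = k)
    ))
  }
  tryCatch(
    {
      res <- fj_run(session$item_ids, session$seed, answer)
      if (nrow(res$records) < n_rec) {
        state_error("corrupt session: log is longer than the algorithm needs")
      }
      list(status = "complete", ranking = res$ranking, records = res$records)
    },
    iqrank_need_input = function(cond) {
      list(status = "pending", left = cond$left, right = cond$right,
           index = cond$index)
    }
  )
}

refresh_session <- function(session) {
  rep <- replay_session(session)
  session$status <- rep$status
  if (rep$status == "complete") session$ranking <- rep$ranking
  session
}

#' Next pair of a pending session
#'
#' Returns the next unordered pair the merge-insertion schedule needs, with
#' the left/right side assignment drawn from the session seed. Pure with
#' respect to session state: calling it twice without [submit_choice()]
#' yields the same pair, and a session resumed from a serialized copy yields
#' the identical pair.
#'
#' @param session A pending `comparison_session`.
#' @return Character vector `c(left_id, right_id)`.
#' @export
next_pair <- function(session) {
  stopifnot(inherits(session, "comparison_session"))
  if (session$status == "complete") {
    state_error("session is complete; no further pairs are needed")
  }
  rep <- replay_session(session)
  if (rep$status == "complete") {
    state_error("session is complete; no further pairs are needed")
  }
  c(rep$left, rep$right)
}

#' Record the observer's choice for the outstanding pair
#'
#' Appends a comparison record for the pair last issued by [next_pair()] and
#' advances the algorithm; the session becomes `complete` once the ranking
#' is fully determined.
#'
#' @param session A pending `comparison_session`.
#' @param chosen_id The preferred (higher-quality) item; must be one of the
#'   two identifiers of the outstanding pair.
#' @return The updated `comparison_session`.
#' @export
submit_choice <- function(session, chosen_id) {
  stopifnot(inherits(session, "comparison_session"))
  if (session$status == "complete") {
    state_error("session is complete; there is no outstanding pair")
  }
  rep <- replay_session(session)
  if (rep$status == "complete") {
    state_error("session is complete; there is no outstanding pair")
  }
  chosen_id <- as.character(chosen_id)
  if (length(chosen_id) != 1L || !(chosen_id %in% c(rep$left, rep$right))) {
    protocol_error(
      sprintf(
        "record %d: choice %s is not in the offered pair {%s, %s}",
        rep$index, deparse(chosen_id), rep$left, rep$right
      ),
      index = rep$index
    )
  }
  session$records <- rbind(
    session$records,
    data.frame(
      index = rep$index, left = rep$left, right = rep$right,
      chosen = chosen_id, stringsAsFactors = FALSE
    )
  )
  refresh_session(session)
}

#' Extract the ranking from a completed session
#'
#' @param session A complete `comparison_session`.
#' @return An `iq_ranking` (see [fj_rank()]).
#' @export
session_ranking <- function(session) {
  stopifnot(inherits(session, "comparison_session"))
  if (session$status != "complete") {
    state_error("session is still pending; the ranking is not determined yet")
  }
  session$ranking
}

#' @export
print.comparison_session <- function(x, ...) {
  cat(sprintf(
    "<comparison_session> %d items, %d comparisons logged, status: %s\n",
    length(x$item_ids), nrow(x$records), x$status
  ))
  invisible(x)
}

#' Write a session to JSON
#'
#' The file stores `items`, `seed`, the full comparison log and the status;
#' algorithm state is reconstructed from the log on read.
#'
#' @param session A `comparison_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "comparison_session"))
  obj <- list(
    items = session$item_ids,
    seed = session$seed,
    records = session$records,
    status = session$status
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from JSON
#'
#' @param path File written by [write_session()].
#' @return A `comparison_session` with status recomputed from the log.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- structure(
    list(
      item_ids = as.character(obj$items),
      seed = as.integer(obj$seed),
      records = if (length(obj$records)) {
        data.frame(
          index = as.integer(obj$records$index),
          left = as.character(obj$records$left),
          right = as.character(obj$records$right),
          chosen = as.character(obj$records$chosen),
          stringsAsFactors = FALSE
        )
      } else {
        empty_records()
      },
      status = "pending"
    ),
    class = "comparison_session"
  )
  refresh_session(s)
}

#' Export a ranking as CSV
#'
#' Writes a two-column table `item_id,rank` with rank 1 the lowest image
#' quality and rank n the highest.
#'
#' @param ranking An `iq_ranking`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "iq_ranking"))
  utils::write.csv(
    data.frame(item_id = ranking$item_ids,
               rank = seq_along(ranking$item_ids)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
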