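# End-to-end study orchestration: two datasets (high/low quality variation)
# x two rating methods (pairwise-comparison ranking, 5-point Likert) x k
# observers, with the 25 original scans shared between datasets providing
# the repeated measurements for intraobserver agreement.

#' Study configuration
#'
#' Bundles everything [run_study()] needs. Defaults mirror the reference
#' design: 30 patients of which 5 are excluded (emulating artifact
#' exclusions), 6 observers, two 50-scan datasets each holding the 25
#' originals plus 25 profile-drawn variants. All randomness descends from
#' `master_seed` through a documented splitting scheme (child seeds are
#' successive draws from a generator seeded with `master_seed`).
#'
#' @param n_patients Patients in the source pool (default 30).
#' @param n_excluded Patients dropped before composition (default 5).
#' @param observers List of [observer_model()]s (>= 2; default
#'   [default_observers()]).
#' @param quality_model A [latent_quality_model()]; its seed is replaced by
#'   a child of `master_seed` so replicate studies differ end to end.
#' @param profiles List with `high` and `low` cell-count tables (see
#'   [variation_profile()]).
#' @param dataset_order Order in which the two datasets are rated
#'   (default high then low; the reference design fixes the order).
#' @param master_seed Integer master seed.
#' @return A `study_config`.
#' @export
study_config <- function(n_patients = 30L,
                         n_excluded = 5L,
                         observers = default_observers(6L),
                         quality_model = latent_quality_model(),
                         profiles = list(high = variation_profile("high"),
                                         low = variation_profile("low")),
                         dataset_order = c("high", "low"),
                         master_seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  n_excluded <- check_count(n_excluded, "n_excluded", min = 0L)
  if (n_patients - n_excluded < 2L) {
    validation_error("`n_patients - n_excluded` must be at least 2")
  }
  if (length(observers) < 2L ||
      !all(vapply(observers, inherits, logical(1), "observer_model"))) {
    validation_error("`observers` must be a list of >= 2 observer_model objects")
  }
  if (is.null(names(observers)) || anyDuplicated(names(observers))) {
    names(observers) <- sprintf("obs%d", seq_along(observers))
  }
  if (!setequal(dataset_order, c("high", "low"))) {
    validation_error("`dataset_order` must be a permutation of c('high', 'low')")
  }
  structure(
    list(
      n_patients = n_patients,
      n_excluded = n_excluded,
      observers = observers,
      quality_model = quality_model,
      profiles = profiles,
      dataset_order = dataset_order,
      master_seed = as.integer(master_seed)
    ),
    class = "study_config"
  )
}

# Study-level ICCs degrade gracefully: a degenerate (constant) ratings
# matrix — possible for Likert scores under extreme observer noise or
# thresholds — yields an NA-filled icc_result instead of aborting the study.
safe_icc <- function(m, measures) {
  tryCatch(
    icc_agreement(m, measures),
    iqrank_validation_error = function(e) {
      structure(
        list(
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          measures = measures,
          model = "two-way random, absolute agreement",
          ms_rows = NA_real_, ms_cols = NA_real_, ms_error = NA_real_,
          df_rows = nrow(m) - 1L, df_cols = ncol(m) - 1L,
          df_error = (nrow(m) - 1L) * (ncol(m) - 1L),
          alpha = 0.05, n = nrow(m), k = ncol(m),
          clamped = list(estimate = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_)
        ),
        class = "icc_result"
      )
    }
  )
}

#' Run a complete simulated observer study
#'
#' Generates the scan pool, drops the excluded patients, composes the high-
#' and low-variation datasets (both containing every remaining patient's
#' original scan), and has every observer rate each dataset with both
#' methods: one pairwise-comparison session producing ranks 1..50 and one
#' Likert pass over the same 50 scans in independently randomized order.
#' Interobserver agreement is the average-measures absolute-agreement ICC of
#' the 50 x k ratings matrix per dataset and method; intraobserver agreement
#' is the single-measures ICC of each observer's 25 x 2 matrix over the
#' originals (raw full-session ranks for the PC method, scores for Likert).
#'
#' @param config A [study_config()].
#' @return An `iq_study` list: `datasets`, `sessions` (PC logs and Likert
#'   scores per observer/dataset), `matrices` (`inter` and `intra` ratings
#'   matrices), `inter_icc`/`intra_icc` (lists of `icc_result`),
#'   `icc_table` (tidy data frame of all agreement estimates), `originals`,
#'   and the `config`. A degenerate (constant) ratings matrix — possible for
#'   Likert scores under extreme noise or threshold settings — yields an
#'   NA-filled `icc_result` rather than aborting the study.
#' @export
#' @examples
#' \donttest{
#' res <- run_study(study_config(master_seed = 7))
#' res$icc_table
#' }
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  k <- length(config$observers)
  seeds <- child_seeds(config$master_seed, 4L + 4L * k)

  qm <- config$quality_model
  qm$seed <- seeds[1]
  pool <- generate_scan_pool(config$n_patients, qm)

  patients <- unique(pool$patient_id)
  keep <- sort(with_seed(
    seeds[2],
    sample(patients, config$n_patients - config$n_excluded)
  ))
  pool <- pool[pool$patient_id %in% keep, ]

  n_inc <- length(keep)
  datasets <- list(
    high = compose_dataset(pool, "high", n_inc, seeds[3],
                           table = config$profiles$high),
    low = compose_dataset(pool, "low", n_inc, seeds[4],
                          table = config$profiles$low)
  )
  originals <- sort(pool$scan_id[pool$is_original])

  pc_sessions <- list()
  likert_scores <- list()
  obs_names <- names(config$observers)
  for (oi in seq_len(k)) {
    obs <- config$observers[[oi]]
    for (di in seq_along(config$dataset_order)) {
      dname <- config$dataset_order[di]
      ds <- datasets[[dname]]
      pc_seed <- seeds[4L + (oi - 1L) * 4L + di]
      lik_seed <- seeds[4L + (oi - 1L) * 4L + 2L + di]

      res <- fj_rank(ds$scan_id, observer_oracle(obs, ds, pc_seed),
                     seed = pc_seed)
      pc_sessions[[dname]][[obs_names[oi]]] <- res

      stream <- rng_stream(lik_seed)
      order_idx <- stream_eval(stream, sample(nrow(ds)))
      shuffled <- ds[order_idx, ]
      scores <- vapply(seq_len(nrow(shuffled)), function(i) {
        simulate_likert(obs, shuffled[i, ], stream)
      }, integer(1))
      likert_scores[[dname]][[obs_names[oi]]] <-
        stats::setNames(scores, shuffled$scan_id)
    }
  }

  inter <- list()
  inter_icc <- list()
  for (dname in c("high", "low")) {
    ranks <- lapply(pc_sessions[[dname]], function(s) s$ranking$rank_of)
    inter[[dname]] <- list(
      pc = interobserver_matrix(ranks),
      likert = interobserver_matrix(likert_scores[[dname]])
    )
    inter_icc[[dname]] <- list(
      pc = safe_icc(inter[[dname]]$pc, "average"),
      likert = safe_icc(inter[[dname]]$likert, "average")
    )
  }

  intra <- list()
  intra_icc <- list()
  for (oname in obs_names) {
    intra[[oname]] <- list(
      pc = intraobserver_matrix(
        pc_sessions$high[[oname]]$ranking$rank_of,
        pc_sessions$low[[oname]]$ranking$rank_of,
        originals
      ),
      likert = intraobserver_matrix(
        likert_scores$high[[oname]],
        likert_scores$low[[oname]],
        originals
      )
    )
    intra_icc[[oname]] <- list(
      pc = safe_icc(intra[[oname]]$pc, "single"),
      likert = safe_icc(intra[[oname]]$likert, "single")
    )
  }

  icc_row <- function(scope, dataset, observer, method, r) {
    data.frame(
      scope = scope, dataset = dataset, observer = observer, method = method,
      measures = r$measures, estimate = r$estimate,
      ci_low = r$ci_low, ci_high = r$ci_high, stringsAsFactors = FALSE
    )
  }
  tab <- rbind(
    do.call(rbind, lapply(c("high", "low"), function(d) {
      rbind(
        icc_row("inter", d, NA_character_, "pc", inter_icc[[d]]$pc),
        icc_row("inter", d, NA_character_, "likert", inter_icc[[d]]$likert)
      )
    })),
    do.call(rbind, lapply(obs_names, function(o) {
      rbind(
        icc_row("intra", NA_character_, o, "pc", intra_icc[[o]]$pc),
        icc_row("intra", NA_character_, o, "likert", intra_icc[[o]]$likert)
      )
    }))
  )

  structure(
    list(
      datasets = datasets,
      originals = originals,
      sessions = list(pc = pc_sessions, likert = likert_scores),
      matrices = list(inter = inter, intra = intra),
      inter_icc = inter_icc,
      intra_icc = intra_icc,
      icc_table = tab,
      config = config
    ),
    class = "iq_study"
  )
}

#' @export
print.iq_study <- function(x, ...) {
  cat(sprintf(
    "<iq_study> %d observers, datasets of %d scans (%d shared originals)\n",
    length(x$config$observers), nrow(x$datasets$high), length(x$originals)
  ))
  print(x$icc_table[x$icc_table$scope == "inter", ], row.names = FALSE)
  invisible(x)
}

#' Assemble an interobserver ratings matrix
#'
#' Aligns per-observer score vectors (PC ranks 1..n or Likert scores) for
#' one dataset and method into a subjects-by-observers matrix, subject order
#' fixed by sorted `scan_id`.
#'
#' @param scores Named list (one element per observer) of numeric vectors
#'   named by `scan_id`. All observers must have scored the identical scan
#'   set.
#' @return An n x k ratings matrix.
#' @export
interobserver_matrix <- function(scores) {
  if (length(scores) < 2L) {
    validation_error("at least two observers are required")
  }
  ids <- sort(names(scores[[1]]))
  for (o in seq_along(scores)) {
    other <- names(scores[[o]])
    if (!setequal(other, ids)) {
      diff <- union(setdiff(ids, other), setdiff(other, ids))
      alignment_error(sprintf(
        "observers scored different scan sets; symmetric difference: %s",
        paste(sort(diff), collapse = ", ")
      ))
    }
  }
  m <- vapply(scores, function(s) unname(s[ids]), numeric(length(ids)))
  ratings_matrix(
    m, subject_ids = ids,
    rater_ids = if (is.null(names(scores))) sprintf("obs%d", seq_along(scores)) else names(scores)
  )
}

#' Assemble an intraobserver ratings matrix
#'
#' One observer's scores for the original scans in two sessions, as a
#' 25 x 2 (subjects x sessions) matrix. PC entries are the raw full-session
#' ranks (1..50), not re-normalized among the originals.
#'
#' @param scores1,scores2 Numeric vectors named by `scan_id` from session 1
#'   and session 2.
#' @param originals Scan ids present in both sessions.
#' @return An n x 2 ratings matrix with columns `session1`, `session2`.
#' @export
intraobserver_matrix <- function(scores1, scores2, originals) {
  originals <- sort(as.character(originals))
  miss1 <- setdiff(originals, names(scores1))
  miss2 <- setdiff(originals, names(scores2))
  if (length(miss1) || length(miss2)) {
    alignment_error(sprintf(
      "originals absent from a session: %s",
      paste(sort(unique(c(miss1, miss2))), collapse = ", ")
    ))
  }
  ratings_matrix(
    cbind(unname(scores1[originals]), unname(scores2[originals])),
    subject_ids = originals,
    rater_ids = c("session1", "session2")
  )
}

#' Read a study configuration from JSON
#'
#' Top-level fields mirror [study_config()]; `observers` is an array of
#' [observer_model()] field sets and `quality_model` a
#' [latent_quality_model()] field set. Absent fields take the defaults.
#'
#' @param path JSON file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("n_patients", "n_excluded", "master_seed", "dataset_order")) {
    if (!is.null(obj[[f]])) args[[f]] <- obj[[f]]
  }
  if (!is.null(obj$quality_model)) {
    qa <- obj$quality_model
    if (!is.null(qa$beta_recon)) qa$beta_recon <- unlist(qa$beta_recon)
    args$quality_model <- do.call(latent_quality_model, qa)
  }
  if (!is.null(obj$observers)) {
    olist <- obj$observers
    if (is.data.frame(olist)) {
      olist <- lapply(seq_len(nrow(olist)), function(i) as.list(olist[i, ]))
      olist <- lapply(olist, function(o) {
        o$thresholds <- unlist(o$thresholds)
        o
      })
    }
    args$observers <- lapply(olist, function(o) {
      do.call(observer_model, o[intersect(names(o), names(formals(observer_model)))])
    })
  }
  do.call(study_config, args)
}
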