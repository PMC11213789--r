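# Synthetic scan pools and stochastic observers. No pixels are involved:
# each scan carries a latent scalar quality driven by tube-current fraction
# and reconstruction method plus a patient random effect, and observers
# perceive it through a Thurstonian lens (gain, bias, fresh Gaussian noise
# per look) with ordinal thresholds for Likert scoring.

RECON_LEVELS <- c("FBP", "IR2", "IR3", "IR4")
CURRENT_LEVELS <- c(60L, 70L, 80L, 90L, 100L)
SIM_CURRENTS <- c(60L, 70L, 80L, 90L)

#' Latent scan-quality model
#'
#' Defines the scalar image quality attached to each synthetic scan:
#' `latent_q = beta_current * log(current_pct/100) + beta_recon[recon] +
#' u_patient`, with `u_patient ~ N(0, sigma_patient^2)`. Linear-in-log-dose
#' with additive reconstruction offsets is the simplest monotone stand-in
#' for the dose/noise/smoothing trade-off; all coefficients are exposed.
#'
#' Defaults: `beta_current = 2` (so dropping from 100% to 60% tube current
#' costs about 1 IQ unit), reconstruction offsets `FBP = -1.5, IR2 = 0,
#' IR3 = 0.6, IR4 = 1` (filtered backprojection markedly noisier, stronger
#' iterative smoothing a modest gain), and `sigma_patient = 0.5`.
#'
#' @param beta_current IQ units per unit `log(current fraction)`; must be
#'   >= 0 (more dose never lowers latent quality).
#' @param beta_recon Named numeric vector of offsets for `FBP, IR2, IR3, IR4`.
#' @param sigma_patient SD of the patient random effect (>= 0).
#' @param seed Integer seed for the patient effects.
#' @return A `latent_quality_model`.
#' @export
latent_quality_model <- function(beta_current = 2,
                                 beta_recon = c(FBP = -1.5, IR2 = 0,
                                                IR3 = 0.6, IR4 = 1),
                                 sigma_patient = 0.5,
                                 seed = 101L) {
  if (!is.numeric(beta_current) || length(beta_current) != 1L || beta_current < 0) {
    validation_error("`beta_current` must be a single non-negative number")
  }
  if (!setequal(names(beta_recon), RECON_LEVELS)) {
    validation_error("`beta_recon` must be named FBP, IR2, IR3, IR4")
  }
  if (!is.numeric(sigma_patient) || length(sigma_patient) != 1L || sigma_patient < 0) {
    validation_error("`sigma_patient` must be a single non-negative number")
  }
  structure(
    list(
      beta_current = as.numeric(beta_current),
      beta_recon = vapply(beta_recon[RECON_LEVELS], as.numeric, numeric(1)),
      sigma_patient = as.numeric(sigma_patient),
      seed = as.integer(seed)
    ),
    class = "latent_quality_model"
  )
}

#' Generate a synthetic scan pool
#'
#' Emits 17 scans per patient: the original acquisition (100% tube current,
#' IR2) plus the 16 simulated variants — every combination of
#' `{60, 70, 80, 90}%` tube current with `{FBP, IR2, IR3, IR4}`
#' reconstruction. 30 patients therefore yield 510 scans. Latent qualities
#' follow `model`; the draw is deterministic given `model$seed`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param model A [latent_quality_model()].
#' @return Data frame with columns `scan_id`, `patient_id`, `current_pct`,
#'   `recon`, `is_original`, `latent_q`.
#' @export
#' @examples
#' nrow(generate_scan_pool(30, latent_quality_model()))
generate_scan_pool <- function(n_patients, model = latent_quality_model()) {
  n_patients <- check_count(n_patients, "n_patients")
  stopifnot(inherits(model, "latent_quality_model"))

  u <- with_seed(model$seed, stats::rnorm(n_patients, 0, model$sigma_patient))
  patient_ids <- sprintf("P%03d", seq_len(n_patients))

  variants <- expand.grid(
    current_pct = SIM_CURRENTS, recon = RECON_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  per_patient <- rbind(
    data.frame(current_pct = 100L, recon = "IR2", stringsAsFactors = FALSE),
    variants
  )

  out <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    d <- per_patient
    d$patient_id <- patient_ids[i]
    d$is_original <- d$current_pct == 100L & d$recon == "IR2"
    d$latent_q <- model$beta_current * log(d$current_pct / 100) +
      model$beta_recon[d$recon] + u[i]
    d$scan_id <- sprintf("%s_%s_%03d", d$patient_id, d$recon, d$current_pct)
    d
  }))
  rownames(out) <- NULL
  out[, c("scan_id", "patient_id", "current_pct", "recon", "is_original", "latent_q")]
}

#' Default dataset-composition profiles
#'
#' Cell-count tables over (reconstruction x tube-current) for the 25
#' non-original scans of a composed dataset. The high-variation profile
#' spreads scans over all four reconstructions and 60-90% current; the
#' low-variation profile concentrates on IR2/IR4 at 80-90%, i.e. close to
#' the original acquisition settings, so quality differences are subtle.
#' Both tables are overridable in [compose_dataset()] and [study_config()].
#'
#' @param profile `"high"` or `"low"`.
#' @return Integer matrix, rows `FBP, IR2, IR3, IR4`, columns `60, 70, 80,
#'   90` (% tube current), summing to 25.
#' @export
variation_profile <- function(profile = c("high", "low")) {
  profile <- match.arg(profile)
  tab <- matrix(
    0L, nrow = 4, ncol = 4,
    dimnames = list(recon = RECON_LEVELS, current_pct = as.character(SIM_CURRENTS))
  )
  if (profile == "high") {
    tab["FBP", ] <- c(2L, 1L, 2L, 2L)
    tab["IR2", ] <- c(2L, 2L, 1L, 2L)
    tab["IR3", ] <- c(2L, 2L, 2L, 1L)
    tab["IR4", ] <- c(1L, 1L, 1L, 1L)
  } else {
    tab["IR2", c("80", "90")] <- c(5L, 8L)
    tab["IR4", c("80", "90")] <- c(4L, 8L)
  }
  tab
}

#' Compose a 2-per-patient study dataset
#'
#' Builds a dataset of `2 * n_patients_included` scans: every included
#' patient's original scan plus exactly one non-original scan per patient,
#' drawn so the non-original cell counts over (reconstruction x current)
#' follow the requested variation profile. Patients are taken in pool order;
#' the cell-to-patient assignment is a seeded random permutation, mirroring
#' the random complementation of the study design.
#'
#' If `n_patients_included` differs from the profile-table total, cells are
#' drawn with probability proportional to the table counts instead.
#'
#' @param pool Scan pool from [generate_scan_pool()].
#' @param profile `"high"` or `"low"` (ignored if `table` is given).
#' @param n_patients_included Number of patients to include (default 25).
#' @param seed Integer seed for the assignment draw.
#' @param table Optional replacement cell-count matrix shaped like
#'   [variation_profile()].
#' @return Data frame of `2 * n_patients_included` rows, same columns as the
#'   pool, ordered originals first.
#' @export
compose_dataset <- function(pool, profile = c("high", "low"),
                            n_patients_included = 25L, seed = 1L,
                            table = NULL) {
  n_patients_included <- check_count(n_patients_included, "n_patients_included")
  need <- c("scan_id", "patient_id", "current_pct", "recon", "is_original", "latent_q")
  if (!all(need %in% names(pool))) {
    validation_error("`pool` must have the scan-pool columns")
  }
  counts <- table(pool$patient_id)
  full <- names(counts)[counts == 17L]
  full <- full[vapply(full, function(p) {
    sum(pool$is_original[pool$patient_id == p]) == 1L
  }, logical(1))]
  full <- full[order(match(full, pool$patient_id))]
  if (length(full) < n_patients_included) {
    composition_error(sprintf(
      "pool has only %d patients with complete 17-scan sets; %d required",
      length(full), n_patients_included
    ))
  }
  included <- full[seq_len(n_patients_included)]

  if (is.null(table)) table <- variation_profile(match.arg(profile))
  if (!identical(dim(table), c(4L, 4L))) {
    validation_error("profile `table` must be a 4x4 recon-by-current matrix")
  }
  dimnames(table) <- list(recon = RECON_LEVELS, current_pct = as.character(SIM_CURRENTS))
  cells <- expand.grid(recon = RECON_LEVELS, current_pct = SIM_CURRENTS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$count <- as.vector(table)

  assigned <- with_seed(seed, {
    cell_idx <- if (sum(cells$count) == n_patients_included) {
      sample(rep.int(seq_len(nrow(cells)), cells$count))
    } else {
      sample(seq_len(nrow(cells)), n_patients_included,
             replace = TRUE, prob = cells$count)
    }
    data.frame(patient_id = sample(included), cell = cell_idx,
               stringsAsFactors = FALSE)
  })

  originals <- pool[pool$is_original & pool$patient_id %in% included, ]
  extras <- do.call(rbind, lapply(seq_len(nrow(assigned)), function(i) {
    p <- assigned$patient_id[i]
    cell <- cells[assigned$cell[i], ]
    hit <- pool$patient_id == p & pool$recon == cell$recon &
      pool$current_pct == cell$current_pct & !pool$is_original
    if (sum(hit) != 1L) {
      composition_error(sprintf(
        "no scan available for patient %s in cell (%s, %d%%)",
        p, cell$recon, cell$current_pct
      ))
    }
    pool[hit, ]
  }))

  out <- rbind(originals[order(originals$scan_id), ],
               extras[order(extras$scan_id), ])
  rownames(out) <- NULL
  out
}

#' Thurstonian observer model
#'
#' One synthetic observer: perceived quality of a scan is
#' `scale * latent_q + bias` plus fresh Gaussian noise at every look
#' (`sigma_compare` per side of a comparison, `sigma_likert` per Likert
#' rating). Fresh per-comparison noise is what makes simulated rankings
#' realistically intransitive. Likert scores cut perceived quality at the
#' four `thresholds`; widening the two middle intervals reproduces the
#' central-tendency bias of human raters who avoid extreme scores.
#'
#' @param scale Perceptual gain (>= 0).
#' @param bias Additive offset in IQ units.
#' @param sigma_compare Per-comparison noise SD (>= 0).
#' @param sigma_likert Per-rating noise SD (>= 0).
#' @param thresholds Strictly increasing cut-points `t1 < t2 < t3 < t4`
#'   mapping perceived quality to scores 1-5.
#' @param seed Integer seed (used when the observer is turned into an
#'   oracle or rating stream).
#' @return An `observer_model`.
#' @export
observer_model <- function(scale = 1, bias = 0,
                           sigma_compare = 0.5, sigma_likert = 0.5,
                           thresholds = c(-1.6, -0.7, 0.5, 1.4),
                           seed = 1L) {
  if (scale < 0) validation_error("`scale` must be >= 0")
  if (sigma_compare < 0 || sigma_likert < 0) {
    validation_error("noise SDs must be >= 0")
  }
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    validation_error("`thresholds` must be 4 strictly increasing cut-points")
  }
  structure(
    list(scale = as.numeric(scale), bias = as.numeric(bias),
         sigma_compare = as.numeric(sigma_compare),
         sigma_likert = as.numeric(sigma_likert),
         thresholds = as.numeric(thresholds), seed = as.integer(seed)),
    class = "observer_model"
  )
}

#' Default observer panel
#'
#' `k` observers sharing the default noise levels and Likert thresholds but
#' with individual perceptual gains (0.9-1.1) and biases (spread over
#' +/- 0.75 IQ units), emulating systematic rater offsets such as one
#' observer scoring consistently lower than another.
#'
#' @param k Number of observers (default 6).
#' @param sigma_compare,sigma_likert Noise SDs shared by the panel.
#' @return List of `observer_model`s named `obs1..obsk`.
#' @export
default_observers <- function(k = 6L, sigma_compare = 0.5, sigma_likert = 0.5) {
  k <- check_count(k, "k", min = 2L)
  obs <- lapply(seq_len(k), function(i) {
    observer_model(
      scale = seq(0.9, 1.1, length.out = k)[i],
      bias = seq(-0.75, 0.75, length.out = k)[i],
      sigma_compare = sigma_compare,
      sigma_likert = sigma_likert,
      seed = 200L + i
    )
  })
  names(obs) <- sprintf("obs%d", seq_len(k))
  obs
}

#' Simulate one forced-choice comparison
#'
#' Draws an independent perceived quality per side —
#' `scale * latent_q + bias + N(0, sigma_compare^2)` — and returns the scan
#' with the larger value, so `P(left wins) =
#' pnorm(scale * (qL - qR) / (sqrt(2) * sigma_compare))` (Thurstone Case V).
#' A tie in perceived quality (possible only in the noiseless limit) goes to
#' the lexicographically smaller `scan_id` for determinism.
#'
#' @param obs An [observer_model()].
#' @param left,right Single scan rows (must contain `scan_id`, `latent_q`).
#' @param stream An [rng_stream()] providing the noise draws.
#' @return The chosen `scan_id`.
#' @export
simulate_choice <- function(obs, left, right, stream) {
  stopifnot(inherits(obs, "observer_model"))
  if (identical(left$scan_id, right$scan_id)) {
    validation_error("a comparison needs two distinct scans")
  }
  noise <- stream_eval(stream, stats::rnorm(2, 0, obs$sigma_compare))
  xl <- obs$scale * left$latent_q + obs$bias + noise[1]
  xr <- obs$scale * right$latent_q + obs$bias + noise[2]
  if (xl > xr) {
    left$scan_id
  } else if (xr > xl) {
    right$scan_id
  } else {
    min(left$scan_id, right$scan_id)
  }
}

#' Simulate one Likert rating
#'
#' Perceived quality `x = scale * latent_q + bias + N(0, sigma_likert^2)` is
#' cut at the observer's thresholds: score `= 1 + #\{c : x > t_c\}`, an
#' ordinal-probit response in 1..5 (1 very poor ... 5 very good).
#'
#' @param obs An [observer_model()].
#' @param scan Single scan row (must contain `latent_q`).
#' @param stream An [rng_stream()].
#' @return Integer score in 1..5.
#' @export
simulate_likert <- function(obs, scan, stream) {
  stopifnot(inherits(obs, "observer_model"))
  x <- obs$scale * scan$latent_q + obs$bias +
    stream_eval(stream, stats::rnorm(1, 0, obs$sigma_likert))
  1L + sum(x > obs$thresholds)
}

#' Turn an observer into a comparison oracle
#'
#' Binds an observer and a dataset into the `(left_id, right_id) ->
#' chosen_id` oracle interface of [fj_rank()], with a private noise stream
#' so the whole session is a pure function of `seed`.
#'
#' @param obs An [observer_model()].
#' @param dataset Data frame with `scan_id` and `latent_q`.
#' @param seed Integer seed for the comparison noise.
#' @return An oracle function.
#' @export
observer_oracle <- function(obs, dataset, seed = obs$seed) {
  stopifnot(inherits(obs, "observer_model"))
  q <- stats::setNames(dataset$latent_q, dataset$scan_id)
  stream <- rng_stream(seed)
  function(left, right) {
    if (is.na(q[left]) || is.na(q[right])) {
      validation_error("oracle offered a scan not in its dataset")
    }
    simulate_choice(
      obs,
      list(scan_id = left, latent_q = unname(q[left])),
      list(scan_id = right, latent_q = unname(q[right])),
      stream
    )
  }
}

#' Read/write scan pools and datasets
#'
#' CSV layout: `scan_id, patient_id, current_pct, recon, is_original,
#' latent_q`.
#'
#' @param path CSV file path.
#' @return `read_scan_pool()`: the pool data frame; `write_scan_pool()`:
#'   `path`, invisibly.
#' @export
read_scan_pool <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "patient_id", "current_pct", "recon", "is_original", "latent_q")
  if (!all(need %in% names(df))) {
    validation_error("scan pool CSV is missing required columns")
  }
  df$is_original <- as.logical(df$is_original)
  df[, need]
}

#' @rdname read_scan_pool
#' @param pool Scan pool data frame.
#' @export
write_scan_pool <- function(pool, path) {
  utils::write.csv(pool, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observer model from JSON
#'
#' The file mirrors the [observer_model()] fields; absent fields take the
#' constructor defaults.
#'
#' @param path JSON file path.
#' @return An `observer_model`.
#' @export
read_observer_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- obj[intersect(names(obj), names(formals(observer_model)))]
  do.call(observer_model, args)
}
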