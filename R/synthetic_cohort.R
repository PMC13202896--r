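#' Configuration for a synthetic multimodal cohort
#'
#' Defines the generative conditions for [generate_cohort()]: expert token
#' groups with a controllable per-group signal, binary and continuous
#' clinical covariates, and proportional-hazards survival times for two
#' endpoints (PFS and OS) with independent uniform censoring.
#'
#' The survival model is exponential proportional hazards:
#' `h(t) = h0 * exp(sum_j beta_j x_j + beta_r * risk_e)`, where `risk_e` for
#' each endpoint mixes the shared standard-normal latent risk `r` with
#' endpoint-specific noise (`risk_e = (r + 0.5 eps_e) / sqrt(1.25)`), so the
#' PFS and OS heads learn related but distinct targets. Tokens of group `g`
#' are isotropic Gaussian noise shifted by `group_signal[g] * r` along a
#' fixed unit "signal direction" drawn once per group.
#'
#' @param n_patients Number of patients (> 0).
#' @param n_groups Number of expert token groups (default 7).
#' @param tokens_per_group Length-2 integer range; each group's token count
#'   is drawn uniformly from it.
#' @param embed_dim Token embedding dimension.
#' @param group_signal Numeric vector (recycled to `n_groups`) of per-group
#'   signal coefficients.
#' @param hazard_coefs Named log-hazard coefficients for the covariates
#'   `beta2m`, `wbc`, `ki67` (binary, Bernoulli(1/2)) and `tlg` (continuous;
#'   the coefficient applies to the standardized log metabolic burden).
#' @param beta_r Log-hazard coefficient of the latent risk.
#' @param baseline_hazard Baseline event rate per month.
#' @param os_hazard_scale OS baseline hazard as a fraction of the PFS one
#'   (overall survival is longer than progression-free survival).
#' @param censor_rate Target fraction of censored records in `[0, 1)`.
#' @param seed Integer seed; the seed fully determines the cohort.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          n_groups = 7L,
                          tokens_per_group = c(6L, 12L),
                          embed_dim = 32L,
                          group_signal = rep(0.5, n_groups),
                          hazard_coefs = c(beta2m = 0.4, wbc = 0.3,
                                           ki67 = 0.5, tlg = 0.3),
                          beta_r = 1.0,
                          baseline_hazard = 0.02,
                          os_hazard_scale = 0.6,
                          censor_rate = 0.3,
                          seed = 1L) {
  check_number(n_patients, "n_patients", positive = TRUE, integer = TRUE)
  check_number(n_groups, "n_groups", positive = TRUE, integer = TRUE)
  check_number(embed_dim, "embed_dim", positive = TRUE, integer = TRUE)
  check_number(baseline_hazard, "baseline_hazard", positive = TRUE)
  check_fraction(censor_rate, "censor_rate")
  if (censor_rate >= 1) stop_moesurv("'censor_rate' must be < 1")
  if (length(tokens_per_group) == 1L) tokens_per_group <- rep(tokens_per_group, 2L)
  if (tokens_per_group[1] < 1L || tokens_per_group[2] < tokens_per_group[1])
    stop_moesurv("'tokens_per_group' must be an increasing range of counts >= 1")
  group_signal <- rep(as.numeric(group_signal), length.out = n_groups)
  structure(list(n_patients = as.integer(n_patients),
                 n_groups = as.integer(n_groups),
                 tokens_per_group = as.integer(tokens_per_group),
                 embed_dim = as.integer(embed_dim),
                 group_signal = group_signal,
                 hazard_coefs = hazard_coefs,
                 beta_r = beta_r,
                 baseline_hazard = baseline_hazard,
                 os_hazard_scale = os_hazard_scale,
                 censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' A single survival record
#'
#' @param time Observed time in months (> 0).
#' @param event 1 if the event was observed, 0 if censored.
#' @param endpoint `"PFS"` or `"OS"`.
#' @return Object of class `survival_record`.
#' @export
survival_record <- function(time, event, endpoint = c("PFS", "OS")) {
  endpoint <- match.arg(endpoint)
  if (any(time <= 0)) stop_moesurv("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stop_moesurv("event indicators must be 0/1")
  structure(list(time = time, event = as.integer(event), endpoint = endpoint),
            class = "survival_record")
}

# Administrative horizon such that uniform-[0, T] censoring yields the
# requested censoring fraction against the observed event-time draws.
calibrate_censor_horizon <- function(event_times, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  # P(censored_i) = P(C < T_i) = min(T_i / Tadm, 1); calibrate the mean
  f <- function(Tadm) mean(pmin(event_times / Tadm, 1)) - censor_rate
  lo <- min(event_times) * 1e-3
  hi <- max(event_times) / censor_rate * 10
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

draw_endpoint <- function(lp, baseline_hazard, censor_rate, endpoint) {
  n <- length(lp)
  event_t <- stats::rexp(n) / (baseline_hazard * exp(lp))
  if (censor_rate <= 0) {
    return(survival_record(event_t, rep(1L, n), endpoint))
  }
  t_adm <- calibrate_censor_horizon(event_t, censor_rate)
  cens_t <- stats::runif(n, 0, t_adm)
  survival_record(pmin(event_t, cens_t), as.integer(event_t <= cens_t), endpoint)
}

#' Generate a synthetic multimodal cohort
#'
#' Draws latent risks, covariates, token groups and right-censored PFS/OS
#' survival records according to a [cohort_config()]. The same seed yields a
#' bit-identical cohort.
#'
#' @param config A `cohort_config`.
#' @return Object of class `moe_cohort`: list with `config`, `covariates`
#'   (data frame: `patient_id`, `beta2m`, `wbc`, `ki67`, `tlg`, `latent_risk`,
#'   `pfs_time`, `pfs_event`, `os_time`, `os_event`), `tokens` (per patient, a
#'   list of `token_group`s), and `directions` (per-group unit signal
#'   directions).
#' @examples
#' coh <- generate_cohort(cohort_config(20, seed = 7))
#' head(coh$covariates)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_moesurv("'config' must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_patients
  G <- config$n_groups
  d <- config$embed_dim

  # one fixed unit signal direction per group
  directions <- lapply(seq_len(G), function(g) {
    v <- stats::rnorm(d); v / sqrt(sum(v^2))
  })

  latent <- stats::rnorm(n)
  beta2m <- stats::rbinom(n, 1, 0.5)
  wbc <- stats::rbinom(n, 1, 0.5)
  ki67 <- stats::rbinom(n, 1, 0.5)
  tlg_z <- stats::rnorm(n)              # standardized log metabolic burden
  tlg <- exp(4.5 + tlg_z)               # reported on the TLG scale

  bc <- config$hazard_coefs
  lp_cov <- bc[["beta2m"]] * beta2m + bc[["wbc"]] * wbc +
    bc[["ki67"]] * ki67 + bc[["tlg"]] * tlg_z

  mix_risk <- function(eps) (latent + 0.5 * eps) / sqrt(1.25)
  risk_pfs <- mix_risk(stats::rnorm(n))
  risk_os <- mix_risk(stats::rnorm(n))

  pfs <- draw_endpoint(lp_cov + config$beta_r * risk_pfs,
                       config$baseline_hazard, config$censor_rate, "PFS")
  os <- draw_endpoint(lp_cov + config$beta_r * risk_os,
                      config$baseline_hazard * config$os_hazard_scale,
                      config$censor_rate, "OS")

  group_names <- default_group_names(G)
  tokens <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- vector("list", G)
    for (g in seq_len(G)) {
      ng <- sample(config$tokens_per_group[1]:config$tokens_per_group[2], 1L)
      X <- matrix(stats::rnorm(ng * d), ng, d) +
        config$group_signal[g] * latent[i] *
        matrix(directions[[g]], ng, d, byrow = TRUE)
      pat[[g]] <- token_group(g, X, name = group_names[g])
    }
    tokens[[i]] <- pat
  }

  covariates <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    beta2m = beta2m, wbc = wbc, ki67 = ki67, tlg = tlg,
    latent_risk = latent,
    pfs_time = pfs$time, pfs_event = pfs$event,
    os_time = os$time, os_event = os$event,
    stringsAsFactors = FALSE)

  structure(list(config = config, covariates = covariates,
                 tokens = tokens, directions = directions),
            class = "moe_cohort")
}

default_group_names <- function(G) {
  canonical <- c("vision_semantic_pet", "vision_semantic_ct",
                 "vision_morphology_pet", "vision_morphology_ct",
                 "radiomics_pet", "radiomics_ct", "text")
  if (G <= 7L) canonical[seq_len(G)] else c(canonical, sprintf("group_%d", 8:G))
}

#' @export
print.moe_cohort <- function(x, ...) {
  cat(sprintf("<moe_cohort n=%d  groups=%d  embed_dim=%d  seed=%d>\n",
              x$config$n_patients, x$config$n_groups,
              x$config$embed_dim, x$config$seed))
  invisible(x)
}

#' Extract the survival records of one endpoint from a cohort
#'
#' @param cohort A `moe_cohort`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @return A `survival_record` vector object.
#' @export
cohort_records <- function(cohort, endpoint = c("PFS", "OS")) {
  endpoint <- match.arg(endpoint)
  cv <- cohort$covariates
  if (endpoint == "PFS") survival_record(cv$pfs_time, cv$pfs_event, "PFS")
  else survival_record(cv$os_time, cv$os_event, "OS")
}

#' Write a cohort to disk
#'
#' Covariates and survival endpoints go to a single CSV; each patient's token
#' groups go to one RDS-free plain-text container (a `.tsv` per patient with a
#' `group`, `token` index and one column per embedding dimension); the config
#' is saved as JSON.
#'
#' @param cohort A `moe_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$covariates, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  cfg <- cohort$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  tok_dir <- file.path(dir, "tokens")
  dir.create(tok_dir, showWarnings = FALSE)
  for (i in seq_along(cohort$tokens)) {
    rows <- do.call(rbind, lapply(cohort$tokens[[i]], function(tg) {
      cbind(group = tg$group_id, token = seq_len(nrow(tg$tokens)), tg$tokens)
    }))
    utils::write.table(rows,
                       file.path(tok_dir, paste0(cohort$covariates$patient_id[i], ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Generate a toy PET/CT phantom with hypermetabolic lesions
#'
#' The PET volume is a uniform background with Gaussian-profile hot spots
#' (`sigma = radius / 2`); profiles are composited by voxelwise maximum so
#' each stated peak SUV is attained exactly at its centre voxel. The CT
#' volume carries matching soft-tissue density blobs.
#'
#' @param shape Integer length-3 grid dimensions `(z, y, x)`.
#' @param lesions List of lesions, each a list with `center` (1-based voxel
#'   index `(z, y, x)`), `radius` (mm) and `peak` (SUV, > background).
#' @param background Background SUV level.
#' @param spacing Voxel spacing in mm.
#' @param ct_background,ct_peak CT levels (HU) for background and lesions.
#' @return List with `pet` and `ct` `volume3d`s.
#' @examples
#' ph <- generate_phantom(c(16, 16, 16),
#'                        list(list(center = c(8, 8, 8), radius = 6, peak = 10)))
#' max(ph$pet$data)  # 10
#' @export
generate_phantom <- function(shape, lesions = list(), background = 1,
                             spacing = c(2, 2, 2),
                             ct_background = 0, ct_peak = 80) {
  shape <- as.integer(shape)
  pet <- array(background, shape)
  ct <- array(ct_background, shape)
  if (length(lesions)) {
    idx <- as.matrix(expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                                 x = seq_len(shape[3]), KEEP.OUT.ATTRS = FALSE))
    world <- sweep(idx - 1, 2, spacing, "*")
    for (les in lesions) {
      ctr <- as.numeric(les$center)
      if (any(ctr < 1) || any(ctr > shape))
        stop_moesurv("lesion center outside the grid")
      if (les$peak <= background)
        stop_moesurv("lesion peak SUV must exceed the background")
      ctr_w <- (ctr - 1) * spacing
      d2 <- rowSums(sweep(world, 2, ctr_w)^2)
      sigma <- les$radius / 2
      prof <- background + (les$peak - background) * exp(-d2 / (2 * sigma^2))
      pet <- array(pmax(pet, prof), shape)
      ct_prof <- ct_background + (ct_peak - ct_background) * exp(-d2 / (2 * sigma^2))
      ct <- array(pmax(ct, ct_prof), shape)
    }
  }
  list(pet = volume3d(pet, spacing = spacing, modality = "PET-SUV"),
       ct = volume3d(ct, spacing = spacing, modality = "CT-HU"))
}
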