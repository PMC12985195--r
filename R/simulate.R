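#' Configuration for the synthetic two-cohort qPCR generator
#'
#' The generator emulates, at the statistical level, the data-generating
#' process behind a two-cohort plasma miRNA panel study: per-assay baseline
#' Ct levels, per-sample additive technical offsets (input amount,
#' extraction/RT efficiency — exactly what pair ratios cancel), per-assay
#' group shifts for planted differential signal, censoring at the cycling
#' ceiling, and pass-by-default run-control wells with switches to inject
#' failures. Defaults mirror a typical pilot design: 30 cases vs 30
#' controls on a 48-assay panel, baselines uniform on 22-34 Ct, unit
#' within-group assay SD, 1.5-Ct sample offsets, 40-cycle ceiling.
#'
#' @param n_case,n_control cohort sizes (default 30 each)
#' @param n_assays panel size (default 48; use 61 with `n_killed = 13` for
#'   elimination-stage scenarios)
#' @param assay_ids assay names; default `SYN-mir-001` ... (or the packaged
#'   panel ids when `n_assays == 48` and `use_panel_ids = TRUE`)
#' @param mu per-assay baseline mean Ct; default drawn once from U\[22, 34\]
#'   under the seed
#' @param sigma per-assay within-group Ct SD (scalar or vector, default 1.0)
#' @param tau SD of the per-sample additive technical offset (default 1.5)
#' @param effects planted case-vs-control shifts: data frame with columns
#'   `assay` (id or index) and `delta` (Ct cycles added to cases); default
#'   none
#' @param censor_at cycling ceiling (default 40)
#' @param n_killed number of assays planted as poorly detectable (baselines
#'   pushed above the ceiling so the detection rate falls to
#'   `killed_detect_rate`); default 0
#' @param killed_detect_rate target detection rate of killed assays
#'   (default 0.3)
#' @param samples_per_plate panel layout: samples per plate (default 4)
#' @param ntc_contaminated plate ids whose NTC wells should amplify (default
#'   none)
#' @param spikein_drift extra across-plate SD injected into spike-in Ct
#'   (default 0)
#' @param tissue_shift,tissue_noise_sd matched-tissue generation: Ct shift
#'   (default -6; tissue amplifies ~6 cycles earlier) and per-assay pattern
#'   noise SD (default 1.7)
#' @param use_panel_ids use the packaged 48-miRNA panel ids when sizes match
#' @param seed integer seed (mandatory; identical config gives bit-identical
#'   output)
#' @return a validated list of class `synthetic_config`
#' @export
synthetic_config <- function(n_case = 30, n_control = 30, n_assays = 48,
                             assay_ids = NULL, mu = NULL, sigma = 1.0,
                             tau = 1.5, effects = NULL, censor_at = 40,
                             n_killed = 0, killed_detect_rate = 0.3,
                             samples_per_plate = 4,
                             ntc_contaminated = character(),
                             spikein_drift = 0,
                             tissue_shift = -6, tissue_noise_sd = 1.7,
                             use_panel_ids = TRUE, seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory for the synthetic generator")
  stopifnot(n_case >= 2, n_control >= 2, n_assays >= 2,
            all(sigma >= 0), tau >= 0, censor_at > 0,
            n_killed >= 0, n_killed < n_assays,
            killed_detect_rate > 0, killed_detect_rate < 1)
  if (is.null(assay_ids)) {
    panel <- gbm_panel()
    assay_ids <- if (use_panel_ids && n_assays <= nrow(panel))
      panel$mirna_id[seq_len(n_assays)]
    else sprintf("SYN-mir-%03d", seq_len(n_assays))
  }
  if (length(assay_ids) != n_assays || anyDuplicated(assay_ids))
    stop("assay_ids must be ", n_assays, " unique names")
  sigma <- rep_len(sigma, n_assays)
  if (!is.null(mu) && length(mu) != n_assays)
    stop("mu must have one baseline per assay")
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    if (!all(c("assay", "delta") %in% names(effects)))
      stop("effects needs columns `assay` and `delta`")
    if (is.numeric(effects$assay)) effects$assay <- assay_ids[effects$assay]
    if (!all(effects$assay %in% assay_ids))
      stop("effects reference unknown assays")
  }
  structure(list(
    n_case = n_case, n_control = n_control, n_assays = n_assays,
    assay_ids = assay_ids, mu = mu, sigma = sigma, tau = tau,
    effects = effects, censor_at = censor_at,
    n_killed = n_killed, killed_detect_rate = killed_detect_rate,
    samples_per_plate = samples_per_plate,
    ntc_contaminated = as.character(ntc_contaminated),
    spikein_drift = spikein_drift,
    tissue_shift = tissue_shift, tissue_noise_sd = tissue_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(list = ".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Theoretical AUC of a pair under the Gaussian Ct model
#'
#' For assays with case-minus-control Ct shifts `delta_a`, `delta_b` and
#' within-group SDs `sigma_a`, `sigma_b`, the pair's log2 feature difference
#' between cohorts is Gaussian, giving a closed-form AUC of
#' `Phi(|delta_a - delta_b| / sqrt(2 * (sigma_a^2 + sigma_b^2)))` (after
#' orientation; the sample offset cancels exactly and contributes nothing).
#'
#' @param delta_a,delta_b planted group shifts (Ct cycles)
#' @param sigma_a,sigma_b within-group assay SDs
#' @return theoretical AUC in \[0.5, 1\]
#' @export
theoretical_pair_auc <- function(delta_a, delta_b, sigma_a = 1, sigma_b = 1) {
  denom <- sqrt(2 * (sigma_a ^ 2 + sigma_b ^ 2))
  out <- ifelse(denom == 0, ifelse(delta_a == delta_b, 0.5, 1),
                stats::pnorm(abs(delta_a - delta_b) / denom))
  pmax(out, 0.5)
}

#' Generate a synthetic two-cohort qPCR dataset
#'
#' Draws `Ct[s, m] = mu_m + delta_m * [s is case] + u_s + eps[s, m]` with
#' `u_s ~ N(0, tau^2)` (per-sample technical offset) and
#' `eps ~ N(0, sigma_m^2)`, censors values above the ceiling, emits
#' per-plate control wells (pass-by-default, with configured failures), and
#' returns the ground-truth table every recovery test needs: per-assay
#' parameters and the theoretical AUC of every pair.
#'
#' @param config a [synthetic_config()]
#' @return list with `ct` (a `ct_matrix`), `controls` (a `control_wells`
#'   table), and `truth` (list: `assays` data frame with `mu`, `sigma`,
#'   `delta`, `killed`; `pairs` data frame with per-pair `theoretical_auc`;
#'   `differential_pairs`; `killed_assays`)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_case + config$n_control
    m <- config$n_assays
    ids <- config$assay_ids
    mu <- if (is.null(config$mu)) stats::runif(m, 22, 34) else config$mu
    sigma <- config$sigma
    tau <- config$tau

    killed <- rep(FALSE, m)
    if (config$n_killed > 0) {
      kill_idx <- seq(m - config$n_killed + 1, m)
      killed[kill_idx] <- TRUE
      # push the baseline so that P(Ct <= ceiling) equals the target rate
      tot_sd <- sqrt(sigma[kill_idx] ^ 2 + tau ^ 2)
      mu[kill_idx] <- config$censor_at -
        stats::qnorm(config$killed_detect_rate) * tot_sd
    }

    delta <- stats::setNames(rep(0, m), ids)
    if (!is.null(config$effects))
      delta[config$effects$assay] <- config$effects$delta

    cohort <- rep(c("case", "control"), c(config$n_case, config$n_control))
    sample_id <- sprintf("%s%03d", ifelse(cohort == "case", "GBM", "CTRL"),
                         c(seq_len(config$n_case), seq_len(config$n_control)))
    u <- stats::rnorm(n, 0, tau)
    eps <- matrix(stats::rnorm(n * m), n, m) *
      matrix(sigma, n, m, byrow = TRUE)
    ct <- matrix(mu, n, m, byrow = TRUE) +
      outer(as.numeric(cohort == "case"), delta) + u + eps
    dimnames(ct) <- list(sample_id, ids)
    cen <- ct > config$censor_at
    ct[cen] <- config$censor_at
    ct[ct <= 0] <- 0.01  # pathological negatives under extreme configs
    mat <- ct_matrix(ct, cohort = cohort, censored = cen,
                     sample_type = "plasma", max_cycles = config$censor_at)

    n_plates <- ceiling(n / config$samples_per_plate)
    plates <- sprintf("P%02d", seq_len(n_plates))
    sp3 <- stats::rnorm(n_plates, 20, 0.2) +
      stats::rnorm(n_plates, 0, config$spikein_drift)
    sp6 <- stats::rnorm(n_plates, 21, 0.2) +
      stats::rnorm(n_plates, 0, config$spikein_drift)
    pos <- stats::rnorm(n_plates, 24, 0.3)
    ntc <- rep(NA_real_, n_plates)
    contam <- plates %in% config$ntc_contaminated
    if (any(contam))
      ntc[contam] <- stats::median(ct[!cen]) - 1  # amplifies near sample level
    controls <- control_wells(
      control_type = rep(c("UniSp3", "UniSp6", "PosCtrl", "NTC", "BlankSpot"),
                         each = n_plates),
      plate_id = rep(plates, 5),
      ct = c(sp3, sp6, pos, ntc, rep(NA_real_, n_plates)),
      max_cycles = config$censor_at
    )

    pairs <- enumerate_pairs(ids)
    ia <- match(pairs$mirna_a, ids)
    ib <- match(pairs$mirna_b, ids)
    pairs$theoretical_auc <- theoretical_pair_auc(delta[ia], delta[ib],
                                                  sigma[ia], sigma[ib])
    truth <- list(
      assays = data.frame(mirna_id = ids, mu = mu, sigma = sigma,
                          delta = unname(delta), killed = killed,
                          stringsAsFactors = FALSE),
      pairs = pairs,
      differential_pairs = pairs$pair_id[delta[ia] != delta[ib]],
      killed_assays = ids[killed]
    )
    list(ct = mat, controls = controls, truth = truth)
  })
}

#' Generate matched tissue profiles from a plasma matrix
#'
#' Emulates matched tumor-tissue qPCR profiles for concordance analyses:
#' each tissue sample's Ct for an assay is the plasma per-assay mean plus a
#' global shift (tissue expresses higher, so the default shift is negative)
#' plus independent pattern noise.
#'
#' @param plasma a `ct_matrix`
#' @param n_samples number of tissue samples (default 3, a matched trio)
#' @param shift Ct shift added to the plasma mean profile (default -6)
#' @param noise_sd SD of the per-well pattern noise (default 1.7)
#' @param seed integer seed (mandatory)
#' @return a `ct_matrix` with `sample_type = "tissue"`
#' @export
generate_matched_tissue <- function(plasma, n_samples = 3, shift = -6,
                                    noise_sd = 1.7, seed) {
  stopifnot(inherits(plasma, "ct_matrix"), n_samples >= 1, noise_sd >= 0)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  with_seed(seed, {
    m <- n_assays(plasma)
    mean_profile <- vapply(seq_len(m), function(j) {
      v <- plasma$ct[!plasma$censored[, j], j]
      if (length(v)) mean(v) else plasma$max_cycles
    }, numeric(1))
    ct <- matrix(mean_profile, n_samples, m, byrow = TRUE) + shift +
      matrix(stats::rnorm(n_samples * m, 0, noise_sd), n_samples, m)
    dimnames(ct) <- list(sprintf("FFPE%02d", seq_len(n_samples)),
                         plasma$assays)
    cen <- ct > plasma$max_cycles
    ct[cen] <- plasma$max_cycles
    ct[ct <= 0] <- 0.01
    ct_matrix(ct, cohort = rep("case", n_samples), censored = cen,
              sample_type = "tissue", max_cycles = plasma$max_cycles)
  })
}
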