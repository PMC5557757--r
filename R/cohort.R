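#' Specification of a synthetic study cohort
#'
#' Collects every parameter the synthetic-data generator needs: group sizes,
#' event-related SCR amplitude cell means/SDs by group and stimulus intensity,
#' tonic skin conductance levels, questionnaire score distributions and their
#' loading on a latent autonomic-reactivity trait, psychophysical observer
#' parameters per task and body site, and a master seed. The defaults are
#' calibrated to the published group cell statistics of the study cohort this
#' package emulates (e.g. ASD weak-intensity event-related SCR mean 1.025
#' microsiemens, SD 0.559; tonic levels near 5-6 microsiemens), so a cohort
#' generated from the default spec has the dependence structure the analysis
#' pipeline assumes.
#'
#' The latent structure is linear-Gaussian: each participant carries a
#' standard-normal autonomic-reactivity trait. Questionnaire subscores are
#' `mean + sd * (loading * trait + sqrt(1 - loading^2) * noise)`, truncated at
#' instrument floors/ceilings, so the trait-questionnaire correlation equals
#' `loading` by construction (the Sensation Seeking subscale loads
#' negatively). Participant-level SCR amplitude means decompose their cell
#' variance into a trait share (`amp_trait_share`), a share common to both
#' intensities (`amp_shared_share`) and an intensity-specific remainder; the
#' within-participant weak-strong amplitude correlation therefore equals
#' `amp_trait_share + amp_shared_share` (default 0.5).
#'
#' @param n_asd,n_td group sizes (>= 1).
#' @param scr_amp_mean,scr_amp_sd named numeric vectors with elements
#'   `asd_weak`, `td_weak`, `asd_strong`, `td_strong`: cell means/SDs of the
#'   participant-mean event-related SCR amplitude, microsiemens.
#' @param trial_amp_sd SD of per-trial amplitude around the participant mean,
#'   microsiemens. Participant-level variance is reduced by `trial_amp_sd^2 /
#'   n_trials` so that observed participant means of the default 3
#'   trials-per-intensity reproduce the configured cell SDs.
#' @param amp_trait_share,amp_shared_share variance shares (each in `[0, 1]`,
#'   sum <= 1) of the amplitude decomposition described above.
#' @param tonic_level_mean named vector (`asd`, `td`) of tonic skin
#'   conductance level means, microsiemens; `tonic_level_sd` the common SD.
#' @param trait_questionnaire_loading correlation-scale loading in `[-1, 1]`
#'   linking the latent trait to questionnaire subscores.
#' @param questionnaire_means_sds data frame with columns `scale`, `subscale`,
#'   `asd_mean`, `asd_sd`, `td_mean`, `td_sd`, `loading_sign`, `floor`,
#'   `ceiling`; defaults cover the seven SRS-2 (sub)scores and four AASP
#'   quadrants.
#' @param nonresponder_rate probability that a participant is an electrodermal
#'   non-responder (phasic amplitudes scaled by `nonresponder_amp_scale`).
#' @param nonresponder_amp_scale amplitude multiplier for non-responders.
#' @param current_mean,current_sd named vectors (`asd_weak`, `td_weak`,
#'   `asd_strong`, `td_strong`) for the per-participant stimulation current,
#'   microamperes; weak currents are truncated to the 200-500 uA calibration
#'   band, strong to 300-2000 uA.
#' @param sensation_threshold_mean,sensation_threshold_sd named vectors
#'   (`asd`, `td`), microamperes (Gaussian).
#' @param pain_threshold_mean,pain_threshold_sd named vectors (`asd`, `td`),
#'   microamperes (moment-matched lognormal, keeping thresholds positive and
#'   right-skewed).
#' @param site_thr_2pdt_mean,site_thr_2pdt_sd named vectors
#'   (`asd_palm`, ..., `td_neck`) of two-point discrimination observer
#'   thresholds, millimetres (lognormal).
#' @param site_thr_tdt_mean,site_thr_tdt_sd same structure for touch
#'   detection observer thresholds, grams (lognormal).
#' @param observer_spread_frac observer psychometric spread as a fraction of
#'   the observer's threshold (Weber-like scaling).
#' @param tct_pse_mean,tct_pse_sd point of subjective equality of the touch
#'   comparison observer, grams (the 1.4 g standard, unbiased by default).
#' @param tct_slope_mean,tct_slope_sd logistic scale parameter `b` of the
#'   comparison observer, per gram (lognormal).
#' @param rating_means list with elements `weak` and `strong`, each a named
#'   vector (`intensity`, `pain`, `unpleasant`) of latent rating means on the
#'   0-10 scale.
#' @param rating_sd latent rating SD; `rating_participant_sd` the SD of a
#'   per-participant additive rating offset.
#' @param seed master integer seed.
#' @return An object of class `"cohort_spec"` (validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(
    n_asd = 23, n_td = 19,
    scr_amp_mean = c(asd_weak = 1.025, td_weak = 0.489,
                     asd_strong = 2.165, td_strong = 1.332),
    scr_amp_sd = c(asd_weak = 0.559, td_weak = 0.336,
                   asd_strong = 1.040, td_strong = 0.581),
    trial_amp_sd = 0.15,
    amp_trait_share = 0.2, amp_shared_share = 0.3,
    tonic_level_mean = c(asd = 5.9, td = 5.03), tonic_level_sd = 2.4,
    trait_questionnaire_loading = 0.7,
    questionnaire_means_sds = default_questionnaires(),
    nonresponder_rate = 0.1, nonresponder_amp_scale = 0.03,
    current_mean = c(asd_weak = 400, td_weak = 376,
                     asd_strong = 1209, td_strong = 1352),
    current_sd = c(asd_weak = 133, td_weak = 90,
                   asd_strong = 537, td_strong = 288),
    sensation_threshold_mean = c(asd = 8.262, td = 8.375),
    sensation_threshold_sd = c(asd = 1.563, td = 1.505),
    pain_threshold_mean = c(asd = 57.235, td = 47.814),
    pain_threshold_sd = c(asd = 41.927, td = 22.422),
    site_thr_2pdt_mean = c(asd_palm = 4.900, asd_forearm = 27.145,
                           asd_neck = 35.318, td_palm = 5.147,
                           td_forearm = 24.074, td_neck = 38.316),
    site_thr_2pdt_sd = c(asd_palm = 2.579, asd_forearm = 11.422,
                         asd_neck = 11.196, td_palm = 1.918,
                         td_forearm = 6.489, td_neck = 15.246),
    site_thr_tdt_mean = c(asd_palm = 0.071, asd_forearm = 0.251,
                          asd_neck = 0.263, td_palm = 0.069,
                          td_forearm = 0.297, td_neck = 0.176),
    site_thr_tdt_sd = c(asd_palm = 0.083, asd_forearm = 0.228,
                        asd_neck = 0.210, td_palm = 0.070,
                        td_forearm = 0.246, td_neck = 0.141),
    observer_spread_frac = 0.3,
    tct_pse_mean = 1.4, tct_pse_sd = 0.25,
    tct_slope_mean = 2.0, tct_slope_sd = 0.6,
    rating_means = list(
      weak = c(intensity = 3.5, pain = 1.2, unpleasant = 2.2),
      strong = c(intensity = 7.5, pain = 4.2, unpleasant = 5.3)
    ),
    rating_sd = 1.3, rating_participant_sd = 1.0,
    seed = 1L) {
  spec <- as.list(environment())
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

#' Default questionnaire score distributions
#'
#' Seven SRS-2 (sub)scores and four AASP quadrant scores on T-score-like
#' scales, with group means separated in the direction reported for
#' autistic-trait and sensory-profile instruments (Sensation Seeking lower in
#' the ASD group and loading negatively on the reactivity trait).
#'
#' @return Data frame consumed by [cohort_spec()].
#' @keywords internal
#' @export
default_questionnaires <- function() {
  rbind(
    data.frame(
      scale = "srs2",
      subscale = c("awareness", "cognition", "communication", "motivation",
                   "rrb", "sci", "total"),
      asd_mean = c(70, 74, 75, 71, 76, 75, 76),
      asd_sd = 10, td_mean = c(50, 49, 50, 51, 49, 50, 50), td_sd = 8,
      loading_sign = 1, floor = 30, ceiling = 95
    ),
    data.frame(
      scale = "aasp",
      subscale = c("low_registration", "sensation_seeking",
                   "sensory_sensitivity", "sensation_avoiding"),
      asd_mean = c(45, 35, 48, 47),
      asd_sd = 7, td_mean = c(33, 45, 36, 40), td_sd = 6,
      loading_sign = c(1, -1, 1, 1), floor = 15, ceiling = 75
    )
  )
}

validate_cohort_spec <- function(spec) {
  check_pos_int <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
      stop("`", nm, "` must be an integer >= 1, got ", x)
    }
  }
  check_pos_int(spec$n_asd, "n_asd")
  check_pos_int(spec$n_td, "n_td")
  cells <- c("asd_weak", "td_weak", "asd_strong", "td_strong")
  for (nm in c("scr_amp_mean", "scr_amp_sd", "current_mean", "current_sd")) {
    if (!all(cells %in% names(spec[[nm]]))) {
      stop("`", nm, "` must be named with cells ", paste(cells, collapse = ", "))
    }
  }
  for (nm in c("scr_amp_sd", "current_sd", "tonic_level_sd", "trial_amp_sd",
               "sensation_threshold_sd", "pain_threshold_sd",
               "site_thr_2pdt_sd", "site_thr_tdt_sd", "tct_pse_sd",
               "tct_slope_sd", "rating_sd", "rating_participant_sd")) {
    if (any(spec[[nm]] < 0)) stop("`", nm, "` must be nonnegative")
  }
  if (any(spec$scr_amp_mean < 0)) stop("`scr_amp_mean` must be nonnegative")
  s <- c(spec$amp_trait_share, spec$amp_shared_share)
  if (any(s < 0) || sum(s) > 1) {
    stop("`amp_trait_share` and `amp_shared_share` must be nonnegative with sum <= 1")
  }
  if (abs(spec$trait_questionnaire_loading) > 1) {
    stop("`trait_questionnaire_loading` must lie in [-1, 1]")
  }
  if (spec$nonresponder_rate < 0 || spec$nonresponder_rate > 1) {
    stop("`nonresponder_rate` must be a probability")
  }
  if (length(spec$seed) != 1 || !is.finite(spec$seed)) {
    stop("`seed` must be a single integer")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d ASD + %d TD participants, seed %d\n",
    x$n_asd, x$n_td, as.integer(x$seed)
  ))
  cat("  SCR amplitude cell means (uS): ",
      paste(sprintf("%s=%.3f", names(x$scr_amp_mean), x$scr_amp_mean),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# moment-matched lognormal draws (mean m, sd s on the natural scale)
rlnorm_ms <- function(n, m, s) {
  stopifnot(all(m > 0))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a synthetic participant cohort
#'
#' Draws the full latent and observed participant-level structure from a
#' [cohort_spec()]: group labels, demographics, the latent
#' autonomic-reactivity trait, questionnaire subscores, per-participant SCR
#' amplitude means by intensity, tonic levels, stimulation currents,
#' sensation/pain thresholds, and per-site psychophysical observer parameters
#' for the staircase and comparison tasks. Deterministic given
#' `(spec, spec$seed)`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `"tact_cohort"`: a list with
#'   \describe{
#'     \item{participants}{data frame of observable per-participant fields
#'       (id, group, age, sex, `srs2_*`, `aasp_*`, sensation/pain
#'       thresholds).}
#'     \item{latent}{data frame of latent fields (trait, responder flag,
#'       amplitude means, tonic level, currents, per-site observer thresholds,
#'       comparison-task parameters, rating offset).}
#'     \item{spec}{the generating spec.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_spec(n_asd = 4, n_td = 4, seed = 7))
#' coh$participants[, c("participant_id", "group", "srs2_total")]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n_asd + spec$n_td
  group <- c(rep("asd", spec$n_asd), rep("td", spec$n_td))
  id <- sprintf("P%03d", seq_len(n))

  with_seed(substream_seed(spec$seed, "cohort"), {
    trait <- stats::rnorm(n)
    age <- round(pmin(pmax(stats::rnorm(n, 40, 8), 20), 62), 1)
    sex <- sample(c("f", "m"), n, replace = TRUE)
    responder <- stats::runif(n) >= spec$nonresponder_rate

    # questionnaire subscores: linear-Gaussian in the trait, truncated at
    # instrument floors/ceilings
    q <- spec$questionnaire_means_sds
    lam <- spec$trait_questionnaire_loading
    qscores <- matrix(NA_real_, n, nrow(q))
    colnames(qscores) <- paste0(q$scale, "_", q$subscale)
    for (j in seq_len(nrow(q))) {
      mu <- ifelse(group == "asd", q$asd_mean[j], q$td_mean[j])
      sdv <- ifelse(group == "asd", q$asd_sd[j], q$td_sd[j])
      lj <- lam * q$loading_sign[j]
      z <- lj * trait + sqrt(1 - lj^2) * stats::rnorm(n)
      qscores[, j] <- round(pmin(pmax(mu + sdv * z, q$floor[j]), q$ceiling[j]))
    }

    # participant-level SCR amplitude means: variance split into trait /
    # shared / intensity-specific components; reduced by the trial-mean
    # sampling variance so that observed 3-trial means match the cell SDs
    wt <- spec$amp_trait_share
    wu <- spec$amp_shared_share
    we <- 1 - wt - wu
    u <- stats::rnorm(n)
    zw <- stats::rnorm(n)
    zs <- stats::rnorm(n)
    cell <- function(intensity) paste0(group, "_", intensity)
    amp_mean_for <- function(intensity, zi) {
      m <- spec$scr_amp_mean[cell(intensity)]
      s <- spec$scr_amp_sd[cell(intensity)]
      s_adj <- sqrt(pmax(s^2 - spec$trial_amp_sd^2 / 3, (0.3 * s)^2))
      a <- m + s_adj * (sqrt(wt) * trait + sqrt(wu) * u + sqrt(we) * zi)
      a <- pmax(a, 0.01)
      ifelse(responder, a, a * spec$nonresponder_amp_scale)
    }
    amp_weak <- amp_mean_for("weak", zw)
    amp_strong <- amp_mean_for("strong", zs)

    tonic <- pmax(stats::rnorm(n, spec$tonic_level_mean[group],
                               spec$tonic_level_sd), 0.5)

    trunc_norm <- function(n, m, s, lo, hi) pmin(pmax(stats::rnorm(n, m, s), lo), hi)
    cur_weak <- trunc_norm(n, spec$current_mean[cell("weak")],
                           spec$current_sd[cell("weak")], 200, 500)
    cur_strong <- trunc_norm(n, spec$current_mean[cell("strong")],
                             spec$current_sd[cell("strong")], 300, 2000)

    sens_thr <- pmax(stats::rnorm(n, spec$sensation_threshold_mean[group],
                                  spec$sensation_threshold_sd[group]), 0.5)
    pain_thr <- rlnorm_ms(n, spec$pain_threshold_mean[group],
                          spec$pain_threshold_sd[group])

    site_cell <- function(site) paste0(group, "_", site)
    thr_site <- function(means, sds, site) {
      rlnorm_ms(n, means[site_cell(site)], sds[site_cell(site)])
    }
    thr2 <- sapply(c("palm", "forearm", "neck"), function(s) {
      thr_site(spec$site_thr_2pdt_mean, spec$site_thr_2pdt_sd, s)
    })
    thrt <- sapply(c("palm", "forearm", "neck"), function(s) {
      thr_site(spec$site_thr_tdt_mean, spec$site_thr_tdt_sd, s)
    })

    tct_pse <- pmax(stats::rnorm(n, spec$tct_pse_mean, spec$tct_pse_sd), 0.45)
    tct_b <- rlnorm_ms(n, spec$tct_slope_mean, spec$tct_slope_sd)
    rating_offset <- stats::rnorm(n, 0, spec$rating_participant_sd)

    participants <- data.frame(
      participant_id = id, group = group, age = age, sex = sex,
      stringsAsFactors = FALSE
    )
    participants <- cbind(participants, as.data.frame(qscores))
    participants$sensation_threshold_uA <- sens_thr
    participants$pain_threshold_uA <- pain_thr

    latent <- data.frame(
      participant_id = id, group = group,
      trait = trait, responder = responder,
      amp_mean_weak = amp_weak, amp_mean_strong = amp_strong,
      tonic_level = tonic,
      current_weak_uA = cur_weak, current_strong_uA = cur_strong,
      thr_2pdt_palm = thr2[, "palm"], thr_2pdt_forearm = thr2[, "forearm"],
      thr_2pdt_neck = thr2[, "neck"],
      thr_tdt_palm = thrt[, "palm"], thr_tdt_forearm = thrt[, "forearm"],
      thr_tdt_neck = thrt[, "neck"],
      tct_pse = tct_pse, tct_slope_b = tct_b,
      rating_offset = rating_offset,
      stringsAsFactors = FALSE
    )

    structure(list(participants = participants, latent = latent, spec = spec),
              class = "tact_cohort")
  })
}

#' @export
print.tact_cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("Synthetic tactile-study cohort: %d ASD, %d TD (seed %d)\n",
              tab[["asd"]], tab[["td"]], as.integer(x$spec$seed)))
  invisible(x)
}
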