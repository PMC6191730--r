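#' Cohort configuration
#'
#' Defines the marginal structure of a simulated patient cohort. The default
#' configuration reproduces the study cohort reported for the benchmarking
#' population: 250 patients split 72 GORD (gastro-oesophageal reflux
#' disease) / 178 LPR (laryngopharyngeal reflux), aspiration probabilities
#' 10/72 and 58/178, severe ineffective oesophageal motility (IOM) in 17%
#' (GORD) vs 35% (LPR) with normal motility in 49% vs 27%, a 25/78/147 split
#' of the 24-h pH study categories, and lower-oesophageal-sphincter (LOS)
#' pressure lognormal with median 2.3 and mean 6.3 mmHg.
#'
#' Covariate couplings are induced through a Gaussian copula with
#' rank-preserving marginals: proximal vs distal acid exposure (target
#' Pearson r), and severe IOM vs aspiration (target phi coefficient per
#' symptom class, solved through the tetrachoric relation).
#'
#' @param n_total,n_gord,n_lpr cohort sizes; \code{n_gord + n_lpr} must equal
#'   \code{n_total}
#' @param aspiration_prob_gord,aspiration_prob_lpr per-class probability of
#'   true pulmonary aspiration
#' @param severe_iom_prob,normal_motility_prob named per-class probability
#'   vectors (\code{gord}, \code{lpr}); the residual mass is split equally
#'   between mild and moderate IOM
#' @param los_lognormal_params \code{c(location, scale)} on the log scale for
#'   LOS pressure in mmHg
#' @param ph_category_probs probabilities of the (normal, weakly_acidic,
#'   abnormal) 24-h pH categories; must sum to 1
#' @param r_proximal_distal target Pearson correlation between proximal and
#'   distal acid exposure
#' @param phi_iom_aspiration named per-class target phi coefficient between
#'   the severe-IOM indicator and aspiration
#' @param r_iom_refluxrate latent coupling between IOM severity and the
#'   reflux event rate (drives the emergent IOM vs rising-curve association)
#' @param sex_prob_female probability of female sex
#' @param seed default master seed used by \code{\link{generate_cohort}}
#' @return an object of class \code{cohort_config}
#' @export
cohort_config <- function(n_total = 250L,
                          n_gord = 72L,
                          n_lpr = 178L,
                          aspiration_prob_gord = 10 / 72,
                          aspiration_prob_lpr = 58 / 178,
                          severe_iom_prob = c(gord = 0.17, lpr = 0.35),
                          normal_motility_prob = c(gord = 0.49, lpr = 0.27),
                          los_lognormal_params = c(location = log(2.3),
                                                   scale = sqrt(2 * log(6.3 / 2.3))),
                          ph_category_probs = c(normal = 25, weakly_acidic = 78,
                                                abnormal = 147) / 250,
                          r_proximal_distal = 0.32,
                          phi_iom_aspiration = c(gord = 0.21, lpr = 0.54),
                          r_iom_refluxrate = 0.45,
                          sex_prob_female = 155 / 250,
                          seed = 1L) {
  cfg <- list(n_total = as.integer(n_total), n_gord = as.integer(n_gord),
              n_lpr = as.integer(n_lpr),
              aspiration_prob_gord = aspiration_prob_gord,
              aspiration_prob_lpr = aspiration_prob_lpr,
              severe_iom_prob = severe_iom_prob,
              normal_motility_prob = normal_motility_prob,
              los_lognormal_params = los_lognormal_params,
              ph_category_probs = ph_category_probs,
              r_proximal_distal = r_proximal_distal,
              phi_iom_aspiration = phi_iom_aspiration,
              r_iom_refluxrate = r_iom_refluxrate,
              sex_prob_female = sex_prob_female,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_gord + cfg$n_lpr != cfg$n_total)
    stop("cohort_config: n_gord + n_lpr must equal n_total")
  if (abs(sum(cfg$ph_category_probs) - 1) > 1e-9)
    stop("cohort_config: ph_category_probs must sum to 1")
  for (f in c("aspiration_prob_gord", "aspiration_prob_lpr", "sex_prob_female")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || p < 0 || p > 1)
      stop(sprintf("cohort_config: %s must be a probability in [0, 1]", f))
  }
  for (cl in c("gord", "lpr")) {
    tot <- cfg$severe_iom_prob[[cl]] + cfg$normal_motility_prob[[cl]]
    if (cfg$severe_iom_prob[[cl]] < 0 || cfg$normal_motility_prob[[cl]] < 0 || tot > 1)
      stop(sprintf("cohort_config: IOM probabilities for class '%s' invalid", cl))
  }
  invisible(cfg)
}

# P(Z1 > q1, Z2 > q2) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature.
.bvn_upper <- function(q1, q2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(-q1) * stats::pnorm(-q2))
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((q2 - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  stats::integrate(f, lower = q1, upper = Inf, rel.tol = 1e-10)$value
}

# latent normal correlation that yields a target phi coefficient between two
# binary indicators with marginal probabilities p1, p2 (upper-tail cuts)
.solve_tetrachoric <- function(p1, p2, phi_target) {
  # degenerate margins admit no association; the latent coupling is moot
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1 || phi_target == 0) return(0)
  q1 <- stats::qnorm(1 - p1)
  q2 <- stats::qnorm(1 - p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  g <- function(rho) (.bvn_upper(q1, q2, rho) - p1 * p2) / denom - phi_target
  stats::uniroot(g, c(-0.995, 0.995), tol = 1e-9)$root
}

# IOM grade probabilities per class: (normal, mild, moderate, severe)
.iom_probs <- function(cfg, class) {
  cl <- tolower(class)
  p_norm <- cfg$normal_motility_prob[[cl]]
  p_sev <- cfg$severe_iom_prob[[cl]]
  rest <- 1 - p_norm - p_sev
  c(normal = p_norm, mild = rest / 2, moderate = rest / 2, severe = p_sev)
}

IOM_LEVELS <- c("normal", "mild", "moderate", "severe")

# clearance rate (per minute) by IOM grade: oesophageal clearance slows as
# motility deteriorates
CLEARANCE_BY_IOM <- c(normal = 0.5, mild = 0.25, moderate = 0.12, severe = 0.05)

# per-patient substream seed: documented counter scheme so cohorts are
# extensible without reshuffling existing patients
patient_seed <- function(master_seed, i, stream = 0L) {
  (as.numeric(master_seed) * 48271 + i * 7919 + stream * 104729) %% 2147483647
}

#' Generate a ground-truth patient cohort
#'
#' Draws patient covariates (symptom class, IOM grade, LOS pressure, acid
#' exposure, pH category, aspiration ground truth) and the kinetics
#' parameters that drive each patient's simulated images. Class counts are
#' exact (\code{n_gord} then \code{n_lpr} patients); all per-patient draws
#' use a deterministic substream of the master seed. Severe IOM implies low
#' oesophageal clearance, and true aspiration implies pharyngeal reflux
#' height with a positive aspiration fraction, so downstream curve grades
#' and lung findings are emergent rather than assigned.
#'
#' @param config a \code{\link{cohort_config}}
#' @param seed master seed; defaults to \code{config$seed}
#' @return an object of class \code{reflux_cohort}: a list with
#'   \code{patients} (data frame, one row per patient) and \code{kinetics}
#'   (list of \code{\link{kinetics_params}})
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  n <- config$n_total

  # per-class copula parameters
  rho_asp_iom <- c(
    gord = .solve_tetrachoric(config$aspiration_prob_gord,
                              config$severe_iom_prob[["gord"]],
                              config$phi_iom_aspiration[["gord"]]),
    lpr = .solve_tetrachoric(config$aspiration_prob_lpr,
                             config$severe_iom_prob[["lpr"]],
                             config$phi_iom_aspiration[["lpr"]]))

  classes <- c(rep("GORD", config$n_gord), rep("LPR", config$n_lpr))
  rows <- vector("list", n)
  kin <- vector("list", n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(n)) {
    set.seed(patient_seed(seed, i))
    cls <- classes[i]
    cl <- tolower(cls)
    p_asp <- if (cls == "GORD") config$aspiration_prob_gord else config$aspiration_prob_lpr

    # latent Gaussian vector: (aspiration, IOM, reflux rate, proximal, distal)
    R <- diag(5)
    R[1, 2] <- R[2, 1] <- rho_asp_iom[[cl]]
    R[2, 3] <- R[3, 2] <- config$r_iom_refluxrate
    R[1, 3] <- R[3, 1] <- rho_asp_iom[[cl]] * config$r_iom_refluxrate
    R[4, 5] <- R[5, 4] <- config$r_proximal_distal
    L <- chol(R)
    z <- drop(stats::rnorm(5) %*% L)

    true_asp <- stats::pnorm(z[1]) > 1 - p_asp
    # IOM grade from the latent: severe occupies the upper tail
    probs <- .iom_probs(config, cls)
    iom <- IOM_LEVELS[findInterval(stats::pnorm(z[2]),
                                   cumsum(probs)[-4], left.open = FALSE) + 1L]
    # acid exposure (% of 24 h with pH < 4): right-skewed gamma marginals
    u_prox <- stats::pnorm(z[4]); u_dist <- stats::pnorm(z[5])
    proximal_acid <- stats::qgamma(u_prox, shape = 1.2, scale = 2.5)
    distal_acid <- stats::qgamma(u_dist, shape = 1.5, scale = 4.5)

    los <- stats::rlnorm(1, config$los_lognormal_params[[1]],
                         config$los_lognormal_params[[2]])
    ph_cat <- sample(names(config$ph_category_probs), 1,
                     prob = config$ph_category_probs)
    sex <- if (stats::runif(1) < config$sex_prob_female) "F" else "M"
    age <- round(min(85, max(20, stats::rnorm(1, 60, 13))))

    # kinetics from covariates
    clearance <- CLEARANCE_BY_IOM[[iom]] * exp(stats::rnorm(1, 0, 0.2))
    u_rate <- stats::pnorm(z[3])
    rate_up <- stats::qlnorm(u_rate, log(0.5), 0.5)
    rate_sup <- stats::qlnorm(stats::pnorm(0.8 * z[3] + 0.6 * stats::rnorm(1)),
                              log(0.3), 0.5)
    if (true_asp) {
      height <- "pharynx"
      asp_frac <- stats::rbeta(1, 4, 76)   # mean 0.05
    } else {
      height_probs <- if (cls == "LPR") c(0.1, 0.2, 0.3, 0.4) else c(0.4, 0.3, 0.2, 0.1)
      height <- sample(REFLUX_HEIGHTS, 1, prob = height_probs)
      asp_frac <- 0
    }
    kin[[i]] <- kinetics_params(
      gastric_half_time = max(10, stats::rnorm(1, 25.2, 5)),
      reflux_event_rate_upright = rate_up,
      reflux_event_rate_supine = rate_sup,
      max_reflux_height = height,
      reflux_fraction = stats::rbeta(1, 2, 38),  # mean 0.05
      clearance_rate = clearance,
      aspiration_fraction = asp_frac,
      administered_activity = stats::runif(1, 40, 60))

    rows[[i]] <- data.frame(
      patient_id = sprintf("P%04d", i),
      symptom_class = cls,
      age = age,
      sex = sex,
      iom_grade = iom,
      los_pressure = los,
      proximal_acid_pct = proximal_acid,
      distal_acid_pct = distal_acid,
      ph_category = ph_cat,
      true_aspiration = true_asp,
      stringsAsFactors = FALSE)
  }
  patients <- do.call(rbind, rows)
  patients$iom_grade <- factor(patients$iom_grade, levels = IOM_LEVELS,
                               ordered = TRUE)
  structure(list(patients = patients, kinetics = kin, config = config,
                 seed = seed),
            class = "reflux_cohort")
}

#' Classify a reflux episode from its pH trace
#'
#' Classifies a reflux episode by the minimum pH reached: below 4 is acid
#' reflux, at least 4 but below 7 is weakly acid, and 7 or above is
#' non-acid.
#'
#' @param ph numeric vector of pH values recorded during the episode, each
#'   in \code{[0, 14]}
#' @return one of \code{"acid"}, \code{"weakly_acid"}, \code{"non_acid"}
#' @export
classify_ph <- function(ph) {
  if (length(ph) == 0) stop("classify_ph: empty pH sequence")
  if (any(!is.finite(ph)) || any(ph < 0) || any(ph > 14))
    stop("classify_ph: pH values must be finite and in [0, 14]")
  m <- min(ph)
  if (m < 4) "acid" else if (m < 7) "weakly_acid" else "non_acid"
}

#' @export
print.reflux_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("Simulated reflux cohort: %d patients (%d GORD / %d LPR), seed %d\n",
              nrow(p), sum(p$symptom_class == "GORD"),
              sum(p$symptom_class == "LPR"), x$seed))
  cat(sprintf("  true aspiration: %d (%.0f%%)\n", sum(p$true_aspiration),
              100 * mean(p$true_aspiration)))
  cat("  IOM grades:", paste(sprintf("%s %d", levels(p$iom_grade),
                                     table(p$iom_grade)), collapse = ", "), "\n")
  invisible(x)
}
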