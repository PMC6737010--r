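# Synthetic cohort generator: block-covariance multivariate-normal ROI time
# series with age-dependent within-network correlation, age-increasing
# scrubbing and cognition scores coupled to true system segregation.

#' Build a simulation configuration
#'
#' Defaults describe a realistic aging resting-state cohort: ten networks
#' with the canonical ROI counts (214 ROIs total), within-network
#' correlations around 0.2-0.3 at age 20 declining linearly with age,
#' weaker age-stable between-network correlation, T = 285 volumes at
#' TR = 2 s (the 9.5-minute protocol; 150 volumes = 5 minutes), scrubbing
#' percentage increasing with age, and cognition domain scores generated as
#' a linear function of each subject's true (noise-free) system segregation
#' plus Gaussian residual.
#'
#' @param network_sizes Named integer vector of per-network ROI counts.
#' @param r_within Named numeric vector: baseline within-network Pearson r
#'   at age 20, per network.
#' @param r_within_slope Named numeric vector: change in within-network r
#'   per year of age (<= 0 for declining networks).
#' @param r_between Baseline between-network r at age 20.
#' @param r_between_slope Change in between-network r per year.
#' @param t_volumes Number of volumes per scan (150 or 285 in the emulated
#'   protocols; any T >= 3 accepted).
#' @param tr_seconds Sampling interval (default 2 s).
#' @param n_per_group Subjects per age group (YA, yMA, oMA, OA).
#' @param age_ranges List of c(min, max) per group.
#' @param scrub_base Scrub fraction at age 20.
#' @param scrub_slope Scrub fraction increase per year.
#' @param scrub_sd Between-subject scrub noise (Gaussian, truncated to
#'   [0, 0.45]; subjects at or above 0.30 are excluded downstream).
#' @param cognition_beta Named numeric vector: slope of each domain's raw
#'   score on true system segregation.
#' @param cognition_sd Residual standard deviation of raw domain scores.
#' @param seed Master seed; all randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    network_sizes = .NETSEG_NETWORKS,
    r_within = c(Hand = 0.28, Vis = 0.30, Mouth = 0.26, Aud = 0.26,
                 DMN = 0.24, Sal = 0.22, CO = 0.24, FP = 0.22,
                 DAN = 0.24, VAN = 0.22),
    r_within_slope = stats::setNames(rep(-0.0015, 10), names(.NETSEG_NETWORKS)),
    r_between = 0.08,
    r_between_slope = 0,
    t_volumes = 285L,
    tr_seconds = 2,
    n_per_group = 30L,
    age_ranges = list(YA = c(20, 34), yMA = c(35, 49),
                      oMA = c(50, 64), OA = c(65, 80)),
    scrub_base = 0.03,
    scrub_slope = 0.0009,
    scrub_sd = 0.02,
    cognition_beta = c(VOCAB = 0, SPEED = 4.5, FLUID = 3.5, MEM = 3.5),
    cognition_sd = 1,
    seed = 1L) {
  stopifnot(all(network_sizes >= 1L), t_volumes >= 3L,
            all(names(r_within) == names(network_sizes)),
            all(names(r_within_slope) == names(network_sizes)),
            all(names(age_ranges) == age_groups()))
  cfg <- list(network_sizes = network_sizes, r_within = r_within,
              r_within_slope = r_within_slope, r_between = r_between,
              r_between_slope = r_between_slope,
              t_volumes = as.integer(t_volumes), tr_seconds = tr_seconds,
              n_per_group = as.integer(n_per_group), age_ranges = age_ranges,
              scrub_base = scrub_base, scrub_slope = scrub_slope,
              scrub_sd = scrub_sd, cognition_beta = cognition_beta,
              cognition_sd = cognition_sd, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  # fail fast if the implied covariance is infeasible at the age extremes
  for (age in c(20, 80)) build_covariance(cfg, age)
  cfg
}

# correlation parameters at a given age (reference age 20), floored at 0
.age_params <- function(config, age) {
  dy <- age - 20
  rw <- pmax(pmin(config$r_within + config$r_within_slope * dy, 0.99), 0)
  rb <- max(min(config$r_between + config$r_between_slope * dy, 0.99), 0)
  list(r_within = rw, r_between = rb)
}

#' Block covariance matrix implied by a config at a given age
#'
#' Unit-variance block matrix: within-network off-diagonal cells carry that
#' network's age-adjusted r, cross-network cells the age-adjusted between
#' r. With r_within >= r_between >= 0 the construction is positive
#' semidefinite by design; a nearest-PSD eigenvalue-clipping repair is
#' applied otherwise, and the config is rejected if the repair shifts any
#' eigenvalue by more than 0.05.
#'
#' @param config A `simulation_config`.
#' @param age Subject age in years.
#' @return N x N covariance matrix with network-labelled dimnames.
#' @export
build_covariance <- function(config, age) {
  p <- .age_params(config, age)
  sizes <- config$network_sizes
  n <- sum(sizes)
  labels <- rep(names(sizes), times = sizes)
  cv <- matrix(p$r_between, n, n)
  for (k in names(sizes)) {
    sel <- labels == k
    cv[sel, sel] <- p$r_within[[k]]
  }
  diag(cv) <- 1
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    shift <- -min(ev)
    if (shift > 0.05)
      stop(sprintf("infeasible config: PSD repair shift %.3f > 0.05", shift))
    e <- eigen(cv, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    cv <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(cv))
    cv <- cv / outer(d, d)
  }
  dimnames(cv) <- list(labels, labels)
  cv
}

#' True (noise-free) system segregation of a config at a given age
#'
#' Closed-form SS of the Fisher-z transform of the exact correlation
#' matrix: cell-weighted means of atanh(r) over within- and between-network
#' cells.
#'
#' @inheritParams build_covariance
#' @return Scalar SS.
#' @export
true_segregation <- function(config, age) {
  p <- .age_params(config, age)
  sizes <- config$network_sizes
  n_within <- sum(sizes * (sizes - 1) / 2)
  n_total <- sum(sizes) * (sum(sizes) - 1) / 2
  n_between <- n_total - n_within
  zw <- sum(atanh(p$r_within) * sizes * (sizes - 1) / 2) / n_within
  zb <- atanh(p$r_between)   # uniform across between cells
  (zw - zb) / zw
}

#' Simulate one subject's ROI time series
#'
#' T independent multivariate-normal draws from the given covariance
#' (temporal autocorrelation of BOLD is deliberately not modelled).
#' Deterministic given the seed.
#'
#' @param cov N x N covariance matrix.
#' @param t_volumes Number of volumes (>= 3).
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @param tr_seconds Sampling interval.
#' @return A `roi_timeseries`, ROI columns named `1..N`.
#' @export
simulate_subject <- function(cov, t_volumes, seed, subject_id = "subj",
                             tr_seconds = 2) {
  if (t_volumes < 3L) stop("need at least 3 volumes")
  n <- nrow(cov)
  L <- tryCatch(chol(cov), error = function(e) {
    e <- eigen(cov, symmetric = TRUE)
    chol(e$vectors %*% diag(pmax(e$values, 1e-10)) %*% t(e$vectors))
  })
  x <- .with_seed(seed, matrix(stats::rnorm(t_volumes * n), t_volumes, n)) %*% L
  colnames(x) <- as.character(seq_len(n))
  time_series(x, subject_id = subject_id, tr_seconds = tr_seconds)
}

#' Remove volumes at random to emulate motion scrubbing
#'
#' Deletes `round(fraction * T)` volumes (round-half-away-from-zero) at
#' seeded random positions and records the realized scrub fraction.
#'
#' @param ts A `roi_timeseries`.
#' @param fraction Fraction of volumes to remove, in [0, 1).
#' @param seed Integer seed.
#' @return A `roi_timeseries` with fewer volumes.
#' @export
scrub_volumes <- function(ts, fraction, seed = 1L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  t0 <- nrow(ts$data)
  n_drop <- as.integer(.round_half_away(fraction * t0))
  if (n_drop == 0L) {
    ts$scrub_fraction <- 0
    return(ts)
  }
  if (t0 - n_drop < 3L) stop("scrubbing would leave fewer than 3 volumes")
  drop <- .with_seed(seed, sample.int(t0, n_drop))
  ts$data <- ts$data[-drop, , drop = FALSE]
  ts$scrub_fraction <- n_drop / t0
  ts
}

#' Simulate a full cohort
#'
#' Draws ages uniformly within each group's range, builds each subject's
#' age-dependent covariance, simulates and scrubs the time series, and
#' generates cognition domain scores as `beta * trueSS + noise`, z-scored
#' against the cohort. Subjects whose drawn scrub fraction reaches 0.30 are
#' excluded (the study inclusion rule) and listed in the result. Fully
#' reproducible from the master seed.
#'
#' @param config A `simulation_config`.
#' @param roi_ids Optional integer vector labelling the simulated ROI
#'   columns, grouped by network in the config's network order (e.g. from
#'   [roi_ids_for_config()] to align with an atlas). Default `1..N`.
#' @return List with `timeseries` (list of `roi_timeseries`), `records`
#'   (data frame: subject_id, age, age_group, scrub_percent, scan_length,
#'   true_ss, VOCAB, SPEED, FLUID, MEM) and `excluded` (character vector of
#'   subject ids dropped by the scrub rule).
#' @export
simulate_cohort <- function(config, roi_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n_roi <- sum(config$network_sizes)
  if (is.null(roi_ids)) roi_ids <- seq_len(n_roi)
  stopifnot(length(roi_ids) == n_roi, !anyDuplicated(roi_ids))
  groups <- age_groups()
  n_tot <- config$n_per_group * length(groups)
  plan <- .with_seed(config$seed, {
    ages <- unlist(lapply(groups, function(g) {
      rg <- config$age_ranges[[g]]
      stats::runif(config$n_per_group, rg[1], rg[2])
    }))
    scrub <- pmin(pmax(config$scrub_base +
                         config$scrub_slope * (ages - 20) +
                         stats::rnorm(n_tot, 0, config$scrub_sd), 0), 0.45)
    cog_resid <- matrix(stats::rnorm(n_tot * length(config$cognition_beta),
                                     0, config$cognition_sd),
                        n_tot, length(config$cognition_beta))
    subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_tot)
    list(ages = ages, scrub = scrub, cog_resid = cog_resid,
         subject_seeds = subject_seeds)
  })
  ids <- sprintf("sub-%03d", seq_len(n_tot))
  scan_length <- ifelse(config$t_volumes >= 200L, "long", "short")
  # inclusion rule applies to the realized (volume-rounded) scrub fraction
  realized <- .round_half_away(plan$scrub * config$t_volumes) /
    config$t_volumes
  keep <- realized < 0.30
  ts_list <- vector("list", n_tot)
  names(ts_list) <- ids
  true_ss <- vapply(plan$ages, function(a) true_segregation(config, a),
                    numeric(1))
  for (i in which(keep)) {
    cv <- build_covariance(config, plan$ages[i])
    ts <- simulate_subject(cv, config$t_volumes,
                           seed = plan$subject_seeds[2 * i - 1],
                           subject_id = ids[i],
                           tr_seconds = config$tr_seconds)
    colnames(ts$data) <- as.character(roi_ids)
    ts_list[[i]] <- scrub_volumes(ts, plan$scrub[i],
                                  seed = plan$subject_seeds[2 * i])
  }
  cog_raw <- outer(true_ss, config$cognition_beta) + plan$cog_resid
  colnames(cog_raw) <- names(config$cognition_beta)
  cog_z <- scale(cog_raw[keep, , drop = FALSE])
  records <- data.frame(subject_id = ids[keep],
                        age = plan$ages[keep],
                        age_group = assign_age_group(plan$ages[keep]),
                        scrub_percent = 100 * vapply(ts_list[keep],
                          function(t) t$scrub_fraction, numeric(1)),
                        scan_length = scan_length,
                        true_ss = true_ss[keep])
  records <- cbind(records, as.data.frame(cog_z))
  rownames(records) <- NULL
  list(timeseries = ts_list[keep], records = records,
       excluded = ids[!keep])
}

#' ROI ids aligning a simulation config with an atlas
#'
#' For each network in the config's order, the atlas ROI ids carrying that
#' label (atlas order). Errors if per-network counts disagree.
#'
#' @param config A `simulation_config`.
#' @param atlas A `roi_atlas`.
#' @return Integer vector of ROI ids, grouped by network.
#' @export
roi_ids_for_config <- function(config, atlas) {
  stopifnot(inherits(config, "simulation_config"), inherits(atlas, "roi_atlas"))
  out <- integer(0)
  for (k in names(config$network_sizes)) {
    ids <- atlas$roi_id[atlas$network == k]
    if (length(ids) != config$network_sizes[[k]])
      stop(sprintf("atlas has %d '%s' ROIs but config expects %d",
                   length(ids), k, config$network_sizes[[k]]))
    out <- c(out, ids)
  }
  out
}

#' Network partition of the simulated columns
#'
#' Partition object matching a cohort simulated with [simulate_cohort()]:
#' networks in config order, ROI ids as supplied (default `1..N`).
#'
#' @param config A `simulation_config`.
#' @param roi_ids Optional ROI ids, as passed to [simulate_cohort()].
#' @return A `network_partition`.
#' @export
partition_from_config <- function(config, roi_ids = NULL) {
  n_roi <- sum(config$network_sizes)
  if (is.null(roi_ids)) roi_ids <- seq_len(n_roi)
  part <- list(roi_id = as.integer(roi_ids),
               network = rep(names(config$network_sizes),
                             times = config$network_sizes),
               networks = names(config$network_sizes),
               sizes = config$network_sizes)
  class(part) <- "network_partition"
  part
}
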