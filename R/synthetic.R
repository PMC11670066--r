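#' Parameters of the synthetic spawning-site generator
#'
#' Defaults emulate the studied site: a ~100 m x 60 m forereef plot of
#' ~210 mapped colonies with 26 focal gravid colonies, two consecutive
#' spawning nights, at least 200 eggs scored per sample, and colony-level
#' fertilization counts that are beta-binomial with a logit mean declining
#' linearly in nearest-gravid-neighbour distance (truth = the
#' [reference_fit()] coefficients). Release and extensive-spawning
#' probabilities follow the observed 74%/77% releasing and 35%/64%
#' extensive per night; gamete-damage probabilities keep a threefold
#' night-1 : night-2 ratio.
#'
#' @param site_extent `c(width, height)` in metres.
#' @param n_colonies Colonies on the map.
#' @param point_process `"uniform"` or `"clustered"` (parent-offspring
#'   clusters plus a uniformly scattered fraction).
#' @param n_parents,cluster_sd,scatter_frac Clustered-process settings:
#'   parent count, Gaussian offspring spread (m), fraction of colonies
#'   scattered uniformly instead of clustered.
#' @param gravid_prob Probability a colony is gravid.
#' @param n_focal Number of focal colonies sampled for fertilization.
#' @param beta0,beta_nn,beta_night2 True logit-scale coefficients.
#' @param phi True beta-binomial precision.
#' @param eggs_per_sample Eggs scored per colony-night sample.
#' @param synchrony_slope Target increase of expected pairwise spawn-time
#'   difference with distance (min m^-1); 0.15 = 3 min over 20 m.
#' @param time_sd Marginal SD of spawn times (minutes).
#' @param release_prob,extensive_prob Named per-night probabilities of any
#'   release and of extensive spawning (marginal over all colonies).
#' @param damage_prob Named per-night damage probabilities.
#' @param damage_scored Eggs scored for damage per eligible sample.
#' @param area_meanlog,area_sdlog Log-normal planar-area parameters
#'   (median 0.2 m^2 by default).
#' @return List of class `gen_params`.
#' @export
gen_params <- function(site_extent = c(100, 60), n_colonies = 210,
                       point_process = c("clustered", "uniform"),
                       n_parents = 8, cluster_sd = 2, scatter_frac = 0.15,
                       gravid_prob = 0.35, n_focal = 26,
                       beta0 = -0.849, beta_nn = -0.16, beta_night2 = -1.01,
                       phi = 8, eggs_per_sample = 200,
                       synchrony_slope = 0.15, time_sd = 15,
                       release_prob = c(n1 = 0.74, n2 = 0.77),
                       extensive_prob = c(n1 = 0.35, n2 = 0.64),
                       damage_prob = c(n1 = 0.30, n2 = 0.10),
                       damage_scored = 100,
                       area_meanlog = log(0.2), area_sdlog = 0.6) {
  point_process <- match.arg(point_process)
  stopifnot(all(site_extent > 0), phi > 0, time_sd >= 0,
            all(release_prob > 0 & release_prob < 1),
            all(extensive_prob > 0 & extensive_prob < 1),
            all(extensive_prob <= release_prob),
            all(damage_prob > 0 & damage_prob < 1))
  structure(as.list(environment()), class = "gen_params")
}

#' Generate a synthetic colony map
#'
#' Homogeneous random placement (`"uniform"`) or a parent-offspring cluster
#' process (`"clustered"`: parents placed uniformly, offspring displaced by
#' isotropic Gaussian noise and clipped to the site, plus a uniformly
#' scattered fraction). Planar areas are log-normal; gravidity is
#' independent Bernoulli; depth class splits the site at mid-height
#' (`shallow` inshore, `deeper` toward the drop-off).
#'
#' @param params A [gen_params()].
#' @param seed Optional integer seed.
#' @return A validated colony table.
#' @export
generate_colony_map <- function(params = gen_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_colonies
  W <- params$site_extent[1]; H <- params$site_extent[2]
  if (n == 0) {
    return(validate_colony_table(data.frame(
      colony_id = character(), x = numeric(), y = numeric(),
      planar_area = numeric(), gravid = logical(),
      depth_class = character(), stringsAsFactors = FALSE)))
  }
  if (params$point_process == "uniform") {
    x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
  } else {
    n_sc <- round(params$scatter_frac * n)
    n_cl <- n - n_sc
    px <- stats::runif(params$n_parents, 0, W)
    py <- stats::runif(params$n_parents, 0, H)
    pa <- sample.int(params$n_parents, n_cl, replace = TRUE)
    x <- c(px[pa] + stats::rnorm(n_cl, 0, params$cluster_sd),
           stats::runif(n_sc, 0, W))
    y <- c(py[pa] + stats::rnorm(n_cl, 0, params$cluster_sd),
           stats::runif(n_sc, 0, H))
    x <- pmin(pmax(x, 0), W); y <- pmin(pmax(y, 0), H)
  }
  validate_colony_table(data.frame(
    colony_id = sprintf("C%03d", seq_len(n)),
    x = x, y = y,
    planar_area = stats::rlnorm(n, params$area_meanlog, params$area_sdlog),
    gravid = stats::runif(n) < params$gravid_prob,
    depth_class = ifelse(y < H / 2, "shallow", "deeper"),
    stringsAsFactors = FALSE))
}

# least-squares slope of the expected pairwise |dt|-vs-distance relation
# for a Gaussian process with exponential correlation of range r and
# marginal sd sigma, over the supplied pair distances; if t_i, t_j are
# bivariate normal their difference has sd sigma*sqrt(2(1-rho)) and
# E|dt| = 2*sigma*sqrt((1-rho)/pi)
expected_dt_slope <- function(r, sigma, dd) {
  e <- 2 * sigma * sqrt((1 - exp(-dd / r)) / pi)
  stats::cov(dd, e) / stats::var(dd)
}

# correlation range giving the target least-squares synchrony slope over
# the site's actual pair-distance distribution; the steeper of the two
# matching ranges (or the best achievable if the target is out of reach)
calibrate_time_range <- function(sigma, slope_target, dd) {
  rs <- exp(seq(log(0.3), log(500), length.out = 200))
  slopes <- vapply(rs, expected_dt_slope, numeric(1), sigma = sigma, dd = dd)
  rs[which.min(abs(slopes - slope_target))]
}

#' Simulate a two-night spawn schedule
#'
#' Per night, each focal colony releases with the configured probability;
#' releasers are `extensive` or `partial` so the marginal extensive
#' probability matches the configuration. Release times are drawn from a
#' spatially correlated Gaussian process (exponential correlation, range
#' calibrated so the expected pairwise absolute time difference grows by
#' approximately `synchrony_slope` per metre over 0-20 m), discretised to
#' integer minutes with the earliest release as minute 1. Observers patrol
#' five spatial transects (blocks of the x axis).
#'
#' @param colonies Focal colony table (gravid colonies are scheduled).
#' @param params A [gen_params()].
#' @param seed Optional integer seed.
#' @return A validated spawn-event table with one row per colony-night,
#'   including `extent = "none"` rows for non-releasers.
#' @export
simulate_spawn_schedule <- function(colonies, params = gen_params(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  foc <- colonies[colonies$gravid, ]
  if (nrow(foc) < 2) stop("need at least two gravid colonies", call. = FALSE)
  m <- nrow(foc)
  obs <- paste0("obs", as.integer(cut(foc$x, breaks = stats::quantile(
    foc$x, probs = seq(0, 1, 0.2)), include.lowest = TRUE)))
  d <- as.matrix(stats::dist(cbind(foc$x, foc$y)))
  rng <- if (params$time_sd > 0)
    calibrate_time_range(params$time_sd, params$synchrony_slope,
                         d[upper.tri(d)]) else 1
  out <- list()
  for (ng in c("n1", "n2")) {
    released <- stats::runif(m) < params$release_prob[[ng]]
    extent <- rep("none", m)
    p_ext_given_rel <- params$extensive_prob[[ng]] / params$release_prob[[ng]]
    extent[released] <- ifelse(stats::runif(sum(released)) < p_ext_given_rel,
                               "extensive", "partial")
    minute <- rep(NA_integer_, m)
    if (any(released)) {
      if (params$time_sd == 0) {
        minute[released] <- 1L
      } else {
        i <- which(released)
        S <- params$time_sd^2 * exp(-d[i, i, drop = FALSE] / rng)
        diag(S) <- diag(S) + 1e-8
        t_raw <- drop(crossprod(chol(S), stats::rnorm(length(i))))
        minute[i] <- as.integer(round(t_raw - min(t_raw))) + 1L
      }
    }
    out[[ng]] <- data.frame(colony_id = foc$colony_id, night = ng,
                            release_minute = minute, extent = extent,
                            observer_id = obs, stringsAsFactors = FALSE)
  }
  validate_spawn_events(do.call(rbind, out))
}

#' Simulate fertilization and damage counts
#'
#' For each colony-night with a release, the mean fertilization proportion
#' is `plogis(beta0 + beta_nn * nn + beta_night2 * I(night 2))` and the
#' fertilized count is beta-binomial with precision `phi` out of
#' `eggs_per_sample` scored eggs. Colonies that spawned on both nights are
#' additionally scored for damage (binomial with per-night damage
#' probabilities); other samples carry zero damage-scored eggs.
#'
#' @param colonies Focal colony table.
#' @param metrics [compute_all_metrics()] table covering the spawners.
#' @param events Spawn-event table; `NULL` means every colony in `metrics`
#'   is sampled on both nights (the balanced design used in
#'   parameter-recovery experiments).
#' @param params A [gen_params()].
#' @param seed Optional integer seed.
#' @return A validated fertilization-sample table.
#' @export
simulate_fertilization <- function(colonies, metrics, events = NULL,
                                   params = gen_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) {
    ids <- metrics$colony_id
    sampled <- data.frame(colony_id = rep(ids, 2),
                          night = rep(c("n1", "n2"), each = length(ids)),
                          stringsAsFactors = FALSE)
  } else {
    rel <- !is.na(events$extent) & events$extent != "none"
    sampled <- events[rel, c("colony_id", "night")]
  }
  idx <- match(sampled$colony_id, metrics$colony_id)
  if (anyNA(idx))
    stop("metrics missing for spawning colony ",
         sampled$colony_id[which(is.na(idx))[1]], call. = FALSE)
  nn <- metrics$nn_m[idx]
  mu <- stats::plogis(params$beta0 + params$beta_nn * nn +
                        params$beta_night2 * (sampled$night == "n2"))
  nr <- nrow(sampled)
  p <- stats::rbeta(nr, mu * params$phi, (1 - mu) * params$phi)
  k <- stats::rbinom(nr, params$eggs_per_sample, p)
  both <- names(which(table(sampled$colony_id) == 2))
  dsc <- ifelse(sampled$colony_id %in% both, params$damage_scored, 0L)
  dmg <- stats::rbinom(nr, dsc,
                       unname(params$damage_prob[sampled$night]))
  validate_fert_samples(data.frame(
    colony_id = sampled$colony_id, night = sampled$night,
    n_scored = params$eggs_per_sample, n_fertilized = k,
    n_damage_scored = as.integer(dsc), n_damaged = as.integer(dmg),
    dispersal_group = ifelse(sampled$night == "n2", "offshore",
                             ifelse(colonies$y[match(sampled$colony_id,
                                                     colonies$colony_id)] <
                                      params$site_extent[2] / 2,
                                    "reef_flat", "forereef_edge")),
    stringsAsFactors = FALSE))
}

#' One deterministic study-shaped input bundle
#'
#' Generates a clustered colony map, selects 26 gravid focal colonies whose
#' nearest-gravid-neighbour distances are nudged into the observed 0.2-19 m
#' envelope (too-close pairs are pushed apart, over-isolated colonies are
#' pulled toward their nearest gravid neighbour), simulates the two-night
#' spawn schedule and the fertilization samples, and returns everything the
#' pipeline consumes.
#'
#' @param seed Integer seed; the same seed always yields the same bundle.
#' @param params A [gen_params()].
#' @return List of class `study_fixture`: `colonies`, `focal_ids`,
#'   `events`, `samples`, `metrics`, `params`.
#' @export
make_study_fixture <- function(seed = 42L, params = gen_params()) {
  set.seed(seed)
  colonies <- generate_colony_map(params)
  colonies <- enforce_nn_envelope(colonies, lo = 0.2, hi = 19,
                                  extent = params$site_extent)
  grav <- which(colonies$gravid)
  focal_ids <- colonies$colony_id[sample(grav, min(params$n_focal,
                                                   length(grav)))]
  events_all <- simulate_spawn_schedule(colonies, params)
  events <- events_all[events_all$colony_id %in% focal_ids, ]
  rownames(events) <- NULL
  cfg <- run_config()
  metrics <- compute_all_metrics(focal_ids, colonies, cfg)
  samples <- simulate_fertilization(colonies, metrics,
                                    events = events, params = params)
  structure(list(colonies = colonies, focal_ids = focal_ids,
                 events = validate_spawn_events(events),
                 samples = samples, metrics = metrics, params = params),
            class = "study_fixture")
}

# push gravid colonies apart to a minimum separation and pull isolated ones
# inside a maximum nearest-neighbour distance; deterministic given the map
enforce_nn_envelope <- function(colonies, lo = 0.2, hi = 19,
                                extent = c(100, 60), max_iter = 20) {
  for (iter in seq_len(max_iter)) {
    g <- which(colonies$gravid)
    if (length(g) < 2) break
    d <- as.matrix(stats::dist(cbind(colonies$x[g], colonies$y[g])))
    diag(d) <- Inf
    moved <- FALSE
    close <- which(d < lo, arr.ind = TRUE)
    close <- close[close[, 1] < close[, 2], , drop = FALSE]
    for (r in seq_len(nrow(close))) {
      i <- g[close[r, 1]]; j <- g[close[r, 2]]
      v <- c(colonies$x[j] - colonies$x[i], colonies$y[j] - colonies$y[i])
      nv <- sqrt(sum(v^2))
      u <- if (nv < 1e-9) c(1, 0) else v / nv
      shift <- (lo * 1.05 - nv) * u
      colonies$x[j] <- min(max(colonies$x[j] + shift[1], 0), extent[1])
      colonies$y[j] <- min(max(colonies$y[j] + shift[2], 0), extent[2])
      moved <- TRUE
    }
    nnv <- apply(d, 1, min)
    far <- which(nnv > hi)
    for (r in far) {
      i <- g[r]; j <- g[which.min(d[r, ])]
      w <- (hi * 0.9) / nnv[r]
      colonies$x[i] <- colonies$x[j] + w * (colonies$x[i] - colonies$x[j])
      colonies$y[i] <- colonies$y[j] + w * (colonies$y[i] - colonies$y[j])
      moved <- TRUE
    }
    if (!moved) break
  }
  colonies
}

#' Write a study fixture's tables to CSV
#'
#' @param fixture A [make_study_fixture()] bundle.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_study_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(colonies = file.path(dir, "colonies.csv"),
             events = file.path(dir, "spawn_events.csv"),
             samples = file.path(dir, "fert_samples.csv"))
  write_colony_table(fixture$colonies, paths["colonies"])
  write_spawn_events(fixture$events, paths["events"])
  write_fert_samples(fixture$samples, paths["samples"])
  truth <- fixture$params[c("beta0", "beta_nn", "beta_night2", "phi",
                            "synchrony_slope")]
  writeLines(paste(names(truth), unlist(truth), sep = ","),
             file.path(dir, "truth.csv"))
  invisible(paths)
}
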