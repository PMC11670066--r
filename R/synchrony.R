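#' Build same-night colony pairs for the synchrony analysis
#'
#' For each night, forms every unordered pair of colonies that released
#' gametes that night, recording the absolute difference in release minute
#' (`abs_dt_min`), the intercolony distance and whether both times were
#' recorded by the same observer. Output is independent of the ordering of
#' the input events (pairs are listed with `colony_a < colony_b`).
#'
#' @param events Spawn-event table; a colony "spawned" a night when its
#'   `release_minute` is recorded and its extent is not `"none"`.
#' @param dists [pairwise_distances()] matrix covering every spawning
#'   colony.
#' @return A `data.frame` of class `synchrony_pairs` with columns
#'   `colony_a`, `colony_b`, `night`, `abs_dt_min`, `distance_m`,
#'   `same_observer`, `t_a`, `t_b`.
#' @export
build_pairs <- function(events, dists) {
  sp <- events[!is.na(events$release_minute) &
                 (is.na(events$extent) | events$extent != "none"), ]
  missing <- setdiff(sp$colony_id, rownames(dists))
  if (length(missing))
    stop("event colony missing from map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (ng in sort(unique(sp$night))) {
    e <- sp[sp$night == ng, ]
    e <- e[order(e$colony_id), ]
    m <- nrow(e)
    if (m < 2) next
    ij <- utils::combn(m, 2)
    ia <- ij[1, ]; ib <- ij[2, ]
    out[[ng]] <- data.frame(
      colony_a = e$colony_id[ia],
      colony_b = e$colony_id[ib],
      night = ng,
      abs_dt_min = abs(e$release_minute[ia] - e$release_minute[ib]),
      distance_m = dists[cbind(e$colony_id[ia], e$colony_id[ib])],
      same_observer = e$observer_id[ia] == e$observer_id[ib],
      t_a = e$release_minute[ia],
      t_b = e$release_minute[ib],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    stop("need at least two spawning colonies on some night", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("synchrony_pairs", "data.frame")
  out
}

#' Regress pairwise spawn-time differences on intercolony distance
#'
#' Fits the linear model `abs_dt ~ distance + same_observer (+ night)` on
#' the pooled pair table (nights pooled with a night indicator; per-night
#' slopes are also reported). Pairs sharing a colony are not independent,
#' so alongside the naive least-squares p-value a permutation p-value is
#' computed for the distance slope by shuffling spawn times across colonies
#' *within* each night and recomputing the partial slope; both are
#' reported, clearly labelled.
#'
#' The permutation statistic is the exact least-squares partial slope of
#' distance: distance is residualised on the remaining covariates once
#' (these do not change under time permutation), so each permutation is a
#' single inner product.
#'
#' @param pairs A [build_pairs()] table.
#' @param n_perm Number of permutations.
#' @param seed Integer seed making the permutations reproducible.
#' @return List of class `synchrony_fit`: `slope` (min m^-1), `se`,
#'   `naive_p`, `perm_p`, `coefficients`, `per_night`, `n_pairs`, `note`.
#' @export
fit_synchrony_model <- function(pairs, n_perm = 9999L, seed = 1L) {
  stopifnot(nrow(pairs) >= 3)
  note <- character()
  if (length(unique(pairs$abs_dt_min)) == 1) {
    return(structure(list(slope = 0, se = NA_real_, naive_p = NA_real_,
                          perm_p = NA_real_, coefficients = NULL,
                          per_night = NULL, n_pairs = nrow(pairs),
                          note = "degenerate: all time differences equal"),
                     class = "synchrony_fit"))
  }
  X <- cbind(`(Intercept)` = 1, distance = pairs$distance_m)
  if (length(unique(pairs$same_observer)) > 1) {
    X <- cbind(X, same_observer = as.numeric(pairs$same_observer))
  } else {
    note <- c(note, "observer term dropped: constant across pairs")
  }
  if (length(unique(pairs$night)) > 1)
    X <- cbind(X, night2 = as.numeric(pairs$night == "n2"))
  y <- pairs$abs_dt_min
  lmfit <- stats::lm.fit(X, y)
  beta <- lmfit$coefficients
  rdf <- lmfit$df.residual
  sigma2 <- sum(lmfit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), rdf)

  # permutation p for the distance slope, shuffling times within night
  other <- X[, setdiff(colnames(X), "distance"), drop = FALSE]
  rd <- stats::lm.fit(other, X[, "distance"])$residuals
  denom <- sum(rd^2)
  obs_stat <- sum(rd * y) / denom
  set.seed(seed)
  nights <- unique(pairs$night)
  acc <- matrix(0, n_perm, nrow(pairs))
  for (ng in nights) {
    i <- which(pairs$night == ng)
    ids <- sort(unique(c(pairs$colony_a[i], pairs$colony_b[i])))
    tt <- stats::setNames(numeric(length(ids)), ids)
    tt[pairs$colony_a[i]] <- pairs$t_a[i]
    tt[pairs$colony_b[i]] <- pairs$t_b[i]
    ia <- match(pairs$colony_a[i], ids)
    ib <- match(pairs$colony_b[i], ids)
    Tm <- matrix(0, n_perm, length(ids))
    for (r in seq_len(n_perm)) Tm[r, ] <- sample(tt)
    acc[, i] <- abs(Tm[, ia, drop = FALSE] - Tm[, ib, drop = FALSE])
  }
  perm_stats <- drop(acc %*% rd) / denom
  perm_p <- (1 + sum(abs(perm_stats) >= abs(obs_stat) - 1e-12)) / (n_perm + 1)

  per_night <- do.call(rbind, lapply(nights, function(ng) {
    pn <- pairs[pairs$night == ng, ]
    if (nrow(pn) < 3 || stats::var(pn$distance_m) == 0)
      return(data.frame(night = ng, slope = NA_real_, se = NA_real_,
                        p = NA_real_))
    f <- summary(stats::lm(abs_dt_min ~ distance_m, data = pn))
    data.frame(night = ng, slope = f$coefficients[2, 1],
               se = f$coefficients[2, 2], p = f$coefficients[2, 4])
  }))

  structure(list(slope = unname(beta["distance"]),
                 se = unname(se["distance"]),
                 naive_p = unname(pval["distance"]),
                 perm_p = perm_p,
                 coefficients = cbind(estimate = beta, se = se, p = pval),
                 per_night = per_night,
                 n_pairs = nrow(pairs),
                 n_perm = n_perm,
                 note = note),
            class = "synchrony_fit")
}

#' @export
print.synchrony_fit <- function(x, ...) {
  cat("spawning-synchrony regression on", x$n_pairs, "colony pairs\n")
  cat(sprintf("distance slope: %.4f min/m (SE %.4f)\n", x$slope, x$se))
  cat(sprintf("naive LS p: %.4g; within-night permutation p: %.4g\n",
              x$naive_p, x$perm_p))
  if (length(x$note)) cat("note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Compare spawning intensity between nights
#'
#' Summarises, per night, the proportion of assessed colonies that released
#' at all and the proportion that spawned extensively, and tests the night
#' effect on extensive spawning with a binomial regression
#' ([fit_binomial_glm()]). Colonies whose extent was not reliably observed
#' (`NA`) are excluded.
#'
#' @param events Spawn-event table.
#' @return List of class `intensity_summary`: `table` (per-night counts and
#'   proportions), `fit`, `p_value` (Wald p for the night effect),
#'   `night_effect` (log-odds of extensive spawning, night 2 vs night 1).
#' @export
compare_spawning_intensity <- function(events) {
  e <- events[!is.na(events$extent), ]
  nights <- sort(unique(events$night))
  tab <- do.call(rbind, lapply(nights, function(ng) {
    en <- e[e$night == ng, ]
    if (nrow(en) == 0)
      stop("no colonies with assessed spawning extent on night ", ng,
           call. = FALSE)
    data.frame(night = ng,
               n_assessed = nrow(en),
               n_released = sum(en$extent != "none"),
               n_extensive = sum(en$extent == "extensive"),
               prop_released = mean(en$extent != "none"),
               prop_extensive = mean(en$extent == "extensive"))
  }))
  X <- cbind(`(Intercept)` = 1, night2 = as.numeric(tab$night == "n2"))
  fit <- fit_binomial_glm(X, k = tab$n_extensive, n = tab$n_assessed)
  structure(list(table = tab, fit = fit,
                 night_effect = unname(fit$coefficients["night2"]),
                 p_value = unname(fit$p_values["night2"])),
            class = "intensity_summary")
}

#' Compare gamete-damage probability between nights
#'
#' Binomial regression of damaged counts out of damage-scored eggs on the
#' night indicator, for the subset of samples scored for damage.
#'
#' @param samples Fertilization-sample table with `n_damage_scored` > 0 for
#'   at least one sample each night.
#' @return List: `fit`, `odds_ratio` (night 1 vs night 2 damage odds),
#'   `p_value`.
#' @export
compare_damage <- function(samples) {
  s <- samples[samples$n_damage_scored > 0, ]
  if (!all(c("n1", "n2") %in% s$night))
    stop("damage scored on fewer than two nights", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, night2 = as.numeric(s$night == "n2"))
  fit <- fit_binomial_glm(X, k = s$n_damaged, n = s$n_damage_scored)
  list(fit = fit,
       odds_ratio_n1_vs_n2 = unname(exp(-fit$coefficients["night2"])),
       p_value = unname(fit$p_values["night2"]))
}
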