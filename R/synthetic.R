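#' Planted guild structure for the simulator
#'
#' Describes the latent correlation blocks ("guilds") planted into synthetic
#' cohorts. OTUs inside a guild share a latent Gaussian correlation that may
#' differ between case and control; everything else shares the background
#' correlation. A per-guild additive shift of the latent (log-scale) mean in
#' cases plants a group-level abundance difference.
#'
#' @param sizes integer vector, number of OTUs per guild (each >= 2).
#' @param rho_intra_case,rho_intra_control within-guild latent correlation
#'   per condition (recycled across guilds), each in (-1, 1).
#' @param rho_inter background latent correlation between all other pairs.
#' @param abundance_log_shift per-guild additive shift of the latent mean in
#'   cases relative to controls (recycled).
#' @return a `guild_spec` object.
#' @export
guild_spec <- function(sizes, rho_intra_case = 0.7,
                       rho_intra_control = rho_intra_case,
                       rho_inter = 0, abundance_log_shift = 0) {
  stopifnot(length(sizes) >= 1, all(sizes >= 2), all(sizes == round(sizes)))
  g <- length(sizes)
  rho_intra_case <- rep_len(rho_intra_case, g)
  rho_intra_control <- rep_len(rho_intra_control, g)
  abundance_log_shift <- rep_len(abundance_log_shift, g)
  stopifnot(all(abs(rho_intra_case) < 1), all(abs(rho_intra_control) < 1),
            abs(rho_inter) < 1)
  structure(list(sizes = as.integer(sizes), rho_intra_case = rho_intra_case,
                 rho_intra_control = rho_intra_control, rho_inter = rho_inter,
                 abundance_log_shift = abundance_log_shift),
            class = "guild_spec")
}

#' Synthetic cohort composition
#'
#' Sample sizes, sequencing-depth model and seed for [generate_cohort()].
#' Defaults state the simulated world once: negative-binomial depths with
#' mean 30,000 (so the 10,000-read depth filter is occasionally exercised)
#' and grey-zone mixing coefficients drawn from (0.25, 0.75).
#'
#' @param n_case,n_control,n_grey sample counts per state.
#' @param n_noise_otus number of background OTUs outside any guild.
#' @param depth_mean,depth_dispersion negative-binomial read-depth
#'   parameters (mean and size).
#' @param grey_lambda_range interval within (0, 1) for the case-weight
#'   lambda of grey (transitional) samples.
#' @param seed master seed; all randomness flows from it.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_case, n_control, n_grey = 0, n_noise_otus = 50,
                        depth_mean = 30000, depth_dispersion = 10,
                        grey_lambda_range = c(0.25, 0.75), seed = 1) {
  stopifnot(n_case >= 0, n_control >= 0, n_grey >= 0, n_noise_otus >= 0,
            depth_mean > 0, depth_dispersion > 0,
            length(grey_lambda_range) == 2,
            grey_lambda_range[1] > 0, grey_lambda_range[2] < 1,
            grey_lambda_range[1] <= grey_lambda_range[2])
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 n_grey = as.integer(n_grey), n_noise_otus = as.integer(n_noise_otus),
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 grey_lambda_range = grey_lambda_range, seed = seed),
            class = "cohort_spec")
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

# Latent Gaussian model implied by (guilds, cohort): means per condition,
# block covariances, Cholesky factors, OTU ids and membership. The baseline
# mean vector is drawn under a seed derived from the cohort seed, so the
# model is identical across generate_cohort / implied_odds_ratio calls.
latent_model <- function(guilds, cohort) {
  stopifnot(inherits(guilds, "guild_spec"), inherits(cohort, "cohort_spec"))
  k_guild <- sum(guilds$sizes)
  k <- k_guild + cohort$n_noise_otus
  otu_ids <- sprintf("OTU_%04d", seq_len(k))
  membership <- rep("noise", k)
  idx <- 0L
  blocks <- vector("list", length(guilds$sizes))
  for (g in seq_along(guilds$sizes)) {
    blocks[[g]] <- idx + seq_len(guilds$sizes[g])
    membership[blocks[[g]]] <- paste0("guild_", g)
    idx <- idx + guilds$sizes[g]
  }
  names(membership) <- otu_ids

  base_mu <- with_seed(derive_seed(cohort$seed, 101), rnorm(k, 0, 1.2))
  mu_control <- base_mu
  mu_case <- base_mu
  for (g in seq_along(blocks))
    mu_case[blocks[[g]]] <- mu_case[blocks[[g]]] + guilds$abundance_log_shift[g]

  make_sigma <- function(rho_intra) {
    s <- matrix(guilds$rho_inter, k, k)
    for (g in seq_along(blocks))
      s[blocks[[g]], blocks[[g]]] <- rho_intra[g]
    diag(s) <- 1
    s
  }
  sigma_case <- make_sigma(guilds$rho_intra_case)
  sigma_control <- make_sigma(guilds$rho_intra_control)
  chol_or_die <- function(s, lab) {
    tryCatch(chol(s), error = function(e)
      abort("latent covariance (", lab, ") is not positive definite"))
  }
  list(k = k, otu_ids = otu_ids, membership = membership, blocks = blocks,
       mu_case = mu_case, mu_control = mu_control,
       sigma_case = sigma_case, sigma_control = sigma_control,
       chol_case = chol_or_die(sigma_case, "case"),
       chol_control = chol_or_die(sigma_control, "control"))
}

# Latent draws -> composition -> multinomial counts at NB depth.
draw_counts <- function(z, depth) {
  p <- softmax_rows(z)
  k <- ncol(p)
  counts <- t(vapply(seq_len(nrow(p)),
                     function(i) rmultinom(1L, depth[i], p[i, ])[, 1L],
                     integer(k)))
  counts
}

#' Generate a synthetic case/control cohort with planted guilds
#'
#' Latent Gaussian vectors are drawn from a block covariance (blocks =
#' guilds, within-block correlation per condition), mapped to a composition
#' by softmax, and converted to counts by a multinomial draw at a
#' negative-binomial sequencing depth. Grey (transitional) samples mix the
#' case and control latent means with a per-sample weight
#' `lambda ~ Uniform(grey_lambda_range)`; their clinical label is drawn
#' `Bernoulli(lambda)`, emulating the clinically mixed grey zone. The same
#' seed always yields byte-identical output.
#'
#' @param guilds a [guild_spec()].
#' @param cohort a [cohort_spec()].
#' @return a list with elements `table` ([otu_table()]), `metadata`
#'   (data frame: sample_id, condition, cohort, timepoint) and `truth`
#'   (list: `membership`, `sample_state`, `lambda`, `planted_or`).
#' @export
generate_cohort <- function(guilds, cohort) {
  model <- latent_model(guilds, cohort)
  n_all <- cohort$n_case + cohort$n_control + cohort$n_grey
  if (n_all == 0L) abort("cohort has no samples")

  out <- with_seed(derive_seed(cohort$seed, 202), {
    ids <- c(sprintf("CASE_%04d", seq_len(cohort$n_case)),
             sprintf("CTRL_%04d", seq_len(cohort$n_control)),
             sprintf("GREY_%04d", seq_len(cohort$n_grey)))
    state <- rep(c("case", "control", "grey"),
                 c(cohort$n_case, cohort$n_control, cohort$n_grey))
    depth <- pmax(1L, rnbinom(n_all, size = cohort$depth_dispersion,
                              mu = cohort$depth_mean))
    z <- matrix(0, n_all, model$k)
    n_cc <- cohort$n_case + cohort$n_control
    if (cohort$n_case > 0) {
      e <- matrix(rnorm(cohort$n_case * model$k), cohort$n_case)
      z[seq_len(cohort$n_case), ] <- sweep(e %*% model$chol_case, 2L,
                                           model$mu_case, "+")
    }
    if (cohort$n_control > 0) {
      e <- matrix(rnorm(cohort$n_control * model$k), cohort$n_control)
      z[cohort$n_case + seq_len(cohort$n_control), ] <-
        sweep(e %*% model$chol_control, 2L, model$mu_control, "+")
    }
    lambda <- rep(NA_real_, n_all)
    label <- state
    if (cohort$n_grey > 0) {
      lam <- runif(cohort$n_grey, cohort$grey_lambda_range[1],
                   cohort$grey_lambda_range[2])
      lambda[n_cc + seq_len(cohort$n_grey)] <- lam
      same_sigma <- isTRUE(all.equal(model$sigma_case, model$sigma_control))
      for (j in seq_len(cohort$n_grey)) {
        mu_j <- lam[j] * model$mu_case + (1 - lam[j]) * model$mu_control
        ch <- if (same_sigma) model$chol_case else
          chol(lam[j] * model$sigma_case + (1 - lam[j]) * model$sigma_control)
        z[n_cc + j, ] <- mu_j + rnorm(model$k) %*% ch
      }
      label[n_cc + seq_len(cohort$n_grey)] <-
        ifelse(rbinom(cohort$n_grey, 1L, lam) == 1L, "case", "control")
    }
    counts <- draw_counts(z, depth)
    dimnames(counts) <- list(ids, model$otu_ids)
    list(ids = ids, state = state, label = label, lambda = lambda,
         counts = counts)
  })

  planted_or <- if (any(guilds$abundance_log_shift != 0))
    implied_odds_ratio(guilds, cohort) else 1
  metadata <- data.frame(sample_id = out$ids, condition = out$label,
                         cohort = "synthetic", timepoint = NA_character_,
                         stringsAsFactors = FALSE)
  truth <- list(membership = model$membership,
                sample_state = setNames(out$state, out$ids),
                lambda = setNames(out$lambda, out$ids),
                planted_or = planted_or)
  list(table = otu_table(out$counts), metadata = metadata, truth = truth)
}

#' Generate only the grey (transitional) samples of a cohort
#'
#' Convenience wrapper around [generate_cohort()] for the transitional
#' state: latent means are `lambda * mu_case + (1 - lambda) * mu_control`.
#'
#' @inheritParams generate_cohort
#' @return same structure as [generate_cohort()], grey samples only.
#' @export
generate_grey_samples <- function(guilds, cohort) {
  if (cohort$n_grey <= 0) abort("`n_grey` must be positive")
  cohort$n_case <- 0L
  cohort$n_control <- 0L
  generate_cohort(guilds, cohort)
}

# Monte-Carlo median-split odds ratio of a guild's relative abundance under
# the latent model, with common random numbers across shift values so that
# calibrate_guild_shift can root-find smoothly.
mc_median_split_or <- function(e_case, e_control, chols, members) {
  g_of <- function(e, chol_m, mu) {
    z <- sweep(e %*% chol_m, 2L, mu, "+")
    rowSums(softmax_rows(z)[, members, drop = FALSE])
  }
  function(mu_case, mu_control) {
    gc <- g_of(e_case, chols$case, mu_case)
    gn <- g_of(e_control, chols$control, mu_control)
    m <- median(c(gc, gn))
    p1 <- mean(gc > m); p0 <- mean(gn > m)
    (p1 * (1 - p0)) / (p0 * (1 - p1))
  }
}

#' Odds ratio implied by the planted abundance shift
#'
#' Monte-Carlo estimate of the case/control odds ratio obtained when the
#' guild's relative abundance is dichotomized at the pooled median, under
#' the latent (pre-sequencing) model. This is the ground-truth `planted_or`
#' recorded by [generate_cohort()].
#'
#' @inheritParams generate_cohort
#' @param guild index of the guild (default: largest absolute shift).
#' @param n_sim Monte-Carlo draws per arm.
#' @param seed RNG seed (default derived from the cohort seed).
#' @return a single odds ratio.
#' @export
implied_odds_ratio <- function(guilds, cohort, guild = NULL, n_sim = 4000,
                               seed = NULL) {
  model <- latent_model(guilds, cohort)
  if (is.null(guild)) guild <- which.max(abs(guilds$abundance_log_shift))
  members <- model$blocks[[guild]]
  if (is.null(seed)) seed <- derive_seed(cohort$seed, 303)
  with_seed(seed, {
    e_case <- matrix(rnorm(n_sim * model$k), n_sim)
    e_control <- matrix(rnorm(n_sim * model$k), n_sim)
    or_fun <- mc_median_split_or(e_case, e_control,
                                 list(case = model$chol_case,
                                      control = model$chol_control), members)
    or_fun(model$mu_case, model$mu_control)
  })
}

#' Calibrate the latent shift for a target planted odds ratio
#'
#' Root-finds the per-guild latent mean shift whose implied median-split
#' odds ratio (see [implied_odds_ratio()]) equals `target_or`, using common
#' random numbers so the objective is smooth in the shift.
#'
#' @inheritParams implied_odds_ratio
#' @param target_or desired odds ratio (> 1).
#' @return the input `guild_spec` with `abundance_log_shift[guild]` set.
#' @export
calibrate_guild_shift <- function(guilds, cohort, target_or, guild = 1,
                                  n_sim = 8000, seed = NULL) {
  stopifnot(target_or > 1)
  if (is.null(seed)) seed <- derive_seed(cohort$seed, 404)
  base <- guilds
  base$abundance_log_shift[guild] <- 0
  model <- latent_model(base, cohort)
  members <- model$blocks[[guild]]
  or_fun <- with_seed(seed, {
    e_case <- matrix(rnorm(n_sim * model$k), n_sim)
    e_control <- matrix(rnorm(n_sim * model$k), n_sim)
    mc_median_split_or(e_case, e_control,
                       list(case = model$chol_case, control = model$chol_control),
                       members)
  })
  objective <- function(delta) {
    mu_case <- model$mu_control
    mu_case[members] <- mu_case[members] + delta
    log(or_fun(mu_case, model$mu_control)) - log(target_or)
  }
  delta <- uniroot(objective, c(0.01, 3), extendInt = "upX", tol = 1e-4)$root
  guilds$abundance_log_shift[guild] <- delta
  guilds
}

#' Generate offspring tables vertically coupled to maternal samples
#'
#' Each offspring's latent profile is a convex combination of the maternal
#' latent profile (approximated by the CLR of maternal counts; softmax of a
#' CLR vector recovers the maternal composition) and an independent draw
#' from the control-state latent model, so `transmission_weight = 1`
#' reproduces the maternal composition (up to multinomial resampling) and
#' `transmission_weight = 0` is an independent cohort.
#'
#' @param maternal an [otu_table()] whose OTUs match the latent model of
#'   (`guilds`, `cohort`).
#' @inheritParams generate_cohort
#' @param transmission_weight fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return an `otu_table` of offspring counts (ids prefixed `OFF_`).
#' @export
generate_paired_offspring <- function(maternal, guilds, cohort,
                                      transmission_weight, seed = 1) {
  stopifnot(inherits(maternal, "otu_table"),
            transmission_weight >= 0, transmission_weight <= 1)
  model <- latent_model(guilds, cohort)
  if (!identical(otu_ids(maternal), model$otu_ids))
    abort("maternal table OTUs do not match the latent model of (guilds, cohort)")
  z_m <- clr_transform(maternal)
  n <- nrow(z_m)
  with_seed(seed, {
    e <- matrix(rnorm(n * model$k), n)
    z_new <- sweep(e %*% model$chol_control, 2L, model$mu_control, "+")
    z_off <- transmission_weight * z_m + (1 - transmission_weight) * z_new
    depth <- pmax(1L, rnbinom(n, size = cohort$depth_dispersion,
                              mu = cohort$depth_mean))
    counts <- draw_counts(z_off, depth)
    dimnames(counts) <- list(paste0("OFF_", sample_ids(maternal)), model$otu_ids)
    otu_table(counts)
  })
}

#' Build a guild partition from a ground-truth membership map
#'
#' Utility to evaluate downstream operations (e.g. [guild_abundance()])
#' against the simulator's planted membership.
#'
#' @param membership named vector (OTU id -> guild label); entries equal to
#'   `"noise"` are dropped.
#' @return a `guild_partition`.
#' @export
partition_from_membership <- function(membership) {
  keep <- membership != "noise"
  labs <- membership[keep]
  lev <- names(sort(table(labs), decreasing = TRUE))
  assignment <- setNames(match(labs, lev) - 1L, names(labs))
  new_guild_partition(assignment, algorithm = "ground_truth", seed = NA,
                      resolution = NA, modularity = NA_real_)
}
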