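# Default rest-phase baselines and stress responses for the simulated
# sheep physiology. rest_mean/rest_sd are cross-animal at 07:00; delta is
# the mean rest-to-stress change for an average animal (latent score 0).
# The 2*rest_sd/delta ratios are deliberately staggered (0.25 .. 1.75) so
# the five AHTI flags trip at evenly spread values of the latent
# heat-response score, keeping the 0-5 score close to linear in it.
.physio_defaults <- data.frame(
  param = c("RT", "ET", "RR", "TV", "MR"),
  rest_mean = c(39.0, 36.0, 40.0, 0.25, 140.0),
  rest_sd = c(0.35, 0.60, 8.00, 0.03, 10.0),
  delta = c(1.12, 1.20, 64.0, -0.0436, 11.43),
  stringsAsFactors = FALSE
)

# Nominal AHTI change per unit of the latent heat-response score, implied
# by the staggered flag thresholds; converts user-facing causal effects
# (AHTI units per Alt allele) into latent-score shifts.
.ahti_slope <- 2.5

# SD of the latent heat-response score s in the simulated cohort.
.latent_sd <- 0.5

#' Simulate admixed genotypes under the Balding-Nichols model
#'
#' Draws, per marker, an ancestral Alt frequency `p0 ~ U(0.05, 0.95)` and
#' K population frequencies from the Balding-Nichols Beta distribution
#' with drift parameter `fst_target`; ancestry proportions are Dirichlet,
#' each individual's Alt frequency is `q = sum_k Q_ik F_kj`, and dosages
#' are Binomial(2, q). Entries are masked missing independently. Breed
#' and location labels are the argmax-ancestry component. Markers are
#' placed on `n_chrom` chromosomes at regular spacing so positional steps
#' (LD windows, gene mapping) are exercised downstream.
#'
#' @param n_samples,n_markers Cohort dimensions (>= 2 each).
#' @param K Number of ancestral populations (>= 1).
#' @param fst_target Balding-Nichols drift parameter in (0, 1).
#' @param alpha Dirichlet concentration (scalar or length-K); small values
#'   give unadmixed individuals.
#' @param missing_rate Fraction of calls masked missing, in [0, 1).
#' @param seed Integer seed; all randomness derives from it.
#' @param n_chrom Number of chromosomes to spread markers over.
#' @return List with `geno` (a [genotype_matrix()]) and `truth` (class
#'   `synthetic_truth`): `Q_true`, `F_true`, `fst_target`, `alpha`,
#'   `seed`, plus `causal_markers`/`h2` slots filled by
#'   [simulate_physiology()].
#' @export
simulate_admixed_genotypes <- function(n_samples, n_markers, K = 3L,
                                       fst_target = 0.05, alpha = 0.2,
                                       missing_rate = 0.02, seed = 1L,
                                       n_chrom = 5L) {
  if (n_samples < 2L || n_markers < 2L) stop_validation("need n_samples >= 2 and n_markers >= 2")
  if (K < 1L) stop_validation("K must be >= 1")
  assert_scalar_number(fst_target, "fst_target", 1e-6, 1 - 1e-6)
  assert_scalar_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(alpha) != K || any(alpha <= 0)) {
    stop_validation("alpha must be positive, scalar or length K")
  }

  withr::with_seed(seed, {
    p0 <- stats::runif(n_markers, 0.05, 0.95)
    Fdrift <- fst_target
    F_true <- matrix(0, K, n_markers)
    if (K == 1L) {
      F_true[1L, ] <- p0
    } else {
      for (k in seq_len(K)) {
        F_true[k, ] <- stats::rbeta(n_markers,
                                    p0 * (1 - Fdrift) / Fdrift,
                                    (1 - p0) * (1 - Fdrift) / Fdrift)
      }
    }
    gam <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  n_samples, K)
    Q_true <- gam / rowSums(gam)
    q_ind <- Q_true %*% F_true
    calls <- matrix(stats::rbinom(n_samples * n_markers, 2L, as.vector(q_ind)),
                    n_samples, n_markers)
    if (missing_rate > 0) {
      calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
    }
  })

  pop <- max.col(Q_true, ties.method = "first")
  marker_ids <- sprintf("snp%05d", seq_len(n_markers))
  # Contiguous chromosome blocks, so the map is already position-sorted.
  chrom <- as.character(sort(rep_len(seq_len(n_chrom), n_markers)))
  pos <- integer(n_markers)
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    pos[sel] <- seq(10000L, by = 25000L, length.out = sum(sel))
  }
  geno <- genotype_matrix(
    calls,
    map = data.frame(marker_id = marker_ids, chrom = chrom, pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("animal%03d", seq_len(n_samples)),
                         breed = paste0("Breed", pop),
                         location = paste0("Site", pop),
                         stringsAsFactors = FALSE),
    sort_markers = FALSE)

  truth <- structure(list(Q_true = Q_true, F_true = F_true,
                          fst_target = fst_target, alpha = alpha,
                          causal_markers = NULL, h2 = NA_real_,
                          seed = seed),
                     class = "synthetic_truth")
  list(geno = geno, truth = truth)
}

#' Simulate paired rest/stress physiology driven by genotype
#'
#' Builds a latent heat-response score
#' `s_i = sqrt(h2) * g_i + sqrt(1 - h2) * z_i` (scaled to SD
#' `0.5`), where the genetic part `g` combines declared causal-marker
#' effects with a polygenic term drawn with covariance proportional to
#' the realized vanRaden kinship (so the GWAS model assumptions hold
#' exactly under simulation), and `z` is independent noise. Each of the
#' five scored parameters then changes by `delta * (1 + s_i)` plus
#' measurement noise proportional to `|delta|` -- so setting every delta
#' to zero yields exactly zero change and AHTI 0 for all animals. Tidal
#' volume and metabolic rate are simulated directly and the raw gas
#' measurements (GV, VO2, VCO2) back-computed so the derivations
#' `TV = GV/RR` and the Weir-equation MR hold exactly. Causal effects are
#' declared in AHTI units per Alt allele and mapped to the latent scale
#' through the generator's nominal AHTI-per-latent-unit slope (2.5).
#'
#' @param geno A [genotype_matrix()] from [simulate_admixed_genotypes()].
#' @param truth The matching `synthetic_truth` (updated in the return).
#' @param causal_markers Named numeric vector: marker id -> effect in
#'   AHTI units per Alt allele. May be empty.
#' @param h2 Fraction of latent-score variance that is genetic, in [0, 1].
#' @param baselines Data frame overriding the per-parameter
#'   (`rest_mean`, `rest_sd`, `delta`) defaults; same shape as the
#'   package default table.
#' @param noise_frac Measurement-noise SD as a fraction of `|delta|`.
#' @param rq Respiratory quotient used to back out VCO2 from VO2.
#' @param seed Integer seed.
#' @return List with `panel` (physiology data frame: one rest and one
#'   stress row per animal, columns `animal_id`, `timepoint`, `RT`, `ET`,
#'   `RR`, `GV`, `VO2`, `VCO2`, `BW`) and the updated `truth` carrying
#'   `causal_markers`, `h2` and the realized latent scores `s`.
#' @export
simulate_physiology <- function(geno, truth, causal_markers = NULL,
                                h2 = 0.3, baselines = NULL,
                                noise_frac = 0.25, rq = 0.85, seed = 1L) {
  assert_scalar_number(h2, "h2", 0, 1)
  base <- baselines %||% .physio_defaults
  if (!all(c("param", "rest_mean", "rest_sd", "delta") %in% names(base))) {
    stop_validation("baselines needs columns param, rest_mean, rest_sd, delta")
  }
  base <- base[match(.ahti_params, base$param), ]
  if (anyNA(base$param)) stop_validation("baselines must cover RT, ET, RR, TV, MR")

  n <- n_samples(geno)
  eff <- numeric(0)
  if (!is.null(causal_markers) && length(causal_markers)) {
    eff <- unlist(causal_markers)
    missing_ids <- setdiff(names(eff), geno$map$marker_id)
    if (length(missing_ids)) {
      stop_validation("causal markers absent from genotypes: ",
                      paste(missing_ids, collapse = ", "))
    }
  }

  withr::with_seed(seed, {
    # Genetic part of the latent score, in latent units.
    g_caus <- rep(0, n)
    var_caus <- 0
    if (length(eff)) {
      dose <- impute_column_mean(
        geno$calls[, names(eff), drop = FALSE] * 1.0)
      beta_lat <- eff / .ahti_slope
      g_caus <- drop(dose %*% beta_lat)
      g_caus <- g_caus - mean(g_caus)
      var_caus <- stats::var(g_caus) * (n - 1) / n
    }
    target_gvar <- h2 * .latent_sd^2
    poly_var <- max(0, target_gvar - var_caus)
    u <- rep(0, n)
    if (poly_var > 0 && h2 > 0) {
      Kmat <- vanraden_kinship(geno)
      L <- chol(Kmat + diag(1e-6, n))
      u <- drop(crossprod(L, stats::rnorm(n)))
      u <- u - mean(u)
      sdu <- stats::sd(u)
      if (sdu > 0) u <- u * sqrt(poly_var) / sdu
    }
    g <- g_caus + u
    env_var <- max(0, .latent_sd^2 - target_gvar)
    s <- g + stats::rnorm(n, 0, sqrt(env_var))

    bw <- pmax(20, stats::rnorm(n, 45, 5))
    vals_rest <- vals_stress <- matrix(0, n, 5L,
                                       dimnames = list(NULL, .ahti_params))
    for (k in seq_len(5L)) {
      rest <- stats::rnorm(n, base$rest_mean[k], base$rest_sd[k])
      noise <- if (base$delta[k] == 0) rep(0, n) else
        stats::rnorm(n, 0, noise_frac * abs(base$delta[k]))
      vals_rest[, k] <- rest
      vals_stress[, k] <- rest + base$delta[k] * (1 + s) + noise
    }
  })

  # Guard physical ranges for the derived back-computation.
  vals_rest[, "RR"] <- pmax(vals_rest[, "RR"], 5)
  vals_stress[, "RR"] <- pmax(vals_stress[, "RR"], 5)
  vals_rest[, "TV"] <- pmax(vals_rest[, "TV"], 0.01)
  vals_stress[, "TV"] <- pmax(vals_stress[, "TV"], 0.01)
  vals_rest[, "MR"] <- pmax(vals_rest[, "MR"], 10)
  vals_stress[, "MR"] <- pmax(vals_stress[, "MR"], 10)

  make_rows <- function(vals, timepoint) {
    gv <- vals[, "TV"] * vals[, "RR"]
    # MR = 1440 * VO2 * (c1 + c2 * rq) / BW^0.75  =>  solve for VO2.
    vo2 <- vals[, "MR"] * bw^0.75 / (1440 * (3.941 + 1.106 * rq))
    data.frame(animal_id = geno$samples$sample_id, timepoint = timepoint,
               RT = vals[, "RT"], ET = vals[, "ET"], RR = vals[, "RR"],
               GV = gv, VO2 = vo2, VCO2 = rq * vo2, BW = bw,
               stringsAsFactors = FALSE)
  }
  panel <- rbind(make_rows(vals_rest, "rest"), make_rows(vals_stress, "stress"))
  rownames(panel) <- NULL

  truth$causal_markers <- eff
  truth$h2 <- h2
  truth$s <- s
  list(panel = panel, truth = truth)
}

#' Build a meteorological table for THI computation
#'
#' @param site_params Data frame with columns `location`, `DBT_am`,
#'   `RH_am`, `DBT_pm`, `RH_pm` (temperatures in Celsius, humidity in
#'   percent), one row per site.
#' @return Data frame with one row per site and clock time (`07:00`,
#'   `14:00`): `location`, `clock_time`, `DBT`, `RH` -- ready for
#'   [thi_table()].
#' @export
simulate_meteo <- function(site_params) {
  req <- c("location", "DBT_am", "RH_am", "DBT_pm", "RH_pm")
  miss <- setdiff(req, names(site_params))
  if (length(miss)) stop_validation("site_params lacks columns: ",
                                    paste(miss, collapse = ", "))
  if (!nrow(site_params)) {
    return(data.frame(location = character(), clock_time = character(),
                      DBT = numeric(), RH = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(site_params$location)) stop_validation("duplicate site labels")
  rh <- c(site_params$RH_am, site_params$RH_pm)
  dbt <- c(site_params$DBT_am, site_params$DBT_pm)
  if (any(rh < 0 | rh > 100)) stop_validation("RH must be within [0, 100]")
  if (any(dbt < -20 | dbt > 60)) stop_validation("DBT outside plausible range (-20..60 C)")
  out <- data.frame(
    location = rep(site_params$location, 2L),
    clock_time = rep(c("07:00", "14:00"), each = nrow(site_params)),
    DBT = dbt, RH = rh, stringsAsFactors = FALSE)
  out[order(out$location, out$clock_time), , drop = FALSE]
}
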