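#' @title Synthetic litter/soil NUE datasets
#' @description Generates datasets with the statistical structure the
#'   analysis pipeline assumes: three substrate classes (36 mineral soil,
#'   19 organic soil, 38 litter samples by default), substrate-specific
#'   resource C:N distributions spanning 9-62, a weakly non-homeostatic
#'   biomass C:N (log-log slope 0.14), a continuous two-segment NUE mean
#'   function (break point 20, NUE 0.83 at the break), gross N fluxes
#'   consistent with that NUE, and isotope-pool-dilution tracer time
#'   courses simulated from the true rates with configurable noise.  A
#'   ground-truth table accompanies every dataset so that each pipeline
#'   stage can be tested by parameter recovery.
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' All distribution shapes and noise magnitudes are explicit configuration
#' calibrated to the emulated survey's printed group sizes, ranges, means
#' and coefficients of variation; see the package vignette for the
#' rationale behind each default.
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration and this seed.
#' @param n_mineral,n_organic,n_litter samples per substrate class.
#' @param rcn per-substrate truncated-normal parameters
#'   (`mean`, `sd`, `bounds`) for resource C:N (mass ratio).
#' @param homeostasis parameters of the biomass C:N model
#'   `log10(B_CN) = intercept + slope * log10(R_CN) + noise`:
#'   `intercept`, `slope`, `sd` (log10 units), `bounds` on B_CN.
#' @param nue NUE mean-function parameters: `model` (`"piecewise"`,
#'   `"saturating"` or `"flat"`), two-segment parameters `breakpoint`,
#'   `y_at_break`, `left_slope`, `right_slope`; saturating-truth
#'   parameters `sat_a`, `sat_k` (applied to the C:N imbalance);
#'   `flat_value`; residual `sd` and `clip` bounds.
#' @param u_n lognormal gross organic-N uptake: `median`
#'   (ug N g^-1 d.w. day^-1) and `sdlog`.
#' @param biomass_missing per-substrate counts of samples whose microbial
#'   biomass is "not determined" (the trailing samples of each block);
#'   defaults reproduce a 71-of-93 biomass coverage.
#' @param resource_c per-substrate truncated-normal parameters for total
#'   resource C (% dry weight); resource N follows as `C / R_CN`.
#' @param inorganic per-substrate lognormal `median`/`sdlog` for ammonium
#'   and nitrate concentrations (ug N g^-1 d.w.).
#' @param tracer tracer-assay parameters: natural abundance, label
#'   enrichments (98 atom% for the amino-acid mix, 10 atom% for the
#'   inorganic spikes), assay time points (litter amino acids 2/10/20 min,
#'   soil 10/30 min, inorganic pools 4 h and 24 h), replicate counts
#'   (triplicate litter / duplicate soil amino-acid assays, quadruplicate
#'   inorganic assays), spike sizes (ug N g^-1 d.w.), free-amino-acid
#'   pool turnover times (days; the pool size is gross uptake times
#'   turnover, reflecting its minutes-to-hours half-life),
#'   multiplicative ranges tying the unobserved fluxes
#'   (amino-acid production, ammonium and nitrate consumption) to the
#'   observed ones, the nitrification distribution, and the noise levels:
#'   `conc_noise` (lognormal sd on concentrations, default 5%) and
#'   `ape_noise` (relative Gaussian sd on atom% excess, default 2%).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_mineral = 36L, n_organic = 19L, n_litter = 38L,
    rcn = list(mineral = list(mean = 15, sd = 4, bounds = c(9, 30)),
               organic = list(mean = 24, sd = 6, bounds = c(12, 38)),
               litter  = list(mean = 48, sd = 7, bounds = c(35, 62))),
    homeostasis = list(intercept = 0.77, slope = 0.14, sd = 0.08,
                       bounds = c(4, 25)),
    nue = list(model = "piecewise", breakpoint = 20, y_at_break = 0.83,
               left_slope = 0.048, right_slope = 0.0056,
               sat_a = 1.03, sat_k = 0.92, flat_value = 0.8,
               sd = 0.06, clip = c(0.15, 1.0)),
    u_n = list(median = 5, sdlog = 0.4),
    biomass_missing = c(mineral = 16L, organic = 6L, litter = 0L),
    resource_c = list(mineral = list(mean = 5, sd = 2, bounds = c(1.5, 10)),
                      organic = list(mean = 30, sd = 8, bounds = c(10, 45)),
                      litter  = list(mean = 48, sd = 2, bounds = c(44, 52))),
    inorganic = list(
      nh4 = list(mineral = c(median = 5.3, sdlog = 0.9),
                 organic = c(median = 18.9, sdlog = 1.0),
                 litter  = c(median = 14.1, sdlog = 0.45)),
      no3 = list(mineral = c(median = 1.0, sdlog = 0.7),
                 organic = c(median = 1.4, sdlog = 1.0),
                 litter  = c(median = 4.1, sdlog = 0.5))),
    tracer = list(natural_abundance = 0.3663, label_aa = 98,
                  label_inorg = 10,
                  conc_noise = 0.05, ape_noise = 0.02,
                  aa_times_litter = c(2, 10, 20), aa_times_soil = c(10, 30),
                  aa_reps_litter = 3L, aa_reps_soil = 2L,
                  aa_spike_litter = 0.1, aa_spike_soil = 0.06,
                  aa_turnover = list(litter = c(days = 0.04, sdlog = 0.3),
                                     soil = c(days = 0.02, sdlog = 0.3)),
                  inorg_times = c(240, 1440), inorg_reps = 4L,
                  inorg_spike = 1,
                  aa_prod_range = c(0.7, 1.3),
                  nh4_cons_range = c(0.6, 1.4),
                  nit = c(median = 0.5, sdlog = 0.6),
                  no3_cons_range = c(0.5, 1.5))) {
  cfg <- list(seed = as.integer(seed), n_mineral = as.integer(n_mineral),
              n_organic = as.integer(n_organic),
              n_litter = as.integer(n_litter), rcn = rcn,
              homeostasis = homeostasis, nue = nue, u_n = u_n,
              biomass_missing = biomass_missing, resource_c = resource_c,
              inorganic = inorganic, tracer = tracer)
  stopifnot(cfg$n_mineral > 0L, cfg$n_organic > 0L, cfg$n_litter > 0L,
            homeostasis$sd >= 0, nue$sd >= 0,
            tracer$conc_noise >= 0, tracer$ape_noise >= 0)
  for (s in names(rcn)) {
    b <- rcn[[s]]$bounds
    if (b[1L] >= b[2L] ||
        stats::pnorm(b[2L], rcn[[s]]$mean, rcn[[s]]$sd) -
        stats::pnorm(b[1L], rcn[[s]]$mean, rcn[[s]]$sd) < 1e-6) {
      stop("config error: infeasible truncated-normal bounds for ", s,
           " resource C:N", call. = FALSE)
    }
  }
  if (nue$model == "piecewise") {
    all_b <- range(unlist(lapply(rcn, `[[`, "bounds")))
    if (nue$breakpoint <= all_b[1L] || nue$breakpoint >= all_b[2L]) {
      stop("config error: break point outside the resource C:N range",
           call. = FALSE)
    }
  }
  structure(cfg, class = "generator_config")
}

# inverse-CDF truncated normal (one uniform draw per value)
.rtruncnorm <- function(n, mean, sd, bounds) {
  plo <- stats::pnorm(bounds[1L], mean, sd)
  phi <- stats::pnorm(bounds[2L], mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.nue_mean <- function(cfg, R_CN, B_CN) {
  nu <- cfg$nue
  switch(nu$model,
         piecewise = nu$y_at_break +
           nu$left_slope * pmin(R_CN - nu$breakpoint, 0) +
           nu$right_slope * pmax(R_CN - nu$breakpoint, 0),
         saturating = {
           imb <- R_CN / B_CN
           nu$sat_a * imb / (nu$sat_k + imb)
         },
         flat = rep(nu$flat_value, length(R_CN)),
         stop("unknown NUE model: ", nu$model, call. = FALSE))
}

#' Generate a synthetic litter/soil dataset
#'
#' Fully deterministic given the configuration and seed: all draws come
#' from one seeded stream in a fixed, documented order (resource C:N,
#' resource C, biomass C:N, biomass C, NUE residuals, gross uptake,
#' flux multipliers, inorganic concentrations, nitrification,
#' free-amino-acid pools, then per-series tracer noise, each vector in
#' substrate order mineral / organic / litter).  Tracer time courses are
#' integrated from the true rates with [simulate_ipd_forward()] and then
#' perturbed with the configured observation noise.
#'
#' @param config a [generator_config()].
#' @param seed optional override of `config$seed`.
#' @param tracer if `FALSE`, skip the tracer time-course simulation and
#'   return only `samples` and `truth`.  The tracer noise draws come last
#'   in the random stream, so the sample-level tables are identical either
#'   way; use this for analyses that only need the per-sample quantities.
#' @return list of class `nue_dataset`: `samples` (a sample table as read
#'   by [read_sample_table()]), `tracer` (a tracer table as read by
#'   [read_tracer_table()], or `NULL`), `truth` (per-sample ground truth:
#'   true C:N ratios, NUE, gross fluxes per pool) and `config`.
#' @export
generate_dataset <- function(config = generator_config(),
                             seed = config$seed, tracer = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  tr <- config$tracer
  nat <- tr$natural_abundance

  substrate <- rep(c("mineral", "organic", "litter"),
                   c(config$n_mineral, config$n_organic, config$n_litter))
  n <- length(substrate)
  counts <- c(mineral = config$n_mineral, organic = config$n_organic,
              litter = config$n_litter)
  sample_id <- unlist(lapply(names(counts), function(s) {
    sprintf("%s_%02d", s, seq_len(counts[[s]]))
  }))

  draw_by_substrate <- function(fn) {
    unlist(lapply(names(counts), function(s) fn(s, counts[[s]])))
  }

  # 1. resource C:N, 2. resource C (% d.w.)
  R_CN <- draw_by_substrate(function(s, k) {
    p <- config$rcn[[s]]
    .rtruncnorm(k, p$mean, p$sd, p$bounds)
  })
  res_C <- draw_by_substrate(function(s, k) {
    p <- config$resource_c[[s]]
    .rtruncnorm(k, p$mean, p$sd, p$bounds)
  })
  res_N <- res_C / R_CN

  # 3. biomass C:N from the homeostasis model, 4. biomass C
  h <- config$homeostasis
  B_CN <- 10^.rtruncnorm(n, h$intercept + h$slope * log10(R_CN), h$sd,
                         log10(h$bounds))
  bio_C <- draw_by_substrate(function(s, k) {
    med <- c(mineral = 300, organic = 2000, litter = 3000)[[s]]
    stats::rlnorm(k, log(med), 0.3)
  })
  bio_N <- bio_C / B_CN

  # 5. NUE = mean function + residual, clipped
  nue_mu <- .nue_mean(config, R_CN, B_CN)
  NUE <- pmin(pmax(nue_mu + stats::rnorm(n, 0, config$nue$sd),
                   config$nue$clip[1L]), config$nue$clip[2L])

  # 6. gross organic N uptake; mineralization follows from NUE exactly
  U_N <- stats::rlnorm(n, log(config$u_n$median), config$u_n$sdlog)
  M_N <- U_N * (1 - NUE)

  # 7-10. unobserved flux multipliers and inorganic chemistry
  aa_prod <- U_N * stats::runif(n, tr$aa_prod_range[1L],
                                tr$aa_prod_range[2L])
  nh4 <- draw_by_substrate(function(s, k) {
    p <- config$inorganic$nh4[[s]]
    stats::rlnorm(k, log(p[["median"]]), p[["sdlog"]])
  })
  no3 <- draw_by_substrate(function(s, k) {
    p <- config$inorganic$no3[[s]]
    stats::rlnorm(k, log(p[["median"]]), p[["sdlog"]])
  })
  nh4_cons_raw <- M_N * stats::runif(n, tr$nh4_cons_range[1L],
                                     tr$nh4_cons_range[2L])
  g_nit <- stats::rlnorm(n, log(tr$nit[["median"]]), tr$nit[["sdlog"]])
  g_nit[substrate != "litter"] <- NA_real_
  no3_cons_raw <- g_nit * stats::runif(n, tr$no3_cons_range[1L],
                                       tr$no3_cons_range[2L])
  # 11. free amino acid pool sizes: flux times turnover time (the pool
  # is small and highly dynamic, half-life of minutes to hours), so the
  # short assay sees a measurable dilution at any uptake rate
  aa_turn <- lapply(substrate, function(s) {
    tr$aa_turnover[[if (s == "litter") "litter" else "soil"]]
  })
  aa_pool <- U_N *
    vapply(aa_turn, `[[`, numeric(1L), "days") *
    stats::rlnorm(n, 0, vapply(aa_turn, `[[`, numeric(1L), "sdlog"))

  # keep consumption from driving a pool negative over the assay horizon
  horizon_d <- max(tr$inorg_times) / MINUTES_PER_DAY
  nh4_cons <- pmin(nh4_cons_raw,
                   M_N + 0.8 * (nh4 + tr$inorg_spike) / horizon_d)
  no3_cons <- pmin(no3_cons_raw,
                   g_nit + 0.8 * (no3 + tr$inorg_spike) / horizon_d)

  biomass_measured <- rep(TRUE, n)
  for (s in names(counts)) {
    k_miss <- config$biomass_missing[[s]]
    if (k_miss > 0L) {
      idx <- which(substrate == s)
      biomass_measured[utils::tail(idx, k_miss)] <- FALSE
    }
  }

  samples <- data.frame(
    sample_id = sample_id, substrate = substrate,
    resource_C = res_C, resource_N = res_N,
    biomass_C = ifelse(biomass_measured, bio_C, NA_real_),
    biomass_N = ifelse(biomass_measured, bio_N, NA_real_),
    nh4 = nh4, no3 = no3, stringsAsFactors = FALSE)

  u_tot <- U_N + nh4_cons + ifelse(is.na(no3_cons), 0, no3_cons)
  nue_inorg_true <- ifelse(
    substrate == "litter",
    pmin(pmax((u_tot - M_N - ifelse(is.na(g_nit), 0, g_nit)) / u_tot, 0), 1),
    NA_real_)
  truth <- data.frame(
    sample_id = sample_id, substrate = substrate,
    R_CN = R_CN, B_CN = B_CN, biomass_measured = biomass_measured,
    NUE_true = NUE, NUE_inorg_true = nue_inorg_true,
    U_N_true = U_N, M_N_true = M_N, G_N_true = U_N - M_N,
    aa_production = aa_prod, nh4_consumption = nh4_cons,
    gross_nitrification = g_nit, no3_consumption = no3_cons,
    aa_pool = aa_pool, stringsAsFactors = FALSE)

  if (!tracer) {
    return(structure(list(samples = samples, tracer = NULL, truth = truth,
                          config = config, seed = as.integer(seed)),
                     class = "nue_dataset"))
  }

  # 12. tracer time courses, pool order amino_acid / ammonium / nitrate
  rows <- vector("list", 3L * n)
  ri <- 0L
  noisy_rows <- function(series, reps) {
    m <- length(series$times)
    conc <- matrix(0, reps, m)
    ape <- matrix(0, reps, m)
    true_ape <- series$atom_pcts - nat
    for (r in seq_len(reps)) {
      for (j in seq_len(m)) {
        conc[r, j] <- series$concentrations[j] *
          stats::rlnorm(1L, 0, tr$conc_noise)
        ape[r, j] <- true_ape[j] *
          pmax(0.2, 1 + stats::rnorm(1L, 0, tr$ape_noise))
      }
    }
    data.frame(sample_id = series$sample_id, pool = series$pool,
               replicate = rep(seq_len(reps), each = m),
               time_min = rep(series$times, reps),
               conc_ugN_gdw = as.vector(t(conc)),
               atom_pct_15N = as.vector(t(ape)) + nat,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    is_litter <- substrate[i] == "litter"
    # amino acid assay
    spike <- if (is_litter) tr$aa_spike_litter else tr$aa_spike_soil
    C0 <- aa_pool[i] + spike
    A0 <- spike * (tr$label_aa - nat) / C0
    times <- if (is_litter) tr$aa_times_litter else tr$aa_times_soil
    reps <- if (is_litter) tr$aa_reps_litter else tr$aa_reps_soil
    aa_series <- simulate_ipd_forward(aa_prod[i], U_N[i], C0, A0, times,
                                      sample_id = sample_id[i],
                                      pool = "amino_acid",
                                      natural_abundance = nat)
    ri <- ri + 1L; rows[[ri]] <- noisy_rows(aa_series, reps)
    # ammonium assay
    C0 <- nh4[i] + tr$inorg_spike
    A0 <- tr$inorg_spike * (tr$label_inorg - nat) / C0
    nh4_series <- simulate_ipd_forward(M_N[i], nh4_cons[i], C0, A0,
                                       tr$inorg_times,
                                       sample_id = sample_id[i],
                                       pool = "ammonium",
                                       natural_abundance = nat)
    ri <- ri + 1L; rows[[ri]] <- noisy_rows(nh4_series, tr$inorg_reps)
    # nitrate assay (litter only)
    if (is_litter) {
      C0 <- no3[i] + tr$inorg_spike
      A0 <- tr$inorg_spike * (tr$label_inorg - nat) / C0
      no3_series <- simulate_ipd_forward(g_nit[i], no3_cons[i], C0, A0,
                                         tr$inorg_times,
                                         sample_id = sample_id[i],
                                         pool = "nitrate",
                                         natural_abundance = nat)
      ri <- ri + 1L; rows[[ri]] <- noisy_rows(no3_series, tr$inorg_reps)
    }
  }
  tracer <- do.call(rbind, rows[seq_len(ri)])
  rownames(tracer) <- NULL

  structure(list(samples = samples, tracer = tracer, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "nue_dataset")
}

#' Generate a null dataset with a flat NUE mean
#'
#' Identical structure to [generate_dataset()] but the NUE mean function
#' is constant, providing the null model against which the specificity of
#' the threshold detectors (break-point regression, regression tree) is
#' checked.
#'
#' @inheritParams generate_dataset
#' @param flat_nue the constant mean NUE, in (0, 1).
#' @export
generate_null_dataset <- function(config = generator_config(),
                                  flat_nue = 0.8, seed = config$seed,
                                  tracer = TRUE) {
  stopifnot(flat_nue > 0, flat_nue < 1)
  config$nue$model <- "flat"
  config$nue$flat_value <- flat_nue
  generate_dataset(config, seed = seed, tracer = tracer)
}

#' @export
print.nue_dataset <- function(x, ...) {
  cat(sprintf("Synthetic NUE dataset: %d samples (%s), %d tracer rows, seed %d\n",
              nrow(x$samples),
              paste(table(factor(x$samples$substrate, SUBSTRATES)),
                    collapse = "/"),
              if (is.null(x$tracer)) 0L else nrow(x$tracer), x$seed))
  invisible(x)
}

#' Write a generated dataset to a directory
#'
#' Emits `samples.csv`, `tracer.csv` and `truth.csv` (all via the 6
#' significant digit serializers of the tables module) plus `config.R`, a
#' `dput()` echo of the generator configuration.  Output is
#' byte-reproducible for a given configuration and seed.
#'
#' @param dataset an `nue_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nue_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             tracer = file.path(dir, "tracer.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.R"))
  write_sample_table(dataset$samples, paths[["samples"]])
  write_results_table(dataset$tracer, paths[["tracer"]])
  write_results_table(dataset$truth, paths[["truth"]])
  dput(unclass(dataset$config), file = paths[["config"]])
  invisible(paths)
}
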