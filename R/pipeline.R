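#' @title End-to-end NUE pipeline
#' @description Assembles per-sample records from a sample table and its
#'   tracer series: gross N fluxes by isotope pool dilution, NUE and
#'   NUE_+inorg, C:N ratios and their imbalance.
#' @name pipeline
NULL

#' Build sample records from tables
#'
#' Runs the rate estimation ([pool_rates_for_sample()]) for every sample
#' and derives the NUE quantities.  `NUE_inorg` is only computed for
#' samples with a nitrate assay (litter, in the emulated design);
#' `imbalance` is only computed where microbial biomass was measured
#' (missing biomass is "not determined", never zero).
#'
#' @param samples a sample table (data frame from [read_sample_table()] or
#'   [generate_dataset()], or a path to one).
#' @param tracer tracer series: a named list from [read_tracer_table()], a
#'   tracer data frame from [generate_dataset()], or a path.
#' @param pair interval choice passed to [gross_rates_kb()].
#' @param nue_inorg_variant passed to [compute_nue_inorg()].
#' @return data frame with one row per sample: `sample_id`, `substrate`,
#'   `R_CN`, `B_CN`, `U_N`, `M_N`, `G_N`, `NUE`, `NUE_inorg`, `imbalance`,
#'   `flags` (semicolon-separated QC flags, empty when clean).
#' @export
nue_sample_records <- function(samples, tracer, pair = NULL,
                               nue_inorg_variant = "net") {
  if (is.character(samples)) samples <- read_sample_table(samples)
  if (is.character(tracer)) {
    tracer <- read_tracer_table(tracer)
  } else if (is.data.frame(tracer)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    write_results_table(tracer, tmp)
    tracer <- read_tracer_table(tmp)
  }
  series_ids <- vapply(tracer, `[[`, character(1L), "sample_id")
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    mine <- tracer[series_ids == sid]
    rates <- pool_rates_for_sample(mine, pair = pair)
    R_CN <- samples$resource_C[i] / samples$resource_N[i]
    B_CN <- samples$biomass_C[i] / samples$biomass_N[i]
    flags <- rates$flags
    if (rates$U_N > 0) {
      nue <- compute_nue(rates$U_N, rates$M_N)
      if (isTRUE(attr(nue, "flagged"))) flags <- c(flags, "nue-clamped")
    } else {
      # amino-acid consumption estimated at zero (flagged upstream):
      # NUE undefined for this sample
      nue <- NA_real_
      flags <- c(flags, "undefined-nue")
    }
    nue_inorg <- NA_real_
    if (!is.na(rates$gross_nitrification) &&
        rates$U_N + rates$nh4_consumption + rates$no3_consumption > 0) {
      nue_inorg <- compute_nue_inorg(rates$U_N, rates$nh4_consumption,
                                     rates$no3_consumption, rates$M_N,
                                     rates$gross_nitrification,
                                     variant = nue_inorg_variant)
      if (isTRUE(attr(nue_inorg, "flagged"))) {
        flags <- c(flags, "nue-inorg-clamped")
      }
    }
    out[[i]] <- data.frame(
      sample_id = sid, substrate = samples$substrate[i],
      R_CN = R_CN, B_CN = B_CN,
      U_N = rates$U_N, M_N = rates$M_N, G_N = rates$U_N - rates$M_N,
      NUE = as.numeric(nue), NUE_inorg = as.numeric(nue_inorg),
      imbalance = if (is.na(B_CN)) NA_real_ else imbalance(R_CN, B_CN),
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records
}

#' Run the full NUE analysis on sample records
#'
#' Convenience wrapper fitting every model of the analysis: substrate
#' comparison of NUE (Kruskal-Wallis + Dunn), the homeostasis regression,
#' the break-point regression and regression tree of NUE on resource C:N,
#' the saturating regression of NUE on C:N imbalance (samples with
#' biomass only), and the litter-only linear regression of NUE on
#' resource C:N.
#'
#' @param records data frame from [nue_sample_records()] (or any data
#'   frame with `substrate`, `R_CN`, `B_CN`, `NUE`, `imbalance`).
#' @param tree_seed seed for the regression-tree fold assignment.
#' @return list of class `nue_analysis` with elements `groups`,
#'   `homeostasis`, `piecewise`, `tree`, `saturating`, `litter_linear`.
#' @export
analyze_nue <- function(records, tree_seed = 1L) {
  grp <- split(records$NUE, factor(records$substrate, SUBSTRATES))
  grp <- grp[lengths(grp) >= 2L]
  if (is.null(records$imbalance)) {
    records$imbalance <- imbalance(records$R_CN, records$B_CN)
  }
  has_b <- !is.na(records$imbalance)
  litter <- records$substrate == "litter"
  structure(list(
    groups = compare_groups(grp),
    homeostasis = fit_homeostasis(records$R_CN, records$B_CN),
    piecewise = fit_piecewise(records$R_CN, records$NUE),
    tree = fit_regression_tree(records$R_CN, records$NUE, seed = tree_seed),
    saturating = fit_saturating(records$imbalance[has_b],
                                records$NUE[has_b]),
    litter_linear = fit_linear(records$R_CN[litter], records$NUE[litter])),
    class = "nue_analysis")
}

#' @export
print.nue_analysis <- function(x, ...) {
  cat("== Substrate comparison of NUE ==\n"); print(x$groups)
  cat("\n== Homeostasis ==\n"); print(x$homeostasis)
  cat("\n== NUE ~ resource C:N ==\n"); print(x$tree); print(x$piecewise)
  cat("\n== NUE ~ C:N imbalance ==\n"); print(x$saturating)
  cat("\n== Litter only ==\n"); print(x$litter_linear)
  invisible(x)
}
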