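#' @title Nitrogen use efficiency and its stoichiometric framework
#' @description Microbial nitrogen use efficiency (NUE) partitions gross
#'   organic N uptake `U_N` between growth (`G_N = U_N - M_N`) and release
#'   as ammonium (gross N mineralization `M_N`):
#'   `NUE = (U_N - M_N) / U_N`, dimensionless in `[0, 1]`.  The mass
#'   balance of a homeostatic consumer couples NUE to carbon use
#'   efficiency (CUE) and the resource and biomass C:N ratios,
#'   `B_CN = R_CN * CUE / NUE`, and the threshold elemental ratio at which
#'   growth limitation switches from C to N is
#'   `TER_CN = (NUE / CUE) * B_CN`.
#' @name nue_stoichiometry
NULL

.flagged <- function(x, flagged) {
  attr(x, "flagged") <- flagged
  x
}

#' Nitrogen use efficiency
#'
#' `NUE = (U_N - M_N) / U_N`.  If noise in the two independently measured
#' gross rates makes `M_N > U_N`, the raw negative value is clamped to 0
#' and flagged (attribute `"flagged"`), keeping downstream analyses
#' defined while preserving QC visibility.
#'
#' @param U_N gross uptake of organic N (ug N g^-1 d.w. day^-1), > 0.
#' @param M_N gross N mineralization (same units), >= 0.
#' @return NUE in `[0, 1]` (vectorized), with logical attribute
#'   `"flagged"` marking clamped values.
#' @export
compute_nue <- function(U_N, M_N) {
  if (any(!is.na(U_N) & U_N <= 0)) {
    stop("undefined NUE: U_N must be > 0", call. = FALSE)
  }
  if (any(!is.na(M_N) & M_N < 0)) {
    stop("M_N must be >= 0", call. = FALSE)
  }
  raw <- (U_N - M_N) / U_N
  flag <- !is.na(raw) & raw < 0
  .flagged(pmax(raw, 0), flag)
}

#' Nitrogen use efficiency including inorganic N assimilation
#'
#' Extends NUE to total N uptake `U_tot = U_N + nh4_consumption +
#' no3_consumption`.  The default (`variant = "net"`) subtracts both gross
#' N mineralization and gross nitrification from total uptake,
#' `NUE_inorg = (U_tot - M_N - gross_nitrification) / U_tot`; the
#' `"addition"` variant subtracts mineralization only.  The net variant is
#' the one consistent with inorganic assimilation lowering apparent NUE on
#' N-rich litter.
#'
#' @param U_N,M_N as in [compute_nue()].
#' @param nh4_consumption,no3_consumption gross consumption of ammonium
#'   and nitrate (same units), >= 0.
#' @param gross_nitrification gross nitrate production (same units), >= 0.
#' @param variant `"net"` (default) or `"addition"`.
#' @return NUE_inorg clamped to `[0, 1]`, with attribute `"flagged"`.
#' @export
compute_nue_inorg <- function(U_N, nh4_consumption, no3_consumption,
                              M_N, gross_nitrification,
                              variant = c("net", "addition")) {
  variant <- match.arg(variant)
  rates <- cbind(U_N, nh4_consumption, no3_consumption, M_N,
                 gross_nitrification)
  if (any(!is.na(rates) & rates < 0)) {
    stop("all rates must be >= 0", call. = FALSE)
  }
  u_tot <- U_N + nh4_consumption + no3_consumption
  if (any(!is.na(u_tot) & u_tot <= 0)) {
    stop("undefined NUE_inorg: total uptake must be > 0", call. = FALSE)
  }
  released <- if (variant == "net") M_N + gross_nitrification else M_N
  raw <- (u_tot - released) / u_tot
  flag <- !is.na(raw) & (raw < 0 | raw > 1)
  .flagged(pmin(pmax(raw, 0), 1), flag)
}

#' Carbon-to-nitrogen imbalance
#'
#' The stoichiometric mismatch between a resource and its microbial
#' consumers: resource C:N normalized to microbial biomass C:N.  `NA`
#' biomass ratios propagate (samples without a biomass measurement are
#' excluded from imbalance analyses, not set to zero).
#'
#' @param R_CN resource C:N mass ratio, > 0.
#' @param B_CN microbial biomass C:N mass ratio, > 0 or `NA`.
#' @return `R_CN / B_CN` (vectorized).
#' @export
imbalance <- function(R_CN, B_CN) {
  if (any(!is.na(R_CN) & R_CN <= 0) || any(!is.na(B_CN) & B_CN <= 0)) {
    stop("C:N ratios must be > 0", call. = FALSE)
  }
  R_CN / B_CN
}

#' Threshold elemental ratio
#'
#' `TER_CN = (NUE / CUE) * B_CN`: the resource C:N at which the metabolic
#' control of a decomposer community switches between C limitation
#' (below) and N limitation (above).
#'
#' @param NUE,CUE efficiencies in `(0, 1]`.
#' @param B_CN biomass C:N mass ratio, > 0.
#' @return object of class `ter_result` with fields `TER_CN`, `CUE`,
#'   `NUE`, `B_CN`.
#' @export
ter <- function(NUE, CUE, B_CN) {
  stopifnot(NUE > 0, NUE <= 1, CUE <= 1, B_CN > 0)
  if (CUE <= 0) stop("undefined threshold: CUE must be > 0", call. = FALSE)
  structure(list(TER_CN = (NUE / CUE) * B_CN, CUE = CUE, NUE = NUE,
                 B_CN = B_CN),
            class = "ter_result")
}

#' @export
print.ter_result <- function(x, ...) {
  cat(sprintf(
    "TER_C:N = %.4g  (NUE = %.3g, CUE = %.3g, biomass C:N = %.3g)\n",
    x$TER_CN, x$NUE, x$CUE, x$B_CN))
  invisible(x)
}

#' Carbon use efficiency implied by the TER mass balance
#'
#' Rearranges the threshold relation to `CUE = NUE * B_CN / TER_CN`.
#'
#' @param NUE efficiency in `(0, 1]`.
#' @param B_CN biomass C:N mass ratio, > 0.
#' @param TER_CN threshold elemental ratio, > 0.
#' @return CUE (dimensionless).
#' @export
cue_at_ter <- function(NUE, B_CN, TER_CN) {
  stopifnot(NUE > 0, B_CN > 0)
  if (!all(TER_CN > 0)) stop("TER_CN must be > 0", call. = FALSE)
  NUE * B_CN / TER_CN
}

#' Solve the stoichiometric mass balance for the missing quantity
#'
#' The mass balance `B_CN * NUE = R_CN * CUE` links carbon use
#' efficiency, nitrogen use efficiency and the biomass and resource C:N
#' ratios of a homeostatic consumer.  Supply exactly three of the four;
#' the fourth is returned.
#'
#' @param CUE,NUE,B_CN,R_CN supply exactly three (all > 0), leave the
#'   unknown `NULL`.
#' @return named numeric scalar (name = solved quantity).  A solved
#'   efficiency outside `(0, 1]` carries attribute `flagged = TRUE`.
#' @export
mass_balance_solve <- function(CUE = NULL, NUE = NULL, B_CN = NULL,
                               R_CN = NULL) {
  given <- list(CUE = CUE, NUE = NUE, B_CN = B_CN, R_CN = R_CN)
  supplied <- !vapply(given, is.null, logical(1L))
  if (sum(supplied) != 3L) {
    stop("arity error: supply exactly three of CUE, NUE, B_CN, R_CN",
         call. = FALSE)
  }
  vals <- unlist(given[supplied])
  if (any(vals <= 0)) stop("all supplied quantities must be > 0",
                           call. = FALSE)
  unknown <- names(given)[!supplied]
  value <- switch(unknown,
                  CUE = NUE * B_CN / R_CN,
                  NUE = CUE * R_CN / B_CN,
                  B_CN = R_CN * CUE / NUE,
                  R_CN = B_CN * NUE / CUE)
  out <- stats::setNames(value, unknown)
  if (unknown %in% c("CUE", "NUE") && (value <= 0 || value > 1)) {
    attr(out, "flagged") <- TRUE
  }
  out
}

#' Stoichiometric homeostasis regression
#'
#' Ordinary least squares of `log10(B_CN)` on `log10(R_CN)`.  A shallow
#' slope indicates that the community holds its biomass C:N nearly
#' constant across resources; the conventional cut-off classifies the
#' community as homeostatic when the slope is below 0.25.
#'
#' @param R_CN,B_CN resource and biomass C:N mass ratios.  `NA` pairs are
#'   dropped; at least 3 complete pairs are required.
#' @param threshold classification cut-off on the slope (default 0.25).
#' @return object of class `homeostasis_fit`: `slope`, `slope_se`,
#'   `intercept`, `p_value` (two-sided, slope != 0), `r_squared`, `n`,
#'   `classification` and the underlying `lm` fit.
#' @export
fit_homeostasis <- function(R_CN, B_CN, threshold = 0.25) {
  if (is.data.frame(R_CN) && missing(B_CN)) {
    B_CN <- R_CN$B_CN
    R_CN <- R_CN$R_CN
  }
  keep <- !is.na(R_CN) & !is.na(B_CN)
  if (sum(keep) < 3L) {
    stop("insufficient data: need >= 3 samples with both C:N ratios",
         call. = FALSE)
  }
  lx <- log10(R_CN[keep])
  ly <- log10(B_CN[keep])
  fit <- stats::lm(ly ~ lx)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  structure(list(slope = slope,
                 slope_se = sm$coefficients[2L, 2L],
                 intercept = unname(stats::coef(fit)[1L]),
                 p_value = sm$coefficients[2L, 4L],
                 r_squared = sm$r.squared,
                 n = sum(keep),
                 threshold = threshold,
                 classification = if (slope < threshold) "homeostatic"
                                  else "non-homeostatic",
                 lm = fit),
            class = "homeostasis_fit")
}

#' @export
print.homeostasis_fit <- function(x, ...) {
  cat("Stoichiometric homeostasis regression",
      "(log10 biomass C:N ~ log10 resource C:N)\n")
  cat(sprintf("  slope %.4g (se %.3g), intercept %.4g, R^2 %.3f, P %.3g, n %d\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value, x$n))
  cat(sprintf("  classification: %s (slope %s %.2f)\n", x$classification,
              if (x$slope < x$threshold) "<" else ">=", x$threshold))
  invisible(x)
}

#' @export
coef.homeostasis_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
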