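# Closed-form pool-dilution trajectory: constant gross production p and
# consumption c give C(t) = C0 + (p - c) t and, for the atom% excess,
# A(t) = A0 (C(t)/C0)^(-p/(p-c)) (p != c) or A0 exp(-p t / C0) (p = c).
# Rates per day, t in minutes.  Used to cross-check both the numerical
# integrator and, together with it, the two-point estimator.
closed_form_ipd <- function(p, c, C0, A0, t_min) {
  t_d <- t_min / 1440
  C_t <- C0 + (p - c) * t_d
  A_t <- if (abs(p - c) < 1e-12 * max(p, c, 1)) {
    A0 * exp(-p * t_d / C0)
  } else {
    A0 * (C_t / C0)^(-p / (p - c))
  }
  list(C = C_t, A = A_t)
}

# A small valid sample table
make_sample_df <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3"),
    substrate = c("litter", "organic", "mineral"),
    resource_C = c(48, 30, 5),
    resource_N = c(1, 2, 0.5),
    biomass_C = c(3000, 2000, NA),
    biomass_N = c(330, 290, NA),
    nh4 = c(14, 19, 5),
    no3 = c(4, 1.4, 1),
    stringsAsFactors = FALSE)
}

write_csv_text <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

fast_config <- function(...) generator_config(...)
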