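#' @title Tabular input/output for the NUE pipeline
#' @description Readers and writers for the two input tables (per-sample
#'   chemistry and tracer time courses) and the derived results table.
#' @name tables_io
NULL

SAMPLE_COLUMNS <- c("sample_id", "substrate", "resource_C", "resource_N",
                    "biomass_C", "biomass_N", "nh4", "no3")
TRACER_COLUMNS <- c("sample_id", "pool", "replicate", "time_min",
                    "conc_ugN_gdw", "atom_pct_15N")
SUBSTRATES <- c("litter", "organic", "mineral")
POOLS <- c("amino_acid", "ammonium", "nitrate")

.delim_char <- function(dialect) {
  dialect <- match.arg(dialect, c("csv", "tsv"))
  if (dialect == "csv") "," else "\t"
}

.read_raw <- function(path, dialect) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  utils::read.table(path, header = TRUE, sep = .delim_char(dialect),
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = NULL,
                    fileEncoding = "UTF-8")
}

.require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# Convert a character column to numeric, reporting the offending row on
# failure.  Empty cells become NA (used for "not determined" biomass).
.to_numeric <- function(col, name) {
  col <- trimws(col)
  blank <- col == "" | toupper(col) == "NA"
  out <- suppressWarnings(as.numeric(col))
  bad <- which(!blank & is.na(out))
  if (length(bad) > 0L) {
    stop("parse error: non-numeric value '", col[bad[1L]], "' in column '",
         name, "' at data row ", bad[1L], call. = FALSE)
  }
  out[blank] <- NA_real_
  out
}

#' Read a per-sample table
#'
#' Reads the sample chemistry table (`samples.csv`) with columns
#' `sample_id, substrate, resource_C, resource_N, biomass_C, biomass_N,
#' nh4, no3`.  Resource C and N are mass fractions (% dry weight);
#' microbial biomass C and N and inorganic N are in ug per g dry weight.
#' Biomass cells may be empty ("not determined"); they are read as `NA`,
#' never as zero.  Row order is preserved.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab).
#' @return a `data.frame` with the canonical columns, validated: resource
#'   C and N strictly positive, ammonium/nitrate non-negative, substrate
#'   one of `litter`, `organic`, `mineral`.
#' @seealso [resource_cn()], [biomass_cn()], [write_sample_table()]
#' @export
read_sample_table <- function(path, dialect = "csv") {
  raw <- .read_raw(path, dialect)
  .require_columns(raw, SAMPLE_COLUMNS, "sample table")
  df <- data.frame(sample_id = trimws(raw$sample_id),
                   substrate = trimws(raw$substrate),
                   stringsAsFactors = FALSE)
  for (col in SAMPLE_COLUMNS[-(1:2)]) {
    df[[col]] <- .to_numeric(raw[[col]], col)
  }
  bad_sub <- !df$substrate %in% SUBSTRATES
  if (any(bad_sub)) {
    stop("validation error: unknown substrate '",
         df$substrate[which(bad_sub)[1L]], "' for sample_id ",
         df$sample_id[which(bad_sub)[1L]], call. = FALSE)
  }
  .check_invariant(df, is.na(df$resource_C) | df$resource_C <= 0,
                   "resource_C must be > 0")
  .check_invariant(df, is.na(df$resource_N) | df$resource_N <= 0,
                   "resource_N must be > 0")
  .check_invariant(df, !is.na(df$biomass_C) & df$biomass_C <= 0,
                   "biomass_C must be > 0 where present")
  .check_invariant(df, !is.na(df$biomass_N) & df$biomass_N <= 0,
                   "biomass_N must be > 0 where present")
  .check_invariant(df, is.na(df$nh4) | df$nh4 < 0, "nh4 must be >= 0")
  .check_invariant(df, is.na(df$no3) | df$no3 < 0, "no3 must be >= 0")
  df
}

.check_invariant <- function(df, violated, msg) {
  if (any(violated)) {
    stop("validation error: ", msg, " (sample_id: ",
         paste(df$sample_id[violated], collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Resource and biomass C:N mass ratios
#'
#' Mass-basis ratios computed on demand from a sample table.  Samples
#' lacking a biomass measurement yield `NA` from [biomass_cn()].
#'
#' @param samples a sample table as returned by [read_sample_table()].
#' @return numeric vector, one value per row.
#' @export
resource_cn <- function(samples) samples$resource_C / samples$resource_N

#' @rdname resource_cn
#' @export
biomass_cn <- function(samples) samples$biomass_C / samples$biomass_N

# 6-significant-digit serialization used by every writer
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(signif(v, 6L), format = "g", digits = 6L)
  }, character(1L))
  out
}

.write_delim <- function(df, path, dialect) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- .fmt_num(out[[col]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = .delim_char(dialect), quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("I/O error writing ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Write a per-sample table
#'
#' Inverse of [read_sample_table()]: numeric values are serialized with 6
#' significant digits, missing biomass values as empty cells.
#'
#' @inheritParams read_sample_table
#' @param samples a validated sample table.
#' @export
write_sample_table <- function(samples, path, dialect = "csv") {
  .write_delim(samples[SAMPLE_COLUMNS], path, dialect)
}

#' Read a tracer time-course table
#'
#' Reads `tracer.csv` (columns `sample_id, pool, replicate, time_min,
#' conc_ugN_gdw, atom_pct_15N`) and assembles one [tracer_series()] per
#' `(sample_id, pool)` group.  Replicates at the same time point are
#' averaged (arithmetic mean of concentration and of atom% 15N); points
#' are sorted by time.
#'
#' @inheritParams read_sample_table
#' @param natural_abundance atom% 15N of the unlabelled reference pool,
#'   attached to every series (default air-N2, 0.3663 atom%).
#' @return a named list of `tracer_series` objects; names are
#'   `"<sample_id>.<pool>"`.
#' @export
read_tracer_table <- function(path, dialect = "csv",
                              natural_abundance = 0.3663) {
  raw <- .read_raw(path, dialect)
  .require_columns(raw, TRACER_COLUMNS, "tracer table")
  df <- data.frame(sample_id = trimws(raw$sample_id),
                   pool = trimws(raw$pool),
                   stringsAsFactors = FALSE)
  df$replicate <- .to_numeric(raw$replicate, "replicate")
  df$time_min <- .to_numeric(raw$time_min, "time_min")
  df$conc <- .to_numeric(raw$conc_ugN_gdw, "conc_ugN_gdw")
  df$atom_pct <- .to_numeric(raw$atom_pct_15N, "atom_pct_15N")
  bad_pool <- !df$pool %in% POOLS
  if (any(bad_pool)) {
    stop("validation error: unknown pool '", df$pool[which(bad_pool)[1L]],
         "'", call. = FALSE)
  }
  if (any(is.na(df$time_min)) || any(df$time_min < 0)) {
    stop("validation error: time_min must be >= 0", call. = FALSE)
  }
  if (any(is.na(df$conc)) || any(df$conc <= 0)) {
    stop("validation error: conc_ugN_gdw must be > 0", call. = FALSE)
  }
  if (any(is.na(df$atom_pct)) || any(df$atom_pct <= 0) ||
      any(df$atom_pct > 100)) {
    stop("validation error: atom_pct_15N must be in (0, 100]", call. = FALSE)
  }
  key <- paste(df$sample_id, df$pool, df$replicate, df$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    grp <- df[key == dup, , drop = FALSE]
    if (nrow(unique(grp[c("conc", "atom_pct")])) > 1L) {
      stop("ambiguity error: conflicting duplicate rows for sample_id ",
           grp$sample_id[1L], ", pool ", grp$pool[1L], ", replicate ",
           grp$replicate[1L], ", time ", grp$time_min[1L], call. = FALSE)
    }
  }
  out <- list()
  for (grp in split(df, list(df$sample_id, df$pool), drop = TRUE)) {
    times <- sort(unique(grp$time_min))
    if (length(times) < 2L) {
      stop("insufficient data: sample_id ", grp$sample_id[1L], ", pool ",
           grp$pool[1L], " has a single time point", call. = FALSE)
    }
    conc <- vapply(times, function(t) mean(grp$conc[grp$time_min == t]),
                   numeric(1L))
    ape_in <- vapply(times,
                     function(t) mean(grp$atom_pct[grp$time_min == t]),
                     numeric(1L))
    nm <- paste(grp$sample_id[1L], grp$pool[1L], sep = ".")
    out[[nm]] <- tracer_series(grp$sample_id[1L], grp$pool[1L], times,
                               conc, ape_in,
                               natural_abundance = natural_abundance)
  }
  out[order(names(out))]
}

#' Write a results table
#'
#' Writes any data frame of derived quantities (sample records, rates,
#' fit summaries) as delimited text with a deterministic column order (the
#' order of `records`) and numeric values at 6 significant digits.  An
#' empty collection produces a header-only file.
#'
#' @param records a data frame.
#' @inheritParams read_sample_table
#' @export
write_results_table <- function(records, path, dialect = "csv") {
  stopifnot(is.data.frame(records))
  .write_delim(records, path, dialect)
}

#' Read back a results table written by [write_results_table()]
#'
#' Columns are type-guessed (numeric where all non-empty cells parse).
#' @inheritParams read_sample_table
#' @export
read_results_table <- function(path, dialect = "csv") {
  raw <- .read_raw(path, dialect)
  for (col in names(raw)) {
    v <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(v))
    if (!any(!is.na(v) & v != "" & is.na(num))) {
      num[v == ""] <- NA_real_
      raw[[col]] <- num
    }
  }
  raw
}
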