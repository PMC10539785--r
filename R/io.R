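#' Read a delimited intensity table
#'
#' Accepts comma- or tab-delimited text with a mandatory header. Required
#' columns: `resonance_id`, `b1_hz`, `offset_hz` (or `offset_ppm`, which
#' is converted using `spectrometer_mhz`), `t_ex_s`, `replicate`,
#' `intensity`. For R1rho decay tables an additional `delay_s` column is
#' accepted.
#'
#' @param path File path.
#' @param spectrometer_mhz Larmor frequency (MHz) for ppm conversion.
#' @return Validated data frame with offsets in Hz.
#' @export
read_intensity_table <- function(path, spectrometer_mhz = 600) {
  if (!file.exists(path)) stop("read_intensity_table: no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if ("offset_ppm" %in% names(df) && !("offset_hz" %in% names(df))) {
    df$offset_hz <- ppm_to_hz(df$offset_ppm, spectrometer_mhz)
    df$offset_ppm <- NULL
  }
  need <- c("resonance_id", "b1_hz", "offset_hz", "t_ex_s", "replicate",
            "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_intensity_table: missing column(s): ",
         paste(miss, collapse = ", "))
  num <- setdiff(need, "resonance_id")
  for (cn in c(num, intersect("delay_s", names(df)))) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v) & !is.na(df[[cn]])))
      stop("read_intensity_table: non-numeric values in column ", cn)
    if (any(is.na(v)))
      stop("read_intensity_table: missing values in column ", cn)
    df[[cn]] <- v
  }
  keycols <- intersect(c("resonance_id", "b1_hz", "offset_hz", "t_ex_s",
                         "delay_s", "replicate"), names(df))
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  if (anyDuplicated(key))
    stop("read_intensity_table: duplicate (power, offset, replicate) rows")
  df
}

#' Write an intensity table
#'
#' @param df Data frame as produced by [generate_cest_dataset()].
#' @param path Output path; `.tsv` extension selects tab delimiters.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Collects every tunable of the pipeline with its default: offset
#' windows per relaxation delay (ppm), spectrometer frequency, fractional
#' B1 inhomogeneity FWHM, the multistart grid, the model-selection weight
#' threshold, Monte Carlo iteration counts and the base seed. Entries can
#' be overridden by name.
#'
#' @param ... Named overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    spectrometer_mhz = 600,
    window_ppm_short_tex = 6,   # TEX <= 100 ms
    window_ppm_long_tex = 3,    # TEX = 400 ms
    long_tex_threshold_s = 0.2,
    inhomogeneity_fwhm = 0.1,
    weight_threshold = 0.995,
    start_grid = default_start_grid(),
    bounds = default_bounds(),
    n_refine = 4,
    n_monte_carlo = 500,
    seed = 1L,
    schema_version = "1.0")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("run_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Offset window for a relaxation delay
#'
#' Long irradiation delays need a narrower window to avoid NOE
#' artifacts.
#'
#' @param t_ex Relaxation delay (s).
#' @param config A [run_config()].
#' @return Window half-width in ppm.
#' @export
window_for_delay <- function(t_ex, config = run_config()) {
  if (t_ex >= config$long_tex_threshold_s) config$window_ppm_long_tex
  else config$window_ppm_short_tex
}

#' Serialize a fit result and selection report to JSON
#'
#' @param fit_ex,fit_noex `fit_result` objects (no-exchange may be NULL).
#' @param report Optional `selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit_ex, fit_noex = NULL, report = NULL,
                           path) {
  as_rec <- function(f) if (is.null(f)) NULL else
    list(with_exchange = f$with_exchange,
         pars = as.list(f$pars), errors = as.list(f$errors),
         rss = f$rss, n = f$n, k = f$k, r_chi2 = f$r_chi2,
         aic = f$aic, bic = f$bic, at_bound = f$at_bound,
         converged = f$converged)
  out <- list(schema_version = "1.0",
              fit_exchange = as_rec(fit_ex),
              fit_no_exchange = as_rec(fit_noex))
  if (!is.null(report))
    out$selection <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
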