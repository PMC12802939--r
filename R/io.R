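#' @keywords internal
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write CD spectra as two-column CSV
#'
#' Format: header `wavelength_nm,ellipticity_mdeg`, optional leading `#`
#' metadata lines (`# key: value`).
#'
#' @param spectrum A `cd_spectrum`.
#' @param path File path.
#' @return `write_cd_spectrum_csv` returns the path invisibly;
#'   `read_cd_spectrum_csv` returns a `cd_spectrum`.
#' @export
write_cd_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(name = spectrum$name, cation = spectrum$cation,
            temperature = spectrum$temperature)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  writeLines("wavelength_nm,ellipticity_mdeg", con)
  writeLines(sprintf("%.10g,%.10g", spectrum$wavelengths, spectrum$ellipticity), con)
  invisible(path)
}

#' @rdname write_cd_spectrum_csv
#' @export
read_cd_spectrum_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  cd_spectrum(df$wavelength_nm, df$ellipticity_mdeg,
              name = meta$name, cation = meta$cation,
              temperature = if (is.null(meta$temperature)) NULL
                            else as.numeric(meta$temperature))
}

#' Read / write melting curves as two-column CSV
#'
#' Format: `#` metadata lines carrying `wavelength` and `direction`, a header
#' `temperature_C,ellipticity_mdeg`, then one row per temperature.
#'
#' @param curve A `melting_curve`.
#' @param path File path.
#' @return `write_melting_curve_csv` returns the path invisibly;
#'   `read_melting_curve_csv` returns a `melting_curve`.
#' @export
write_melting_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength: %g", curve$wavelength), con)
  writeLines(sprintf("# direction: %s", curve$direction), con)
  writeLines("temperature_C,ellipticity_mdeg", con)
  writeLines(sprintf("%.10g,%.10g", curve$temperatures, curve$ellipticity), con)
  invisible(path)
}

#' @rdname write_melting_curve_csv
#' @export
read_melting_curve_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  wl <- meta$wavelength %||% "NA"
  melting_curve(df$temperature_C, df$ellipticity_mdeg,
                wavelength = if (wl == "NA") NA_real_ else as.numeric(wl),
                direction = meta$direction %||% "melt")
}

#' Read / write FRET traces as a long-format TSV
#'
#' Columns `molecule_id`, `frame`, `donor`, `acceptor`, with a leading
#' `# frame_interval: <seconds>` metadata line.
#'
#' @param traces List of `fret_trace` objects.
#' @param path File path.
#' @return `write_fret_traces_tsv` returns the path invisibly;
#'   `read_fret_traces_tsv` returns a list of `fret_trace` objects.
#' @export
write_fret_traces_tsv <- function(traces, path) {
  stopifnot(length(traces) >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval: %g", traces[[1]]$frame_interval), con)
  writeLines("molecule_id\tframe\tdonor\tacceptor", con)
  for (tr in traces) {
    writeLines(sprintf("%s\t%d\t%.10g\t%.10g", tr$molecule_id,
                       seq_along(tr$donor), tr$donor, tr$acceptor), con)
  }
  invisible(path)
}

#' @rdname write_fret_traces_tsv
#' @export
read_fret_traces_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  fi <- 0.1
  for (ln in meta) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2L && kv[1] == "frame_interval") fi <- as.numeric(kv[2])
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  by_mol <- split(df[order(df$frame), ], df$molecule_id[order(df$frame)])
  lapply(by_mol, function(d) {
    fret_trace(d$molecule_id[1], d$donor, d$acceptor, frame_interval = fi)
  })
}

#' Read / write cleavage measurements as TSV
#'
#' Columns `construct`, `cation`, `replicate`, `time_min`,
#' `intensity_cleaved`, `intensity_uncleaved`.
#'
#' @param timecourses List of `cleavage_timecourse` objects.
#' @param path File path.
#' @return `write_cleavage_tsv` returns the path invisibly;
#'   `read_cleavage_tsv` returns a list of `cleavage_timecourse` objects.
#' @export
write_cleavage_tsv <- function(timecourses, path) {
  df <- dplyr::bind_rows(lapply(timecourses, function(tc) {
    tibble::tibble(construct = attr(tc, "construct"),
                   cation = attr(tc, "cation"),
                   replicate = attr(tc, "replicate"),
                   time_min = tc$time_min,
                   intensity_cleaved = tc$intensity_cleaved,
                   intensity_uncleaved = tc$intensity_uncleaved)
  }))
  write_table_tsv(df, path)
}

#' @rdname write_cleavage_tsv
#' @export
read_cleavage_tsv <- function(path) {
  df <- utils::read.delim(path)
  keys <- unique(df[c("construct", "cation", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- merge(keys[i, ], df)
    d <- d[order(d$time_min), ]
    cleavage_timecourse(keys$construct[i], keys$cation[i], keys$replicate[i],
                        d$time_min, d$intensity_cleaved, d$intensity_uncleaved)
  })
}

#' Run configuration: defaults, file parsing, validation
#'
#' A flat namespaced key-value text file (`key = value` per line, `#`
#' comments) overriding the documented defaults of every stage parameter.
#' Validation happens before any computation; unknown keys and out-of-range
#' values are errors.
#'
#' @param path Optional config file path.
#' @param overrides Named list applied after the file (e.g. from a script's
#'   command line).
#' @return A named list with class `run_config`; numeric-looking values are
#'   converted. Keys: `seed`, every [synth_config()] field, plus
#'   `fret.threshold`, `fret.min_dwell`, `fret.bin_width`, `cd.threshold`,
#'   `cd.share_min`, `cd.tolerance`, `cleave.nd_as_zero`, `out_dir`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- c(
    as.list(synth_config()),
    list(fret.threshold = 0.6, fret.min_dwell = 5, fret.bin_width = 0.02,
         cd.threshold = 0.75, cd.share_min = 0.2, cd.tolerance = 8,
         cleave.nd_as_zero = TRUE, out_dir = "results")
  )
  cfg <- defaults
  set_kv <- function(cfg, key, value) {
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
    if (is.character(value)) {
      num <- suppressWarnings(as.numeric(value))
      if (!is.na(num)) value <- num
      else if (value %in% c("TRUE", "FALSE", "true", "false")) {
        value <- toupper(value) == "TRUE"
      }
    }
    cfg[[key]] <- value
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "\\s*=\\s*")[[1]]
      if (length(kv) != 2L) {
        stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
      }
      cfg <- set_kv(cfg, kv[1], kv[2])
    }
  }
  for (k in names(overrides)) cfg <- set_kv(cfg, k, overrides[[k]])
  # range checks before any computation
  validate_synth_config(cfg)
  if (cfg$fret.threshold <= 0 || cfg$fret.threshold >= 1) {
    stop("fret.threshold must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$fret.min_dwell < 1) stop("fret.min_dwell must be >= 1", call. = FALSE)
  if (cfg$fret.bin_width <= 0) stop("fret.bin_width must be > 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Synthetic-generator configuration carried by a run config
#'
#' @param cfg A `run_config`.
#' @return A `synth_config` built from the matching keys of `cfg`.
#' @export
as_synth_config <- function(cfg) {
  keys <- names(formals(synth_config))
  do.call(synth_config, cfg[keys])
}

#' Provenance record for a run
#'
#' Everything needed to reproduce a run: the full parameter set, its hash,
#' the seed, and package/R versions. Written alongside every stage output by
#' the analysis drivers.
#'
#' @param cfg A `run_config`.
#' @param path Optional path; when given, the record is written as JSON.
#' @return The provenance list, invisibly when written.
#' @export
provenance_record <- function(cfg, path = NULL) {
  plain <- unclass(cfg)
  canonical <- paste(
    names(plain),
    vapply(plain, function(v) paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = ";"
  )
  codes <- utf8ToInt(canonical)
  rec <- list(
    config = plain,
    config_hash = sprintf("%08x",
                          sum(codes * (seq_along(codes) %% 97 + 1)) %%
                            .Machine$integer.max),
    seed = plain$seed,
    package_version = as.character(utils::packageVersion("teloG4")),
    r_version = as.character(getRversion())
  )
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rec))
  }
  rec
}
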