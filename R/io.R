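.schemas <- list(
  kill_curve = c("time_min", "od600"),
  event_table = c("cell_id", "species", "progeny_count"),
  size_table = c("species", "prey_length", "bdelloplast_diameter")
)

#' Read a typed CSV table
#'
#' CSV dialect: comma-separated, '.' decimal, UTF-8, header required.
#' The header is checked against the schema and every numeric cell is
#' parsed with row/column error reporting; the returned table is validated
#' by the matching constructor ([kill_curve()], [event_table()],
#' [size_table()]).  In event tables the `progeny_lengths` column holds
#' semicolon-separated micrometre values.
#'
#' @param path CSV file path.
#' @param schema one of `"kill_curve"`, `"event_table"`, `"size_table"`.
#' @return the validated, classed table.
#' @export
read_table <- function(path, schema = c("kill_curve", "event_table", "size_table")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- .schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s file '%s' is missing column(s) %s", schema, path,
                 paste(sprintf("'%s'", missing), collapse = ", ")))
  }
  char_cols <- c("cell_id", "species", "replicate", "progeny_lengths")
  for (col in setdiff(names(df), char_cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      stop(sprintf("unparseable value '%s' at row %d, column '%s' of %s",
                   df[[col]][bad[1L]], bad[1L], col, path))
    }
    df[[col]] <- v
  }
  switch(schema,
    kill_curve = kill_curve(df$time_min, df$od600,
                            species = df$species, replicate = df$replicate),
    event_table = {
      if ("progeny_lengths" %in% names(df)) {
        df$progeny_lengths <- lapply(strsplit(df$progeny_lengths, ";", fixed = TRUE),
                                     as.numeric)
      }
      event_table(df)
    },
    size_table = size_table(df)
  )
}

#' Write a typed table as CSV
#'
#' Inverse of [read_table()]: `write_table` then `read_table` round-trips
#' all values.
#'
#' @param x a `kill_curve`, `event_table` or `size_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  if ("progeny_lengths" %in% names(df)) {
    df$progeny_lengths <- vapply(
      df$progeny_lengths,
      function(v) paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                        collapse = ";"),
      character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Ties the stages together reproducibly for a set of prey species: load
#' parameters, run the infection simulation to complete lysis, project the
#' trajectory onto the 20-min OD600 grid, fit the four-parameter Weibull
#' and compute EKT50, generate a synthetic single-cell event table and
#' summarize it, and generate the calibrated prey-size table and its pooled
#' correlation.  All outputs are written under `out_dir` together with a
#' run manifest (command, configuration echo, seed, package version, MD5
#' digest of every output file, timestamp).  Identical configurations and
#' seeds give identical numeric outputs.
#'
#' @param species prey species to process.
#' @param seed RNG seed for the synthetic stages.
#' @param n_cells cells per species for the synthetic event/size tables.
#' @param out_dir output directory (created if needed).
#' @param od_top,od_floor OD600 scale of the projection.
#' @param verbose print stage progress.
#' @return invisibly, a list with `lysis_times`, `ekt50`, `event_summary`,
#'   `size_r`, `manifest`, `files`.
#' @export
pipeline_run <- function(species = c("P_mirabilis", "S_enterica", "S_flexneri"),
                         seed = 1L, n_cells = 100L,
                         out_dir = tempfile("bdellosim_run_"),
                         od_top = 1.0, od_floor = 0.05, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table(x, path)
    files <<- c(files, path)
    path
  }

  lysis <- ekt50 <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    params <- tryCatch(load_prey_params(sp), error = function(e) stop_stage("params", e))
    say("simulate: %s", sp)
    traj <- tryCatch(simulate_predation(params),
                     error = function(e) stop_stage("simulate", e))
    lysis[sp] <- complete_lysis_time(traj)
    tdf <- as.data.frame(traj)
    tp <- file.path(out_dir, sprintf("trajectory_%s.csv", sp))
    utils::write.csv(tdf, tp, row.names = FALSE, quote = FALSE)
    files <- c(files, tp)
    say("fit kill curve: %s", sp)
    kc <- od_projection(traj, od_top, od_floor,
                        times = seq(0, max(2520, max(traj$t_min)), by = 20))
    emit(kc, sprintf("killcurve_%s.csv", sp))
    fit <- tryCatch(fit_weibull4(kc), error = function(e) stop_stage("fit", e))
    ekt50[sp] <- if (fit$converged) ekt(fit) else NA_real_
    fp <- file.path(out_dir, sprintf("weibull_%s.json", sp))
    jsonlite::write_json(
      list(species = sp, b = fit$b, c = fit$c, d = fit$d, e = fit$e,
           rss = fit$rss, EKT50 = ekt50[[sp]], converged = fit$converged),
      fp, auto_unbox = TRUE, digits = NA)
    files <- c(files, fp)
  }

  say("generate + summarize synthetic single-cell data")
  cfg <- generator_config(species = species, n_cells = n_cells, seed = seed)
  events <- tryCatch(gen_event_table(cfg),
                     error = function(e) stop_stage("generate", e))
  emit(events, "events.csv")
  summary_df <- tryCatch(summarize_events(events),
                         error = function(e) stop_stage("summarize", e))
  sp_path <- file.path(out_dir, "event_summary.csv")
  utils::write.csv(summary_df, sp_path, row.names = FALSE, quote = FALSE)
  files <- c(files, sp_path)

  sizes <- gen_size_table(cfg)
  emit(sizes, "sizes.csv")
  size_r <- pearson_r(sizes$prey_length, sizes$bdelloplast_diameter)

  manifest <- list(
    command = "pipeline_run",
    config = list(species = species, seed = seed, n_cells = n_cells,
                  od_top = od_top, od_floor = od_floor),
    seed = seed,
    package_version = as.character(utils::packageVersion("bdellosim")),
    lysis_times_min = as.list(lysis),
    ekt50_min = as.list(ekt50),
    pooled_size_correlation = size_r,
    file_digests = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(lysis_times = lysis, ekt50 = ekt50,
                 event_summary = summary_df, size_r = size_r,
                 manifest = manifest, files = c(files, mp)))
}
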