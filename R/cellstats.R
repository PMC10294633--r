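#' Event-timing table columns
#'
#' Appearance-time keys (`t_*`, minutes since bdelloplast formation) are
#' temporally ordered within the replication/segregation chain and the
#' division chain; duration keys (`d_*`) are only required to be positive.
#' @keywords internal
#' @noRd
.timing_keys <- c("t_dnaN1", "t_parB2", "d_oric_migration", "t_dnaN2",
                  "t_parB3", "t_dnaN3", "t_parB4", "t_ftsZ1", "t_ftsZ2",
                  "t_ftsZ3", "d_ftsZ", "d_replication", "t_release")
.chain_rep <- c("t_dnaN1", "t_parB2", "t_dnaN2", "t_parB3", "t_dnaN3", "t_parB4")
.chain_div <- c("t_ftsZ1", "t_ftsZ2", "t_ftsZ3", "t_release")

#' Construct and validate a per-cell event table
#'
#' One row per observed predator filament: the species of the prey it grew
#' in, the timing of cell-cycle events (appearance of DnaN/ParB/FtsZ foci,
#' progeny release) in minutes since bdelloplast formation, the number of
#' progeny released, and optionally the lengths of those progeny.  Missing
#' events (e.g. no 3rd DnaN focus in binary-dividing cells) are `NA`, never
#' zero.
#'
#' @param df data frame with columns `cell_id`, `species`, `progeny_count`,
#'   any subset of the timing columns (`t_dnaN1`, `t_parB2`,
#'   `d_oric_migration`, `t_dnaN2`, `t_parB3`, `t_dnaN3`, `t_parB4`,
#'   `t_ftsZ1`, `t_ftsZ2`, `t_ftsZ3`, `d_ftsZ`, `d_replication`,
#'   `t_release`), and optionally a list column `progeny_lengths`
#'   (micrometres).
#' @return the validated data frame, classed `event_table`.
#' @export
event_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("cell_id", "species", "progeny_count")) {
    if (!col %in% names(df)) stop(sprintf("event table missing column '%s'", col))
  }
  pc <- df$progeny_count
  if (any(!is.finite(pc)) || any(pc < 2) || any(pc != round(pc))) {
    stop("progeny_count must be integers >= 2")
  }
  present <- intersect(.timing_keys, names(df))
  for (col in present) {
    v <- df[[col]]
    if (any(v[!is.na(v)] < 0)) stop(sprintf("column '%s' has negative times", col))
  }
  for (chain in list(.chain_rep, .chain_div)) {
    cols <- intersect(chain, present)
    if (length(cols) < 2L) next
    m <- as.matrix(df[cols])
    bad <- apply(m, 1L, function(r) {
      r <- r[!is.na(r)]
      length(r) >= 2L && any(diff(r) <= 0)
    })
    if (any(bad)) {
      stop(sprintf("event ordering violated in row(s) %s (chain %s)",
                   paste(utils::head(which(bad), 5L), collapse = ", "),
                   paste(cols, collapse = " < ")))
    }
  }
  if ("progeny_lengths" %in% names(df) && !is.list(df$progeny_lengths)) {
    stop("progeny_lengths must be a list column of numeric vectors")
  }
  structure(df, class = unique(c("event_table", class(df))))
}

#' Summarize event timings per species
#'
#' Applies [mean_ci95()] per species and event over the non-missing
#' entries, reconstructing the published-style timing tables (mean, 95% CI
#' half-width, back-derived SD, and the `n` actually used).  Events with
#' fewer than two observations in a species are omitted with a warning,
#' never fabricated.
#'
#' @param table an [event_table()].
#' @param events which timing columns to summarize (default: all present).
#' @return data frame with columns `species`, `event`, `mean`, `ci95_half`,
#'   `sd`, `n`.
#' @export
summarize_events <- function(table, events = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (nrow(table) == 0L) stop("event table is empty")
  events <- events %||% intersect(.timing_keys, names(table))
  out <- list()
  for (sp in unique(table$species)) {
    sub <- table[table$species == sp, , drop = FALSE]
    for (ev in events) {
      v <- sub[[ev]]
      v <- v[!is.na(v)]
      if (length(v) < 2L) {
        if (length(v) > 0L) {
          warning(sprintf("event '%s' in %s has n < 2; omitted", ev, sp))
        }
        next
      }
      s <- mean_ci95(v)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, event = ev, mean = s$mean, ci95_half = s$ci95_half,
        sd = s$sd, n = s$n, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no event with at least 2 observations")
  do.call(rbind, out)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length `>= 3` with non-zero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6))  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Empirical progeny-count distribution per species
#'
#' @param table an [event_table()].
#' @return named list (one entry per species) of lists with fields `pmf`
#'   (named numeric, probabilities by progeny count), `mean`, `counts`
#'   (raw tallies) and `n`.
#' @export
progeny_distribution <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (nrow(table) == 0L) stop("event table is empty")
  lapply(split(table$progeny_count, table$species), function(pc) {
    tab <- table(pc)
    pmf <- as.numeric(tab) / length(pc)
    names(pmf) <- names(tab)
    list(pmf = pmf, mean = mean(pc), counts = as.integer(tab), n = length(pc))
  })
}

#' Progeny-length summary per species
#'
#' Pools all measured progeny lengths within each species and summarizes
#' them with [mean_ci95()].
#'
#' @param table an [event_table()] with a `progeny_lengths` list column.
#' @return named list of [summary_stat()] objects, one per species.
#' @export
progeny_length_stats <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (!"progeny_lengths" %in% names(table)) {
    stop("event table has no progeny_lengths column")
  }
  lapply(split(table$progeny_lengths, table$species), function(lst) {
    mean_ci95(unlist(lst))
  })
}

#' Construct and validate a prey-size table
#'
#' Paired measurements of the prey cell length before infection and the
#' diameter of the bdelloplast it rounds into.
#'
#' @param df data frame with columns `species`, `prey_length`,
#'   `bdelloplast_diameter` (micrometres, positive).
#' @return the validated data frame, classed `size_table`.
#' @export
size_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("species", "prey_length", "bdelloplast_diameter")) {
    if (!col %in% names(df)) stop(sprintf("size table missing column '%s'", col))
  }
  if (any(df$prey_length <= 0) || any(df$bdelloplast_diameter <= 0)) {
    stop("lengths and diameters must be positive")
  }
  structure(df, class = unique(c("size_table", class(df))))
}
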