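#' @noRd
.species_codes <- c("P_mirabilis", "S_enterica", "S_flexneri", "E_coli")

# Per-prey constants as printed in the source study.  Event timings are
# minutes since bdelloplast formation; `t_*` keys are appearance times and
# `d_*` keys durations.  All timing summaries were computed over n = 100
# predator filaments; `+/-` values are 95% CI half-widths of the mean.
.build_registry <- function() {
  ss <- function(m, h, n = 100L) summary_stat(m, h, n)
  list(
    P_mirabilis = list(
      species = "P_mirabilis",
      cells_per_ml_at_od1 = 1.5e9,
      culture_volume_ml = 0.28,
      predator_inoculum = 2.1e7,
      progeny_pmf = c(`2` = 1.0),
      lifecycle = ss(252, 7),
      event_timings = list(
        t_dnaN1 = ss(46, 4),
        t_parB2 = ss(69, 4),
        d_oric_migration = ss(19, 2),
        t_dnaN2 = ss(79, 6),
        t_ftsZ1 = ss(165, 4),
        d_ftsZ = ss(49, 3),
        d_replication = ss(144, 7),
        t_release = ss(252, 7)
      ),
      progeny_length = ss(1.25, 0.03)
    ),
    S_enterica = list(
      species = "S_enterica",
      cells_per_ml_at_od1 = 9.5e8,
      culture_volume_ml = 0.28,
      predator_inoculum = 2.1e7,
      # two to five progeny, usually 3 or 4; frequencies chosen so the mean
      # is 3.5 (the value under which the simulator reproduces the printed
      # complete-lysis time)
      progeny_pmf = c(`2` = 0.1, `3` = 0.4, `4` = 0.4, `5` = 0.1),
      lifecycle = ss(288, 7),
      event_timings = list(
        t_dnaN1 = ss(46, 5),
        t_parB2 = ss(65, 5),
        d_oric_migration = ss(18, 2),
        t_dnaN2 = ss(119, 7),
        t_parB3 = ss(138, 8),
        t_dnaN3 = ss(163, 9),
        t_parB4 = ss(182, 10),
        t_ftsZ1 = ss(217, 5),
        t_ftsZ2 = ss(225, 6),
        t_ftsZ3 = ss(244, 6),
        d_ftsZ = ss(52, 6),
        t_release = ss(288, 7)
      ),
      progeny_length = ss(1.16, 0.03)
    ),
    S_flexneri = list(
      species = "S_flexneri",
      cells_per_ml_at_od1 = 3e8,
      culture_volume_ml = 0.28,
      predator_inoculum = 2.1e7,
      # four to eight progeny, usually 5 to 7; mean 6.0
      progeny_pmf = c(`4` = 0.1, `5` = 0.25, `6` = 0.3, `7` = 0.25, `8` = 0.1),
      lifecycle = ss(379, 11),
      event_timings = list(
        t_dnaN1 = ss(44, 5),
        t_parB2 = ss(76, 6),
        d_oric_migration = ss(17, 2),
        t_dnaN2 = ss(128, 7),
        t_parB3 = ss(144, 7),
        t_dnaN3 = ss(191, 9),
        t_parB4 = ss(211, 8),
        t_ftsZ1 = ss(310, 9),
        # FtsZ foci beyond the first, and their duration, were not
        # determinable in this prey (long twisted filaments): left absent.
        t_release = ss(379, 11)
      ),
      progeny_length = ss(1.35, 0.03)
    ),
    E_coli = list(
      # model prey: only progeny counts ("usually 3 or 4") and progeny
      # length were measured; no timing entries, no OD conversion.
      species = "E_coli",
      cells_per_ml_at_od1 = NA_real_,
      culture_volume_ml = 0.28,
      predator_inoculum = 2.1e7,
      progeny_pmf = c(`3` = 0.5, `4` = 0.5),
      lifecycle = NULL,
      event_timings = list(),
      progeny_length = ss(1.11, 0.04)
    )
  )
}

.registry_env <- new.env(parent = emptyenv())

.registry <- function() {
  if (is.null(.registry_env$reg)) .registry_env$reg <- .build_registry()
  .registry_env$reg
}

.finalize_prey_params <- function(p) {
  p$progeny_mean <- sum(as.numeric(names(p$progeny_pmf)) * p$progeny_pmf)
  p$cycle_step_min <- if (is.null(p$lifecycle)) {
    NA_real_
  } else {
    round(p$lifecycle$mean / 10) * 10
  }
  p$ftsZ_duration <- p$event_timings$d_ftsZ
  structure(p, class = "prey_params")
}

#' Load the parameter bundle for a prey species
#'
#' Typed registry of per-prey constants: the OD600-to-cell-count conversion,
#' the killing-curve culture geometry (0.28 mL of prey suspension, predator
#' inoculum 2.1e7 cells), the progeny-count distribution, the life-cycle
#' duration, and the single-cell event timings (appearance of replisome /
#' segrosome / divisome markers, all in minutes since bdelloplast formation).
#' `cycle_step_min` is the life-cycle mean rounded to the nearest 10 min
#' (250 / 290 / 380 for the three pathogens); it is the step duration of the
#' infection simulator.  The `E_coli` entry carries only progeny counts and
#' progeny length; its timing entries are absent.
#'
#' @param species one of `"P_mirabilis"`, `"S_enterica"`, `"S_flexneri"`,
#'   `"E_coli"`, or any name if `overrides` supplies a complete bundle.
#' @param overrides optional named list overriding registry fields.  Summary
#'   statistics are given as `list(mean=, ci95_half=, n=)`; the progeny pmf
#'   as a named numeric vector/list (names = progeny counts, values =
#'   probabilities).
#' @return a validated object of class `prey_params`.
#' @examples
#' load_prey_params("P_mirabilis")$cells_per_ml_at_od1  # 1.5e9
#' load_prey_params("S_flexneri")$lifecycle$mean        # 379
#' @export
load_prey_params <- function(species, overrides = NULL) {
  reg <- .registry()
  if (species %in% names(reg)) {
    base <- prey_params_to_list(.finalize_prey_params(reg[[species]]))
  } else if (is.null(overrides)) {
    stop(sprintf("unknown prey species '%s'; known species: %s",
                 species, paste(names(reg), collapse = ", ")))
  } else {
    base <- list(species = species)
  }
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    # a progeny pmf is replaced wholesale (merging two pmfs is meaningless);
    # event_timings and other nested lists merge entry-wise
    if ("progeny_pmf" %in% names(overrides)) base$progeny_pmf <- NULL
    base <- utils::modifyList(base, overrides, keep.null = TRUE)
    base$species <- base$species %||% species
  }
  prey_params_from_list(base)
}

# serializable plain-list form (summary stats as mean/ci95_half/n triples)
ss_to_list <- function(s) {
  if (is.null(s)) NULL else list(mean = s$mean, ci95_half = s$ci95_half, n = s$n)
}
ss_from_list <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  for (f in c("mean", "ci95_half", "n")) {
    if (is.null(x[[f]])) stop(sprintf("incomplete summary stat '%s': missing field '%s'", what, f))
  }
  summary_stat(x$mean, x$ci95_half, x$n)
}

#' @rdname load_prey_params
#' @param params a `prey_params` object.
#' @export
prey_params_to_list <- function(params) {
  list(
    species = params$species,
    cells_per_ml_at_od1 = params$cells_per_ml_at_od1,
    culture_volume_ml = params$culture_volume_ml,
    predator_inoculum = params$predator_inoculum,
    progeny_pmf = as.list(params$progeny_pmf),
    lifecycle = ss_to_list(params$lifecycle),
    event_timings = lapply(params$event_timings, ss_to_list),
    progeny_length = ss_to_list(params$progeny_length)
  )
}

#' @rdname load_prey_params
#' @param x a plain list as produced by [prey_params_to_list()] (or parsed
#'   from JSON).
#' @export
prey_params_from_list <- function(x) {
  required <- c("species", "culture_volume_ml", "predator_inoculum",
                "progeny_pmf", "progeny_length")
  missing <- setdiff(required, names(x)[!vapply(x, is.null, logical(1))])
  if (length(missing) > 0) {
    stop(sprintf("incomplete prey parameter bundle: missing field(s) %s",
                 paste(sprintf("'%s'", missing), collapse = ", ")))
  }
  pmf <- unlist(x$progeny_pmf)
  p <- list(
    species = x$species,
    cells_per_ml_at_od1 = x$cells_per_ml_at_od1 %||% NA_real_,
    culture_volume_ml = x$culture_volume_ml,
    predator_inoculum = x$predator_inoculum,
    progeny_pmf = pmf,
    lifecycle = if (inherits(x$lifecycle, "summary_stat")) x$lifecycle else ss_from_list(x$lifecycle, "lifecycle"),
    event_timings = Filter(Negate(is.null), lapply(
      stats::setNames(nm = names(x$event_timings %||% list())),
      function(e) {
        s <- x$event_timings[[e]]
        if (inherits(s, "summary_stat")) s else ss_from_list(s, e)
      }
    )),
    progeny_length = if (inherits(x$progeny_length, "summary_stat")) x$progeny_length else ss_from_list(x$progeny_length, "progeny_length")
  )
  validate_prey_params(.finalize_prey_params(p))
}

#' Validate a prey parameter bundle
#'
#' Checks the structural invariants: the progeny pmf sums to 1 over a
#' positive-integer support, the stored progeny mean matches the pmf, the
#' simulator step is the life-cycle mean rounded to the nearest 10 minutes,
#' and every summary statistic is finite with positive `n`.
#'
#' @param params object of class `prey_params`.
#' @return `params`, invisibly usable, after validation (errors otherwise).
#' @export
validate_prey_params <- function(params) {
  stopifnot(inherits(params, "prey_params"))
  pmf <- params$progeny_pmf
  k <- suppressWarnings(as.numeric(names(pmf)))
  if (any(is.na(k)) || any(k <= 0) || any(k != round(k))) {
    stop("progeny_pmf support must be positive integers")
  }
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-12) {
    stop("progeny_pmf probabilities must be >= 0 and sum to 1")
  }
  if (abs(params$progeny_mean - sum(k * pmf)) > 1e-9) {
    stop("progeny_mean inconsistent with progeny_pmf")
  }
  if (!is.null(params$lifecycle) &&
      abs(params$cycle_step_min - round(params$lifecycle$mean / 10) * 10) > 1e-9) {
    stop("cycle_step_min must be the life-cycle mean rounded to the nearest 10 min")
  }
  for (s in c(list(params$lifecycle, params$progeny_length), params$event_timings)) {
    if (is.null(s)) next
    if (!inherits(s, "summary_stat")) stop("timing entries must be summary_stat objects")
    if (s$n <= 0 || s$ci95_half < 0 || !is.finite(s$mean)) {
      stop("summary statistics must have n > 0, ci95_half >= 0, finite mean")
    }
  }
  params
}

#' @export
print.prey_params <- function(x, ...) {
  cat(sprintf("<prey_params: %s>\n", x$species))
  cat(sprintf("  cells/mL at OD600 = 1.0 : %g\n", x$cells_per_ml_at_od1))
  cat(sprintf("  culture volume          : %g mL\n", x$culture_volume_ml))
  cat(sprintf("  predator inoculum       : %g cells\n", x$predator_inoculum))
  cat(sprintf("  progeny mean            : %g  (pmf over {%s})\n",
              x$progeny_mean, paste(names(x$progeny_pmf), collapse = ",")))
  if (!is.null(x$lifecycle)) {
    cat(sprintf("  life cycle              : %s min (step %g min)\n",
                format(x$lifecycle), x$cycle_step_min))
  }
  if (length(x$event_timings) > 0) {
    cat(sprintf("  event timings           : %s\n",
                paste(names(x$event_timings), collapse = ", ")))
  }
  cat(sprintf("  progeny length          : %s um\n", format(x$progeny_length)))
  invisible(x)
}

#' Read or write a prey parameter bundle as JSON
#'
#' @param params a `prey_params` object.
#' @param path file path.
#' @return `write_prey_params` returns `path` invisibly; `read_prey_params`
#'   returns a validated `prey_params` object.
#' @export
write_prey_params <- function(params, path) {
  stopifnot(inherits(params, "prey_params"))
  jsonlite::write_json(prey_params_to_list(params), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_prey_params
#' @export
read_prey_params <- function(path) {
  prey_params_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
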