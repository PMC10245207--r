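#' Validate the survey input tables
#'
#' Checks the two CSV schemas the pipeline consumes — `nodules.csv`
#' (`nest_id`, `genus`, `clade`, `diameter_mm`) and `nests.csv` (`nest_id`,
#' `genus`, `clade`, `density_per_g`, `head_width_<k>_mm`) — and collects
#' every violation: missing columns, non-numeric cells, nonpositive
#' diameters or head widths, negative densities, duplicated nests, and nests
#' present in one table but absent from the other. Row numbers refer to data
#' rows; `line` is the corresponding file line (header = line 1).
#'
#' @param nodules,nests Paths to the two CSV files, or data frames already in
#'   the matching schemas.
#' @return A tibble of violations (`table`, `row`, `line`, `column`,
#'   `message`) of class `table_validation`, with attribute `ok = TRUE` when
#'   empty.
#' @export
validate_tables <- function(nodules, nests) {
  problems <- list()
  note <- function(table, row, column, message) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      table = table, row = as.integer(row),
      line = as.integer(row) + 1L, column = column, message = message
    )
  }

  load_table <- function(x, reader, table) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        note(table, NA, NA_character_, sprintf("file not found: %s", x))
        return(NULL)
      }
      df <- suppressWarnings(reader(x))
      probs <- readr::problems(df)
      if (nrow(probs)) {
        for (i in seq_len(nrow(probs))) {
          note(table, probs$row[i], names(df)[probs$col[i]] %||% NA_character_,
               sprintf("expected %s, got %s", probs$expected[i], probs$actual[i]))
        }
      }
      df
    } else {
      tibble::as_tibble(x)
    }
  }

  nod <- load_table(nodules, read_nodules, "nodules")
  nst <- load_table(nests, read_nests, "nests")

  if (!is.null(nod)) {
    miss <- setdiff(c("nest_id", "genus", "clade", "diameter_mm"), names(nod))
    for (m in miss) note("nodules", NA, m, "required column missing")
    if ("diameter_mm" %in% names(nod)) {
      bad <- which(is.na(nod$diameter_mm) | nod$diameter_mm <= 0)
      for (i in bad) {
        note("nodules", i, "diameter_mm",
             sprintf("diameter must be a positive number (got %s)",
                     format(nod$diameter_mm[i])))
      }
    }
  }
  if (!is.null(nst)) {
    miss <- setdiff(c("nest_id", "genus", "clade", "density_per_g"), names(nst))
    for (m in miss) note("nests", NA, m, "required column missing")
    hw_cols <- grep("^head_width_\\d+_mm$", names(nst), value = TRUE)
    if (!length(hw_cols)) {
      note("nests", NA, "head_width_1_mm", "no head_width_<k>_mm columns found")
    }
    if ("density_per_g" %in% names(nst)) {
      bad <- which(is.na(nst$density_per_g) | nst$density_per_g < 0)
      for (i in bad) {
        note("nests", i, "density_per_g",
             sprintf("density must be a nonnegative number (got %s)",
                     format(nst$density_per_g[i])))
      }
    }
    for (hc in hw_cols) {
      bad <- which(is.na(nst[[hc]]) | nst[[hc]] <= 0)
      for (i in bad) {
        note("nests", i, hc, "head width must be a positive number")
      }
    }
    if ("nest_id" %in% names(nst)) {
      dup <- which(duplicated(nst$nest_id))
      for (i in dup) {
        note("nests", i, "nest_id",
             sprintf("duplicated nest_id %s", nst$nest_id[i]))
      }
    }
  }
  if (!is.null(nod) && !is.null(nst) &&
      all(c("nest_id") %in% names(nod)) && all(c("nest_id") %in% names(nst))) {
    orphan_nod <- setdiff(unique(nod$nest_id), nst$nest_id)
    for (id in orphan_nod) {
      note("nodules", match(id, nod$nest_id), "nest_id",
           sprintf("nest %s has nodule measurements but no nest record", id))
    }
    orphan_nst <- setdiff(nst$nest_id, unique(nod$nest_id))
    for (id in orphan_nst) {
      note("nests", match(id, nst$nest_id), "nest_id",
           sprintf("nest %s has a record but no nodule measurements", id))
    }
  }

  out <- if (length(problems)) dplyr::bind_rows(problems) else {
    tibble::tibble(table = character(), row = integer(), line = integer(),
                   column = character(), message = character())
  }
  structure(out, ok = nrow(out) == 0,
            class = c("table_validation", class(out)))
}

#' @export
print.table_validation <- function(x, ...) {
  if (attr(x, "ok")) {
    cat("Tables valid: no violations.\n")
  } else {
    cat(sprintf("%d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s:%s [%s] %s\n", x$table[i],
                  ifelse(is.na(x$line[i]), "-", x$line[i]),
                  ifelse(is.na(x$column[i]), "-", x$column[i]), x$message[i]))
    }
  }
  invisible(x)
}

#' Run the full trait-matching analysis
#'
#' End-to-end orchestration of the analysis stages, in order: per-nest trait
#' quantification, per-clade summaries, the isoquant production-limit fit,
#' the three one-way ANOVAs, and the head-width correlations. Deterministic
#' given its inputs; running twice writes byte-identical reports.
#'
#' @param nodules,nests Paths to the two CSVs (validated before reading) or
#'   data frames in the matching schemas.
#' @param out_dir Optional directory; when given, writes `nest_traits.csv`,
#'   `clade_summary.csv`, `isoquant_fit.csv`, `group_stats.csv`,
#'   `correlations.csv`, `report.json` (floats at 12 significant digits) and
#'   a human-readable `summary.txt`.
#' @param response Isoquant response variable, see [fit_isoquant()].
#' @param cv_method Clade diameter-CV method, see [clade_summary()].
#' @param expected_nodules,strict_nodule_count Passed to [nest_traits()].
#' @param transform Correlation standardisation, see [trait_correlations()].
#' @param seed Optional integer recorded in provenance (the analysis itself
#'   draws no random numbers; the seed documents how simulated inputs were
#'   produced).
#' @return An object of class `pipeline_report`: a list with `nest_traits`,
#'   `clade_summaries`, `isoquant` (an `isoquant_fit`), `anovas`,
#'   `correlations` and `provenance`.
#' @export
run_pipeline <- function(nodules, nests, out_dir = NULL,
                         response = "density",
                         cv_method = "nest_means",
                         expected_nodules = 50,
                         strict_nodule_count = FALSE,
                         transform = "log1p",
                         seed = NULL) {
  from_files <- is.character(nodules) && is.character(nests)
  check <- validate_tables(nodules, nests)
  if (!attr(check, "ok")) {
    lines <- utils::capture.output(print(check))
    abort(paste(c("input validation failed:", head(lines, 12)),
                collapse = "\n"))
  }
  if (from_files) {
    src <- c(nodules = nodules, nests = nests)
    nodules <- read_nodules(nodules)
    nests <- read_nests(nests)
    input_id <- as.list(tools::md5sum(src))
  } else {
    nodules <- tibble::as_tibble(nodules)
    nests <- tibble::as_tibble(nests)
    input_id <- list(nodules = rlang::hash(nodules),
                     nests = rlang::hash(nests))
  }

  traits <- nest_traits(nodules, nests, expected_nodules = expected_nodules,
                        strict_nodule_count = strict_nodule_count)
  clades <- clade_summary(traits, nodules = nodules, cv_method = cv_method)
  iso <- fit_isoquant(traits, response = response)
  anovas <- trait_anovas(traits)
  corrs <- trait_correlations(traits, transform = transform)

  report <- structure(
    list(
      nest_traits = traits,
      clade_summaries = clades,
      isoquant = iso,
      anovas = anovas,
      correlations = corrs,
      provenance = list(
        input = input_id,
        seed = if (is.null(seed)) "none" else as.integer(seed),
        options = list(response = response, cv_method = cv_method,
                       transform = transform,
                       strict_nodule_count = strict_nodule_count),
        tool = "noduletrade",
        version = as.character(packageVersion("noduletrade"))
      )
    ),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_as_list <- function(report) {
  drop_lists <- function(df) dplyr::select(df, dplyr::where(is.atomic))
  list(
    clade_summaries = report$clade_summaries,
    isoquant = tidy(report$isoquant) |>
      dplyr::bind_cols(glance(report$isoquant)[c("n", "sse", "method",
                                                 "response")]),
    anovas = drop_lists(report$anovas),
    correlations = report$correlations,
    provenance = report$provenance
  )
}

#' Write a pipeline report to disk
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  drop_lists <- function(df) dplyr::select(df, dplyr::where(is.atomic))

  paths <- c(
    nest_traits = file.path(out_dir, "nest_traits.csv"),
    clade_summary = file.path(out_dir, "clade_summary.csv"),
    isoquant_fit = file.path(out_dir, "isoquant_fit.csv"),
    group_stats = file.path(out_dir, "group_stats.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    report = file.path(out_dir, "report.json"),
    summary = file.path(out_dir, "summary.txt")
  )
  readr::write_csv(report$nest_traits, paths[["nest_traits"]])
  readr::write_csv(report$clade_summaries, paths[["clade_summary"]])
  iso <- report$isoquant
  readr::write_csv(
    tibble::tibble(method = iso$method, response = iso$response,
                   L_hat = iso$L_hat, se_L = iso$se_L, t_stat = iso$t_stat,
                   p_value = iso$p_value, n = iso$n, sse = iso$sse),
    paths[["isoquant_fit"]]
  )
  readr::write_csv(drop_lists(report$anovas), paths[["group_stats"]])
  readr::write_csv(report$correlations, paths[["correlations"]])

  json <- jsonlite::toJSON(report_as_list(report), dataframe = "rows",
                           digits = I(12), pretty = TRUE, auto_unbox = TRUE,
                           na = "null")
  writeLines(json, paths[["report"]])
  writeLines(utils::capture.output(print(report)), paths[["summary"]])
  invisible(paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Nodule trait-matching analysis ==\n")
  cat(sprintf("%d nests, %d clades\n", nrow(x$nest_traits),
              nrow(x$clade_summaries)))
  cat("\nPer-clade summaries:\n")
  print(as.data.frame(x$clade_summaries), digits = 4, row.names = FALSE)
  cat("\nIsoquant production limit:\n")
  print(x$isoquant)
  cat("\nOne-way ANOVAs (nest-level):\n")
  print(as.data.frame(dplyr::select(x$anovas, -dplyr::any_of("group_means"))),
        digits = 4, row.names = FALSE)
  cat("\nHead-width correlations:\n")
  print(as.data.frame(x$correlations), digits = 4, row.names = FALSE)
  invisible(x)
}
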