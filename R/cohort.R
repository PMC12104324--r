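#' Read a patient cohort table
#'
#' Reads a cohort CSV in the flattened layout `modality_side_level` (for
#' example `pathology_ipsi_II`, `imaging_contra_III`), together with the
#' per-patient columns `id`, `t_category` and `midline_extension`.
#' Involvement cells are parsed to a tri-state (involved / healthy /
#' missing); unparseable cells become missing and their count is reported as
#' a warning. The early/advanced T-group and the consensus involvement
#' status (pathology overriding imaging) are derived on read unless the file
#' already carries `consensus_*` columns.
#'
#' @param path path to a CSV file.
#' @param graph a [lymph_graph()]; defines the expected levels.
#' @return A `lymph_cohort` data.frame: one row per patient with columns
#'   `id`, `t_category`, `t_group`, `midline_extension` and, per side and
#'   level, any modality columns present plus derived
#'   `consensus_<side>_<level>` columns.
#' @export
read_cohort <- function(path, graph = lymph_graph()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  mandatory <- c("id", "t_category", "midline_extension")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  as_cohort(raw, graph)
}

#' Assemble a cohort from a data.frame
#'
#' @param df data.frame in the [read_cohort()] column layout.
#' @param graph a [lymph_graph()].
#' @return A `lymph_cohort` data.frame.
#' @export
as_cohort <- function(df, graph = lymph_graph()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate patient ids")
  out <- data.frame(id = as.character(df$id), stringsAsFactors = FALSE)
  out$t_category <- suppressWarnings(as.integer(df$t_category))
  out$t_group <- vapply(out$t_category, assign_t_group, character(1))
  out$midline_extension <- parse_tristate(df$midline_extension)$value
  n_bad <- 0L
  status_cols <- grep("^(pathology|imaging|consensus)_(ipsi|contra)_", names(df),
                      value = TRUE)
  for (cl in status_cols) {
    parsed <- parse_tristate(df[[cl]])
    out[[cl]] <- parsed$value
    n_bad <- n_bad + parsed$n_bad
  }
  if (n_bad > 0L) {
    warning(n_bad, " unparseable involvement cell(s) treated as missing")
  }
  out <- add_consensus(out, graph)
  class(out) <- c("lymph_cohort", "data.frame")
  out
}

# tri-state parser: TRUE/FALSE/NA from the spellings seen in cohort files
parse_tristate <- function(x) {
  if (is.logical(x)) return(list(value = x, n_bad = 0L))
  s <- trimws(tolower(as.character(x)))
  value <- rep(NA, length(s))
  value[s %in% c("true", "t", "1", "yes")] <- TRUE
  value[s %in% c("false", "f", "0", "no")] <- FALSE
  known <- s %in% c("true", "t", "1", "yes", "false", "f", "0", "no",
                    "", "na", "none", "nan")
  list(value = value, n_bad = sum(!known))
}

#' Early/advanced T-group from the T-category
#'
#' T1 and T2 tumors form the early group, T3 and T4 the advanced group;
#' other categories are outside the model's domain.
#'
#' @param t_category integer 1-4.
#' @return `"early"` or `"advanced"`.
#' @examples
#' assign_t_group(2)
#' @export
assign_t_group <- function(t_category) {
  if (length(t_category) != 1L || is.na(t_category) ||
      !t_category %in% 1:4) {
    stop("T-category must be 1, 2, 3 or 4 (got ",
         deparse(t_category), ")")
  }
  if (t_category <= 2) "early" else "advanced"
}

# derive consensus_<side>_<level>: pathology wins where reported, then
# imaging; an existing consensus column is kept as supplied
add_consensus <- function(df, graph) {
  for (side in c("ipsi", "contra")) {
    for (lv in graph$lnl_names) {
      con_col <- paste0("consensus_", side, "_", lv)
      if (con_col %in% names(df)) next
      pat <- df[[paste0("pathology_", side, "_", lv)]]
      img <- df[[paste0("imaging_", side, "_", lv)]]
      n <- nrow(df)
      if (is.null(pat)) pat <- rep(NA, n)
      if (is.null(img)) img <- rep(NA, n)
      df[[con_col]] <- ifelse(!is.na(pat), pat, img)
    }
  }
  df
}

#' Consensus involvement for a single record
#'
#' Pathological findings are the gold standard and override any conflicting
#' clinical diagnosis; for levels without pathology, the imaging finding is
#' used; otherwise the status is missing.
#'
#' @param pathology,imaging per-level tri-state vectors (`TRUE`/`FALSE`/`NA`).
#' @return Per-level consensus tri-state vector.
#' @examples
#' consensus_involvement(pathology = c(FALSE, NA), imaging = c(TRUE, TRUE))
#' @export
consensus_involvement <- function(pathology, imaging) {
  if (length(pathology) != length(imaging)) {
    stop("modality vectors must have equal length")
  }
  ifelse(!is.na(pathology), pathology, imaging)
}

#' Write a cohort table
#'
#' @param cohort a `lymph_cohort` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cohort summary counts
#'
#' @param cohort a `lymph_cohort` data.frame.
#' @param graph a [lymph_graph()].
#' @return List with the number of patients, the fraction with no involved
#'   level on consensus (N0), the early-T fraction, and the
#'   midline-extension fraction (among known).
#' @export
cohort_summary <- function(cohort, graph = lymph_graph()) {
  df <- as.data.frame(cohort)
  cols <- c(paste0("consensus_ipsi_", graph$lnl_names),
            paste0("consensus_contra_", graph$lnl_names))
  cols <- intersect(cols, names(df))
  inv <- as.matrix(df[cols]) == TRUE
  n0 <- rowSums(inv, na.rm = TRUE) == 0
  list(
    n = nrow(df),
    frac_n0 = mean(n0),
    frac_early = mean(df$t_group == "early"),
    frac_midline = mean(df$midline_extension, na.rm = TRUE)
  )
}

#' @export
print.lymph_cohort <- function(x, n = 5L, ...) {
  if (nrow(x) == 0L) {
    cat("Lymphatic involvement cohort: 0 patients\n")
    return(invisible(x))
  }
  s <- cohort_summary(x)
  cat(sprintf(
    "Lymphatic involvement cohort: %d patients (%.0f%% N0, %.0f%% early T, %.0f%% midline extension)\n",
    s$n, 100 * s$frac_n0, 100 * s$frac_early, 100 * s$frac_midline))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more patients\n")
  invisible(x)
}
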