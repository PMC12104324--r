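#' Read a model configuration file
#'
#' YAML layout:
#' ```yaml
#' graph:
#'   lnls: [I, II, III, IV, V, VII]
#'   tumor_arcs: [I, II, III, IV, V, VII]   # optional, defaults to all
#'   lnl_arcs: [[I, II], [II, III], [III, IV], [IV, V]]
#' t_max: 10
#' p_early: 0.3
#' modalities:
#'   imaging: {sensitivity: 0.81, specificity: 0.76}
#' ```
#' Modalities listed in the file override or extend the built-in table.
#'
#' @param path path to a YAML file.
#' @return List with `graph` (a [lymph_graph()]), `t_max`, `p_early`, and
#'   `modalities` (a [modality_table()]-shaped data.frame).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gr <- cfg$graph
  if (is.null(gr$lnls)) stop("config lacks graph$lnls")
  arcs <- if (is.null(gr$lnl_arcs)) default_lnl_arcs(unlist(gr$lnls)) else
    do.call(rbind, lapply(gr$lnl_arcs, unlist))
  graph <- lymph_graph(
    lnl_names = unlist(gr$lnls),
    tumor_arcs = if (is.null(gr$tumor_arcs)) unlist(gr$lnls) else unlist(gr$tumor_arcs),
    lnl_arcs = arcs
  )
  modalities <- modality_table()
  for (nm in names(cfg$modalities)) {
    row <- cfg$modalities[[nm]]
    i <- match(nm, modalities$modality)
    if (is.na(i)) {
      modalities <- rbind(modalities, data.frame(
        modality = nm, sensitivity = row$sensitivity,
        specificity = row$specificity))
    } else {
      modalities$sensitivity[i] <- row$sensitivity
      modalities$specificity[i] <- row$specificity
    }
  }
  list(
    graph = graph,
    t_max = if (is.null(cfg$t_max)) 10L else as.integer(cfg$t_max),
    p_early = if (is.null(cfg$p_early)) 0.3 else as.numeric(cfg$p_early),
    modalities = modalities
  )
}

#' Read a diagnosis scenario file
#'
#' YAML layout:
#' ```yaml
#' t_group: advanced
#' midline_extension: true
#' ipsi_involved: [II, III, IV]
#' contra_involved: [II]
#' fna_contra: [II]
#' ```
#'
#' @param path path to a YAML file.
#' @param graph a [lymph_graph()].
#' @return A [risk_scenario()].
#' @export
read_scenario <- function(path, graph = lymph_graph()) {
  cfg <- yaml::read_yaml(path)
  risk_scenario(
    t_group = cfg$t_group,
    midline_extension = if (is.null(cfg$midline_extension)) FALSE else
      cfg$midline_extension,
    ipsi_involved = as.character(unlist(cfg$ipsi_involved)),
    contra_involved = as.character(unlist(cfg$contra_involved)),
    fna_ipsi = as.character(unlist(cfg$fna_ipsi)),
    fna_contra = as.character(unlist(cfg$fna_contra)),
    assume_negative = if (is.null(cfg$assume_negative)) TRUE else
      cfg$assume_negative,
    graph = graph
  )
}

#' Store posterior draws as CSV
#'
#' Writes the retained draws with their parameter names plus a small header
#' of run metadata as comment lines (`# key: value`).
#'
#' @param fit a `lymph_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "lymph_fit"))
  meta <- c(
    sprintf("# seed: %s", ifelse(is.null(fit$seed), "NA", fit$seed)),
    sprintf("# n_walkers: %d", fit$n_walkers),
    sprintf("# burn_in: %d", fit$burn_in),
    sprintf("# accept_frac: %.4f", fit$accept_frac),
    sprintf("# converged: %s", fit$converged)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(fit$draws), con, row.names = FALSE)
  invisible(path)
}

#' Read stored posterior draws
#'
#' @param path CSV written by [write_draws()].
#' @return Matrix of draws with parameter-name columns; run metadata in
#'   `attr(, "meta")`.
#' @export
read_draws <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  m <- as.matrix(df)
  meta <- stats::setNames(
    lapply(meta_lines, function(l) sub("^# [^:]+: ", "", l)),
    sub("^# ([^:]+):.*$", "\\1", meta_lines)
  )
  attr(m, "meta") <- meta
  m
}
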