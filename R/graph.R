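#' Lymphatic drainage graph
#'
#' Defines the directed acyclic graph (DAG) that parameterizes lymphatic
#' spread: the primary tumor seeds a set of lymph node levels (LNLs) directly,
#' and involved LNLs can seed their efferent neighbours. The default graph is
#' the cervical drainage chain used for oropharyngeal tumors: levels I, II,
#' III, IV, V and VII all receive direct tumor spread, and efferent arcs run
#' I->II, II->III, III->IV and IV->V.
#'
#' The level order is fixed and shared by all matrices built from the graph:
#' states are enumerated by binary counting with the first level as the most
#' significant bit (see [lnl_states()]).
#'
#' @param lnl_names character vector of level labels, in fixed order.
#' @param tumor_arcs levels that receive direct spread from the primary tumor.
#' @param lnl_arcs two-column character matrix (or data.frame) of directed
#'   (parent, child) arcs between levels.
#' @return An object of class `lymph_graph` with elements `lnl_names`,
#'   `tumor_arcs`, `lnl_arcs` and `parents` (per-level parent indices).
#' @examples
#' g <- lymph_graph()
#' g$lnl_names
#' @export
lymph_graph <- function(lnl_names = c("I", "II", "III", "IV", "V", "VII"),
                        tumor_arcs = lnl_names,
                        lnl_arcs = default_lnl_arcs(lnl_names)) {
  lnl_names <- as.character(lnl_names)
  if (anyDuplicated(lnl_names)) stop("duplicated LNL names")
  if (is.null(lnl_arcs) || length(lnl_arcs) == 0L) {
    lnl_arcs <- matrix(character(0), 0L, 2L)
  }
  lnl_arcs <- as.matrix(lnl_arcs)
  if (ncol(lnl_arcs) != 2L) stop("`lnl_arcs` must have two columns (parent, child)")
  colnames(lnl_arcs) <- c("parent", "child")
  unknown <- setdiff(c(tumor_arcs, as.vector(lnl_arcs)), lnl_names)
  if (length(unknown)) {
    stop("arc endpoints not declared as LNLs: ", paste(unknown, collapse = ", "))
  }
  assert_acyclic(lnl_arcs, lnl_names)
  parents <- lapply(lnl_names, function(v) {
    match(lnl_arcs[lnl_arcs[, "child"] == v, "parent"], lnl_names)
  })
  names(parents) <- lnl_names
  structure(
    list(
      lnl_names = lnl_names,
      tumor_arcs = as.character(tumor_arcs),
      lnl_arcs = lnl_arcs,
      parents = parents
    ),
    class = "lymph_graph"
  )
}

default_lnl_arcs <- function(lnl_names) {
  chain <- c("I", "II", "III", "IV", "V")
  keep <- chain[chain %in% lnl_names]
  if (length(keep) < 2L) return(matrix(character(0), 0L, 2L))
  cbind(parent = keep[-length(keep)], child = keep[-1L])
}

assert_acyclic <- function(arcs, lnl_names) {
  # Kahn's algorithm on the level-to-level arcs
  indeg <- stats::setNames(integer(length(lnl_names)), lnl_names)
  for (ch in arcs[, "child"]) indeg[ch] <- indeg[ch] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ch <- arcs[arcs[, "parent"] == v, "child"]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen != length(lnl_names)) stop("lymph node arcs contain a cycle")
  invisible(TRUE)
}

#' @export
print.lymph_graph <- function(x, ...) {
  cat("Lymphatic drainage graph\n")
  cat("  LNLs: ", paste(x$lnl_names, collapse = ", "), "\n", sep = "")
  cat("  tumor -> {", paste(x$tumor_arcs, collapse = ", "), "}\n", sep = "")
  if (nrow(x$lnl_arcs)) {
    cat("  arcs:  ",
        paste(paste(x$lnl_arcs[, 1], x$lnl_arcs[, 2], sep = " -> "),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate binary involvement states
#'
#' All `2^V` involvement patterns over `V` lymph node levels, enumerated by
#' binary counting with the first level as the most significant bit. The first
#' state is all-healthy, the last all-involved.
#'
#' @param num_lnls number of levels `V` (>= 0).
#' @return Integer matrix with `2^V` rows and `V` columns of 0/1 entries.
#' @examples
#' lnl_states(2)
#' @export
lnl_states <- function(num_lnls) {
  V <- as.integer(num_lnls)
  if (is.na(V) || V < 0L) stop("`num_lnls` must be a nonnegative integer")
  n <- 2L^V
  if (V == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  s <- matrix(0L, n, V)
  idx <- 0:(n - 1L)
  for (v in seq_len(V)) {
    s[, v] <- bitwAnd(bitwShiftR(idx, V - v), 1L)
  }
  s
}

# index vector (logical) of states in which `level` is involved
state_has_level <- function(states, level_idx) {
  states[, level_idx] == 1L
}
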