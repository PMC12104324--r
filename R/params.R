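#' Bilateral model parameters
#'
#' Bundles the full parameter set of the bilateral progression model:
#' per-level probabilities of direct tumor spread to the ipsilateral neck,
#' per-level probabilities of direct tumor spread to the contralateral neck
#' while the tumor is lateralized, a mixing weight that interpolates the
#' contralateral rates towards the ipsilateral ones once the tumor crosses the
#' mid-sagittal plane, arc spread probabilities shared by both sides, the
#' binomial diagnosis-time parameter for advanced T-category, and the per-step
#' probability of midline crossing. The early T-category time parameter and
#' the number of time steps are fixed model constants.
#'
#' @param graph a [lymph_graph()].
#' @param ipsi_spread named numeric vector (one per level): per-step
#'   probability of direct tumor spread to each ipsilateral LNL.
#' @param contra_spread named numeric vector: per-step probability of direct
#'   tumor spread to each contralateral LNL while the tumor is lateralized.
#' @param mixing scalar in \[0,1\]; once the tumor extends over the midline,
#'   contralateral tumor-spread rates become
#'   `mixing * ipsi_spread + (1 - mixing) * contra_spread`.
#' @param arc_spread named numeric vector, one per (parent, child) arc, named
#'   `"parent->child"`: per-step probability of spread along that arc, shared
#'   by both sides of the neck.
#' @param p_adv binomial success probability of the diagnosis-time prior for
#'   advanced (T3/T4) tumors.
#' @param midline_prob per-step probability that a lateralized tumor grows
#'   over the mid-sagittal plane.
#' @param p_early fixed binomial parameter of the early (T1/T2) time prior.
#' @param t_max fixed number of time steps the model evolves over.
#' @return An object of class `lymph_params`.
#' @seealso [ref_params()] for reference estimates, [as_theta()] for the flat
#'   vector used by the sampler.
#' @export
lymph_params <- function(graph, ipsi_spread, contra_spread, mixing, arc_spread,
                         p_adv, midline_prob, p_early = 0.3, t_max = 10L) {
  stopifnot(inherits(graph, "lymph_graph"))
  lnl <- graph$lnl_names
  ipsi_spread <- check_level_probs(ipsi_spread, lnl, "ipsi_spread")
  contra_spread <- check_level_probs(contra_spread, lnl, "contra_spread")
  arc_nm <- arc_names(graph)
  arc_spread <- check_level_probs(arc_spread, arc_nm, "arc_spread")
  for (p in list(mixing = mixing, p_adv = p_adv, midline_prob = midline_prob,
                 p_early = p_early)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("scalar parameters must be single probabilities in [0, 1]")
    }
  }
  t_max <- as.integer(t_max)
  if (t_max < 0L) stop("`t_max` must be >= 0")
  structure(
    list(
      graph = graph,
      ipsi_spread = ipsi_spread,
      contra_spread = contra_spread,
      mixing = as.numeric(mixing),
      arc_spread = arc_spread,
      p_adv = as.numeric(p_adv),
      midline_prob = as.numeric(midline_prob),
      p_early = as.numeric(p_early),
      t_max = t_max
    ),
    class = "lymph_params"
  )
}

check_level_probs <- function(x, expected_names, what) {
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) != length(expected_names)) {
      stop("`", what, "` must have one value per entry: ",
           paste(expected_names, collapse = ", "))
    }
    names(x) <- expected_names
  }
  if (!setequal(names(x), expected_names)) {
    stop("`", what, "` names must be exactly: ",
         paste(expected_names, collapse = ", "))
  }
  x <- x[expected_names]
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`", what, "` entries must be probabilities in [0, 1]")
  }
  x
}

arc_names <- function(graph) {
  if (!nrow(graph$lnl_arcs)) return(character(0))
  paste0(graph$lnl_arcs[, "parent"], "->", graph$lnl_arcs[, "child"])
}

#' Contralateral tumor-spread rates after midline crossing
#'
#' Linear interpolation between the lateralized contralateral rates and the
#' ipsilateral rates: once the tumor extends over the mid-sagittal plane, its
#' contralateral seeding behaves more like ipsilateral seeding.
#'
#' @param params a [lymph_params()] object.
#' @return Named numeric vector of per-level spread probabilities.
#' @export
mixed_contra_spread <- function(params) {
  stopifnot(inherits(params, "lymph_params"))
  params$mixing * params$ipsi_spread +
    (1 - params$mixing) * params$contra_spread
}

#' @export
print.lymph_params <- function(x, ...) {
  cat("Bilateral lymphatic progression parameters (",
      length(as_theta(x)), " free)\n", sep = "")
  fmt <- function(v) paste(sprintf("%s=%.4f", names(v), v), collapse = " ")
  cat("  ipsi tumor spread:   ", fmt(x$ipsi_spread), "\n", sep = "")
  cat("  contra tumor spread: ", fmt(x$contra_spread), "\n", sep = "")
  cat("  midline mixing:      ", sprintf("%.4f", x$mixing), "\n", sep = "")
  cat("  arc spread:          ", fmt(x$arc_spread), "\n", sep = "")
  cat(sprintf("  p_early=%.2f (fixed)  p_adv=%.4f  midline_prob=%.4f  t_max=%d\n",
              x$p_early, x$p_adv, x$midline_prob, x$t_max))
  invisible(x)
}

#' Names of the free parameter vector
#'
#' Fixed serialization order used by the sampler and for stored draws:
#' ipsilateral tumor-spread rates, lateralized contralateral rates, the
#' midline mixing weight, arc-spread rates, the advanced-T time parameter and
#' the per-step midline-crossing probability.
#'
#' @param graph a [lymph_graph()].
#' @return Character vector of parameter names.
#' @export
theta_names <- function(graph) {
  arcs <- arc_names(graph)
  c(paste0("ipsi_", graph$lnl_names),
    paste0("contra_", graph$lnl_names),
    "mixing",
    if (length(arcs)) paste0("arc_", sub("->", "_", arcs, fixed = TRUE)),
    "p_adv", "midline_prob")
}

#' Flatten parameters to the sampler vector
#'
#' @param params a [lymph_params()] object.
#' @return Named numeric vector in [theta_names()] order.
#' @export
as_theta <- function(params) {
  stopifnot(inherits(params, "lymph_params"))
  stats::setNames(
    c(params$ipsi_spread, params$contra_spread, params$mixing,
      params$arc_spread, params$p_adv, params$midline_prob),
    theta_names(params$graph)
  )
}

#' Rebuild parameters from a flat vector
#'
#' Inverse of [as_theta()]. Fixed constants (`p_early`, `t_max`) are taken
#' from the arguments, not the vector.
#'
#' @param theta numeric vector in [theta_names()] order.
#' @inheritParams lymph_params
#' @return A [lymph_params()] object.
#' @export
theta_to_params <- function(theta, graph, p_early = 0.3, t_max = 10L) {
  V <- length(graph$lnl_names)
  nA <- nrow(graph$lnl_arcs)
  expect_len <- 2L * V + 1L + nA + 2L
  if (length(theta) != expect_len) {
    stop("expected a parameter vector of length ", expect_len,
         ", got ", length(theta))
  }
  theta <- as.numeric(theta)
  lymph_params(
    graph,
    ipsi_spread = stats::setNames(theta[seq_len(V)], graph$lnl_names),
    contra_spread = stats::setNames(theta[V + seq_len(V)], graph$lnl_names),
    mixing = theta[2L * V + 1L],
    arc_spread = stats::setNames(theta[2L * V + 1L + seq_len(nA)], arc_names(graph)),
    p_adv = theta[2L * V + nA + 2L],
    midline_prob = theta[2L * V + nA + 3L],
    p_early = p_early,
    t_max = t_max
  )
}

#' Reference parameter estimates for oropharyngeal carcinoma
#'
#' Posterior-mean spread estimates for the default six-level drainage graph,
#' obtained from a four-institution cohort of 833 oropharyngeal squamous cell
#' carcinoma patients. These serve as defaults for risk prediction and as the
#' generating truth for synthetic cohorts.
#'
#' @param graph a [lymph_graph()]; must be the default six-level graph.
#' @return A [lymph_params()] object.
#' @examples
#' ref_params()
#' @export
ref_params <- function(graph = lymph_graph()) {
  expected <- c("I", "II", "III", "IV", "V", "VII")
  if (!identical(graph$lnl_names, expected)) {
    stop("reference estimates are only available for the default six-level graph")
  }
  lymph_params(
    graph,
    ipsi_spread = c(I = 0.0280, II = 0.3489, III = 0.0545, IV = 0.0094,
                    V = 0.0183, VII = 0.0232),
    contra_spread = c(I = 0.0029, II = 0.0246, III = 0.0014, IV = 0.0019,
                      V = 0.0005, VII = 0.0050),
    mixing = 0.3387,
    arc_spread = c("I->II" = 0.6250, "II->III" = 0.1423,
                   "III->IV" = 0.1586, "IV->V" = 0.1458),
    p_adv = 0.4498,
    midline_prob = 0.0816
  )
}
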