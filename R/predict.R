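#' Diagnostic modality table
#'
#' Sensitivity and specificity of the supported diagnostic modalities.
#' Consensus and pathology findings are treated as perfect; imaging (CT, MRI,
#' PET-CT) detects nodal involvement with sensitivity 0.81 and specificity
#' 0.76; fine needle aspiration (FNA) with sensitivity 0.80 and specificity
#' 0.98.
#'
#' @return A data.frame with columns `modality`, `sensitivity`, `specificity`.
#' @export
modality_table <- function() {
  data.frame(
    modality = c("consensus", "pathology", "imaging", "FNA"),
    sensitivity = c(1, 1, 0.81, 0.80),
    specificity = c(1, 1, 0.76, 0.98),
    stringsAsFactors = FALSE
  )
}

modality_lookup <- function(names, modalities = modality_table()) {
  i <- match(names, modalities$modality)
  if (anyNA(i)) {
    stop("unknown modality: ", paste(unique(names[is.na(i)]), collapse = ", "))
  }
  list(sensitivity = modalities$sensitivity[i],
       specificity = modalities$specificity[i])
}

#' Construct a clinical diagnosis scenario
#'
#' Describes one patient's clinical presentation for risk prediction:
#' T-group, midline-extension status, and the per-side per-level findings
#' with the modality that produced them. Following common reporting
#' conventions, all levels not listed as involved are assumed clinically
#' negative on imaging (including any level later queried for occult
#' disease); set `assume_negative = FALSE` to leave unmentioned levels
#' unexamined instead.
#'
#' @param t_group `"early"` or `"advanced"`.
#' @param midline_extension `TRUE`, `FALSE` or `NA` (unknown; marginalized).
#' @param ipsi_involved,contra_involved level labels with a positive finding.
#' @param fna_ipsi,fna_contra level labels whose finding (positive or
#'   negative) comes from fine needle aspiration instead of imaging.
#' @param assume_negative if `TRUE`, unmentioned levels are diagnosed
#'   negative by imaging; if `FALSE` they are left unexamined.
#' @param graph a [lymph_graph()].
#' @param modalities modality table, see [modality_table()].
#' @return An object of class `risk_scenario` holding per-side status and
#'   confusion vectors.
#' @examples
#' risk_scenario("early", FALSE, ipsi_involved = "II")
#' @export
risk_scenario <- function(t_group, midline_extension = FALSE,
                          ipsi_involved = character(),
                          contra_involved = character(),
                          fna_ipsi = character(), fna_contra = character(),
                          assume_negative = TRUE,
                          graph = lymph_graph(),
                          modalities = modality_table()) {
  t_group <- match.arg(t_group, c("early", "advanced"))
  lnl <- graph$lnl_names
  side <- function(involved, fna) {
    bad <- setdiff(c(involved, fna), lnl)
    if (length(bad)) stop("unknown LNL(s): ", paste(bad, collapse = ", "))
    status <- stats::setNames(
      if (assume_negative) rep(0, length(lnl)) else rep(NA_real_, length(lnl)),
      lnl
    )
    status[involved] <- 1
    mod <- stats::setNames(rep("imaging", length(lnl)), lnl)
    mod[fna] <- "FNA"
    conf <- modality_lookup(mod, modalities)
    list(status = status, modality = mod,
         sensitivity = conf$sensitivity, specificity = conf$specificity)
  }
  structure(
    list(
      t_group = t_group,
      midline_extension = midline_extension,
      ipsi = side(ipsi_involved, fna_ipsi),
      contra = side(contra_involved, fna_contra),
      graph = graph
    ),
    class = "risk_scenario"
  )
}

#' @export
print.risk_scenario <- function(x, ...) {
  show <- function(s) {
    lab <- ifelse(is.na(s$status), "?", ifelse(s$status == 1, "+", "-"))
    fna <- ifelse(s$modality == "FNA", "(FNA)", "")
    paste(paste0(names(s$status), lab, fna), collapse = " ")
  }
  cat("Diagnosis scenario: ", x$t_group, " T-category, midline extension ",
      ifelse(is.na(x$midline_extension), "unknown", x$midline_extension),
      "\n", sep = "")
  cat("  ipsi:   ", show(x$ipsi), "\n", sep = "")
  cat("  contra: ", show(x$contra), "\n", sep = "")
  invisible(x)
}

scenario_joint <- function(scenario, engine) {
  if (is.na(scenario$midline_extension)) {
    engine_joint(engine, scenario$t_group, FALSE) +
      engine_joint(engine, scenario$t_group, TRUE)
  } else {
    engine_joint(engine, scenario$t_group, scenario$midline_extension)
  }
}

#' Posterior over true bilateral involvement given a diagnosis
#'
#' Bayesian inversion of the observation model: the joint posterior over all
#' pairs of true (ipsilateral, contralateral) involvement states given the
#' scenario's clinical findings, the per-level modality confusion values, and
#' the model prior for the scenario's T-group and midline status.
#'
#' @param scenario a [risk_scenario()].
#' @param params a [lymph_params()] object.
#' @return A `2^V x 2^V` matrix of posterior probabilities summing to one;
#'   rows index ipsilateral states, columns contralateral states.
#' @export
posterior_involvement <- function(scenario, params) {
  stopifnot(inherits(scenario, "risk_scenario"))
  engine <- if (inherits(params, "progression_engine")) params
            else progression_engine(params)
  M <- scenario_joint(scenario, engine)
  oi <- diagnosis_factor(scenario$ipsi$status, scenario$ipsi$sensitivity,
                         scenario$ipsi$specificity)
  oc <- diagnosis_factor(scenario$contra$status, scenario$contra$sensitivity,
                         scenario$contra$specificity)
  post <- (oi * M) * rep(oc, each = nrow(M))
  norm <- sum(post)
  if (norm <= 0) stop("diagnosis has zero probability under the model")
  post / norm
}

#' Marginal risk of true involvement in one level
#'
#' The posterior probability that a chosen level truly harbors disease given
#' the clinical diagnosis — the occult-disease risk when that level was
#' diagnosed negative. With a matrix of posterior parameter draws the risk is
#' evaluated per draw, giving a histogram of risks.
#'
#' @param scenario a [risk_scenario()].
#' @param params a [lymph_params()] object, or a matrix of flat parameter
#'   vectors (one row per posterior draw) in [theta_names()] order.
#' @param side `"ipsi"` or `"contra"`.
#' @param level level label to query.
#' @param graph graph used to rebuild parameters from draws.
#' @return For a single parameter set, a scalar probability. For draws, a
#'   list with `mean` and the per-draw `risks`.
#' @export
marginal_risk <- function(scenario, params, side = "contra", level = "II",
                          graph = lymph_graph()) {
  side <- match.arg(side, c("ipsi", "contra"))
  if (is.matrix(params)) {
    risks <- apply(params, 1L, function(th) {
      marginal_risk(scenario, theta_to_params(th, graph), side, level)
    })
    return(list(mean = mean(risks), risks = risks))
  }
  stopifnot(inherits(params, "lymph_params") ||
              inherits(params, "progression_engine"))
  g <- if (inherits(params, "lymph_params")) params$graph else params$graph
  v <- match(level, g$lnl_names)
  if (is.na(v)) stop("unknown level: ", level)
  status <- scenario[[side]]$status[[level]]
  if (!is.na(status) && status == 1) {
    message("queried level ", side, " ", level,
            " is diagnosed involved; this is not an occult-disease query")
  }
  post <- posterior_involvement(scenario, params)
  inv <- state_has_level(lnl_states(length(g$lnl_names)), v)
  if (side == "ipsi") sum(post[inv, ]) else sum(post[, inv])
}

#' Model-predicted prevalence of an involvement pattern
#'
#' The conditional probability, under the model prior, that the true
#' involvement matches a pattern, given T-group and midline-extension status.
#' Pattern entries are 1 (involved), 0 (healthy) or `NA` (masked, i.e.
#' marginalized over). This is the quantity compared against observed cohort
#' prevalences.
#'
#' @param params a [lymph_params()], or a matrix of parameter draws.
#' @param t_group `"early"` or `"advanced"`.
#' @param midline_extension logical.
#' @param ipsi,contra named per-level pattern vectors (default: all masked).
#' @param graph graph used to rebuild parameters from draws.
#' @return A probability, or for draws a list with `mean` and `values`.
#' @export
predicted_prevalence <- function(params, t_group, midline_extension,
                                 ipsi = NULL, contra = NULL,
                                 graph = lymph_graph()) {
  if (is.matrix(params)) {
    values <- apply(params, 1L, function(th) {
      predicted_prevalence(theta_to_params(th, graph), t_group,
                           midline_extension, ipsi, contra)
    })
    return(list(mean = mean(values), values = values))
  }
  stopifnot(inherits(params, "lymph_params"))
  g <- params$graph
  pat <- function(x) {
    full <- stats::setNames(rep(NA_real_, length(g$lnl_names)), g$lnl_names)
    if (!is.null(x)) {
      bad <- setdiff(names(x), g$lnl_names)
      if (length(bad)) stop("unknown LNL(s): ", paste(bad, collapse = ", "))
      full[names(x)] <- as.numeric(x)
    }
    full
  }
  oi <- diagnosis_factor(pat(ipsi))
  oc <- diagnosis_factor(pat(contra))
  M <- joint_state_dist(params, t_group, midline_extension)
  denom <- sum(M)
  if (denom <= 0) {
    stop("requested (T-group, midline) slice has zero probability")
  }
  as.numeric(oi %*% M %*% oc) / denom
}

#' Beta posterior over an observed prevalence
#'
#' With a uniform prior over the unknown prevalence `q` and a binomial
#' likelihood for `k` involved out of `n` patients, the posterior over `q`
#' is `Beta(k + 1, n - k + 1)`, with mode `k / n`.
#'
#' @param k number of patients exhibiting the pattern.
#' @param n total number of patients in the scenario.
#' @return List with `shape1`, `shape2`, `mode`, `mean`, and `density`
#'   (a function of `q`).
#' @examples
#' prevalence_posterior(27, 379)$mode  # ~0.071
#' @export
prevalence_posterior <- function(k, n) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  shape1 <- k + 1
  shape2 <- n - k + 1
  mode <- if (n > 0) k / n else NA_real_
  list(
    shape1 = shape1,
    shape2 = shape2,
    mode = mode,
    mean = shape1 / (shape1 + shape2),
    density = function(q) stats::dbeta(q, shape1, shape2)
  )
}
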