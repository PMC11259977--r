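#' Relaxed-clock configuration
#'
#' Two relaxed clocks are supported. Under the independent log-normal clock
#' (ILN) each branch rate is an iid log-normal draw with mean `mu_r` (the
#' log-normal is mean-corrected: `log r ~ N(log mu_r - sigma2/2, sigma2)`).
#' Under the geometric-Brownian-motion clock (GBM) rates are attached to
#' nodes and the log-rate of a child node is normal around the parent's
#' log-rate with variance `sigma2 * dt`, `dt` the age difference between
#' the two nodes, again mean-corrected so `E[r_child | r_parent] =
#' r_parent`.
#'
#' @param model `"ILN"` or `"GBM"`.
#' @param mu_r Mean rate (substitutions/site/100 Myr).
#' @param sigma2 Rate-variance parameter: log-variance per branch (ILN) or
#'   per 100 Myr (GBM).
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(model = c("ILN", "GBM"), mu_r = 0.05, sigma2 = 0.1) {
  model <- match.arg(model)
  stopifnot(mu_r > 0, sigma2 >= 0)
  structure(list(model = model, mu_r = mu_r, sigma2 = sigma2),
            class = "clock_config")
}

#' Independent log-normal clock log prior
#'
#' @param branch_rates Positive branch rates (canonical branch order).
#' @param cfg A [clock_config()] (field `model` is not consulted; the ILN
#'   density is evaluated).
#' @return Sum of mean-corrected log-normal log densities.
#' @export
iln_log_prior <- function(branch_rates, cfg) {
  stopifnot(inherits(cfg, "clock_config"))
  if (any(branch_rates <= 0)) return(-Inf)
  if (cfg$sigma2 == 0)
    return(if (all(abs(branch_rates - cfg$mu_r) < 1e-12)) Inf else -Inf)
  sum(dlnorm(branch_rates, meanlog = log(cfg$mu_r) - cfg$sigma2 / 2,
             sdlog = sqrt(cfg$sigma2), log = TRUE))
}

#' Geometric-Brownian-motion clock log prior
#'
#' Rates live on nodes; the root-node rate is governed by the locus-rate
#' prior and is not scored here. Each non-root node contributes a
#' mean-corrected log-normal term with variance `sigma2 * dt`, where `dt`
#' is the parent-minus-child age difference (the time separating the two
#' rate realizations). A zero `dt` is a point mass at the parent rate.
#'
#' @param node_rates Positive rates indexed by node id (length
#'   `Ntip + Nnode`).
#' @param tt A dated `timetree`.
#' @param cfg A [clock_config()].
#' @return Log density.
#' @export
gbm_log_prior <- function(node_rates, tt, cfg) {
  stopifnot(inherits(cfg, "clock_config"), inherits(tt, "timetree"))
  if (any(node_rates <= 0)) return(-Inf)
  edge <- tt$phy$edge
  dt <- tt$ages[edge[, 1]] - tt$ages[edge[, 2]]
  rp <- node_rates[edge[, 1]]
  rc <- node_rates[edge[, 2]]
  out <- 0
  zero <- dt <= 0 | cfg$sigma2 == 0
  if (any(zero)) {
    if (!all(abs(log(rc[zero]) - log(rp[zero])) < 1e-12)) return(-Inf)
  }
  if (any(!zero)) {
    v <- cfg$sigma2 * dt[!zero]
    out <- sum(dnorm(log(rc[!zero]), log(rp[!zero]) - v / 2, sqrt(v),
                     log = TRUE) - log(rc[!zero]))
  }
  out
}

#' Expected branch lengths from ages and rates
#'
#' ILN: `b = r_branch * dt`. GBM: `b = (r_parent + r_child)/2 * dt`
#' (arithmetic-mean convention for the average rate along a branch).
#' Branch order follows [canonical_edges()].
#'
#' @param tt A dated `timetree`.
#' @param rates For ILN, branch rates in canonical order; for GBM, node
#'   rates indexed by node id.
#' @param cfg A [clock_config()].
#' @return Numeric vector of expected branch lengths (substitutions/site).
#' @export
expected_branch_lengths <- function(tt, rates, cfg) {
  stopifnot(inherits(tt, "timetree"), inherits(cfg, "clock_config"))
  edge <- canonical_edges(tt)
  dt <- tt$ages[edge[, 1]] - tt$ages[edge[, 2]]
  if (any(dt < -1e-12)) stop("negative branch duration")
  dt <- pmax(dt, 0)
  if (cfg$model == "ILN") {
    stopifnot(length(rates) == nrow(edge))
    rates * dt
  } else {
    (rates[edge[, 1]] + rates[edge[, 2]]) / 2 * dt
  }
}

#' Simulate relaxed-clock rates
#'
#' @param tt A dated `timetree`.
#' @param cfg A [clock_config()].
#' @return For ILN, branch rates in canonical order; for GBM, node rates
#'   indexed by node id (root rate drawn mean-corrected around `mu_r`).
#' @export
simulate_branch_rates <- function(tt, cfg) {
  stopifnot(inherits(tt, "timetree"), inherits(cfg, "clock_config"))
  edge <- canonical_edges(tt)
  if (cfg$model == "ILN") {
    rlnorm(nrow(edge), log(cfg$mu_r) - cfg$sigma2 / 2, sqrt(cfg$sigma2))
  } else {
    n_all <- ape::Ntip(tt$phy) + tt$phy$Nnode
    r <- numeric(n_all)
    root <- root_node(tt)
    r[root] <- rlnorm(1, log(cfg$mu_r) - cfg$sigma2 / 2, sqrt(cfg$sigma2))
    # preorder walk: canonical (postorder) edges reversed visit parents first
    for (i in rev(seq_len(nrow(edge)))) {
      p <- edge[i, 1]; ch <- edge[i, 2]
      v <- cfg$sigma2 * (tt$ages[p] - tt$ages[ch])
      r[ch] <- if (v > 0) rlnorm(1, log(r[p]) - v / 2, sqrt(v)) else r[p]
    }
    r
  }
}
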