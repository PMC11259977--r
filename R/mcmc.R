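# Sampler internals. The chain state couples node ages (100 Myr), per-locus
# log rates (branch rates for ILN, node rates for GBM), and per-locus
# hyperparameters (mu, sigma2). The likelihood is the per-locus normal
# approximation around MLE branch lengths; its state (d = b - bhat, Hd, ll)
# is maintained incrementally in C++ and can be rebuilt from scratch for
# consistency checks.

tree_indexing <- function(phy) {
  edge <- canonical_edges(phy)
  ntip <- ape::Ntip(phy)
  n_all <- ntip + phy$Nnode
  parent_edge <- rep(-1L, n_all)
  parent_edge[edge[, 2]] <- seq_len(nrow(edge)) - 1L # 0-based
  child_edges <- lapply(seq_len(n_all), function(n)
    as.integer(which(edge[, 1] == n) - 1L))
  children <- lapply(seq_len(n_all), function(n) edge[edge[, 1] == n, 2])
  list(edge = edge, ntip = ntip, n_all = n_all, root = ntip + 1L,
       parent_edge = parent_edge, child_edges = child_edges,
       children = children,
       parent = c(edge[, 1][order(edge[, 2])][0], # filled below
                  vapply(seq_len(n_all), function(n) {
                    w <- which(edge[, 2] == n)
                    if (length(w)) edge[w, 1] else NA_integer_
                  }, integer(1))))
}

node_heights <- function(idx) {
  h <- integer(idx$n_all)
  for (k in seq_len(nrow(idx$edge))) { # postorder: children first
    p <- idx$edge[k, 1]; ch <- idx$edge[k, 2]
    h[p] <- max(h[p], h[ch] + 1L)
  }
  h
}

init_ages <- function(idx, cal, bd) {
  root <- idx$root
  h <- node_heights(idx)
  # effective hard floor per node: its own calibration minimum or the
  # largest minimum among its descendants
  floor_ <- numeric(idx$n_all)
  for (nd in names(cal)) floor_[as.integer(nd)] <- cal[[nd]]$t_min
  for (k in seq_len(nrow(idx$edge))) # postorder: children first
    floor_[idx$edge[k, 1]] <- max(floor_[idx$edge[k, 1]],
                                  floor_[idx$edge[k, 2]])
  root_cal <- cal[[as.character(root)]]
  ages <- numeric(idx$n_all)
  ages[root] <- max(calibration_quantile(0.5, root_cal),
                    floor_[root] * 1.05)
  # preorder interpolation between each node's floor and its parent age:
  # always strictly ordered and above every hard minimum
  for (k in rev(seq_len(nrow(idx$edge)))) {
    p <- idx$edge[k, 1]; ch <- idx$edge[k, 2]
    if (ch <= idx$ntip) next
    frac <- max(h[ch] / h[p], 0.15)
    ages[ch] <- floor_[ch] + (ages[p] - floor_[ch]) * frac
  }
  if (any(ages[idx$edge[, 1]] <= ages[idx$edge[, 2]]))
    stop("could not construct a feasible initial state compatible with ",
         "the calibrations")
  ages
}

#' Run one MCMC chain for node ages and rates
#'
#' Metropolis-Hastings sampling from the posterior proportional to
#' calibration densities x birth-death kernel x relaxed-clock rate prior x
#' rate hyperpriors x per-locus normal-approximation likelihoods. The
#' proposal set comprises reflected sliding-window age moves respecting
#' parent/child order, log-space rate moves (one per branch or node per
#' locus), multiplicative hyperparameter moves, and a whole-tree mixing move
#' (ages x c, rates / c) with the proper Jacobian. Step sizes are auto-tuned
#' toward 20-40% acceptance during burn-in and then frozen. The seed fully
#' determines the output.
#'
#' @param tree A `timetree` (ages, if present, seed the initial state).
#' @param loci List of [blen_approx()] objects (empty for a prior-only run).
#' @param clock A [clock_config()]; its `mu_r`/`sigma2` are used only to
#'   initialize (hyperparameters are sampled).
#' @param calibrations Named list (node id -> [calibration()]), e.g. from
#'   [calibrations_for_tree()]. The root must be calibrated.
#' @param bd A [birth_death_prior()] for uncalibrated node ages.
#' @param hyper A [rate_hyperpriors()].
#' @param n_iter Total iterations (sweeps).
#' @param burn_in Fraction of `n_iter` discarded (also the tuning phase).
#' @param thin Keep every `thin`-th post-burn-in sweep (default targets
#'   about 2000 retained draws).
#' @param seed Integer seed; fully determines the chain.
#' @param use_likelihood If `FALSE`, likelihood terms are dropped (sampling
#'   from the effective prior) while rates and hyperparameters, if loci are
#'   supplied, are still sampled from their priors.
#' @return An object of class `posterior_samples`.
#' @export
run_chain <- function(tree, loci = list(), clock = clock_config("ILN"),
                      calibrations, bd = birth_death_prior(),
                      hyper = rate_hyperpriors(),
                      n_iter = 10000L, burn_in = 0.25, thin = NULL,
                      seed = 1L, use_likelihood = TRUE) {
  stopifnot(inherits(tree, "timetree"), inherits(clock, "clock_config"))
  phy <- tree$phy
  idx <- tree_indexing(phy)
  root <- idx$root
  if (is.null(calibrations[[as.character(root)]]))
    stop("the root must carry a calibration (the birth-death kernel ",
         "conditions on the root age)")
  set.seed(as.integer(seed))
  L <- length(loci)
  B <- nrow(idx$edge)
  gbm <- clock$model == "GBM"

  if (L > 0) {
    loci <- lapply(loci, match_blen_approx, tt = tree)
    bhat <- vapply(loci, `[[`, numeric(B), "bhat")
    gmat <- vapply(loci, `[[`, numeric(B), "g")
    Hlist <- lapply(loci, `[[`, "H")
    if (!use_likelihood) {
      gmat[] <- 0
      Hlist <- lapply(Hlist, function(H) matrix(0, B, B))
    }
  }

  cal_nodes <- as.integer(names(calibrations))
  free_nodes <- setdiff((root):(idx$n_all), c(cal_nodes, root))
  intn <- root:idx$n_all

  ages <- if (!anyNA(tree$ages)) tree$ages else init_ages(idx, calibrations, bd)
  # auto-repair supplied ages against calibration floors
  if (any(vapply(cal_nodes, function(n)
    ages[n] < calibrations[[as.character(n)]]$t_min, logical(1))))
    ages <- init_ages(idx, calibrations, bd)

  # flat calibration lookup tables for the hot path
  cal_at <- rep(NA_integer_, idx$n_all)
  cal_at[cal_nodes] <- seq_along(cal_nodes)
  cal_tmin <- vapply(cal_nodes, function(n)
    calibrations[[as.character(n)]]$t_min, numeric(1))
  cal_tmax <- vapply(cal_nodes, function(n)
    calibrations[[as.character(n)]]$t_max, numeric(1))
  cal_lbody <- vapply(cal_nodes, function(n)
    log(calibrations[[as.character(n)]]$body_dens), numeric(1))
  cal_trate <- vapply(cal_nodes, function(n)
    calibrations[[as.character(n)]]$tail_rate, numeric(1))
  cal_ld <- function(i, t) {
    if (t < cal_tmin[i]) return(-Inf)
    if (t <= cal_tmax[i]) return(cal_lbody[i])
    cal_lbody[i] - cal_trate[i] * (t - cal_tmax[i])
  }
  lg_mu <- function(x) dgamma(x, hyper$alpha_r, rate = hyper$beta_r,
                              log = TRUE)
  lg_s2 <- function(x) dgamma(x, hyper$alpha_s, rate = hyper$beta_s,
                              log = TRUE)
  age_log_prior_node <- function(n, t_n, t_root) {
    i <- cal_at[n]
    if (!is.na(i)) cal_ld(i, t_n)
    else log(bd_kernel_density(t_n, t_root, bd))
  }
  age_log_prior_all <- function(t) {
    lp <- 0
    for (i in seq_along(cal_nodes)) lp <- lp + cal_ld(i, t[cal_nodes[i]])
    lp + birth_death_log_prior(t[free_nodes], t[root], bd)
  }

  # rate state
  if (L > 0) {
    mu <- rep(clock$mu_r, L)
    s2 <- rep(clock$sigma2, L)
    mlog <- log(mu) - s2 / 2
    X <- if (gbm) matrix(log(clock$mu_r), idx$n_all, L)
         else matrix(log(clock$mu_r), B, L)
    b_from_state <- function() {
      dt <- ages[idx$edge[, 1]] - ages[idx$edge[, 2]]
      if (gbm) 0.5 * (exp(X[idx$edge[, 1], , drop = FALSE]) +
                      exp(X[idx$edge[, 2], , drop = FALSE])) * dt
      else exp(X) * dt
    }
    dmat <- matrix(0, B, L); Hd <- matrix(0, B, L); ll <- numeric(L)
    refresh_state(b_from_state(), bhat, gmat, Hlist, dmat, Hd, ll)
    rate_log_prior_locus <- function(l, mlog_l = mlog[l], s2_l = s2[l]) {
      if (!gbm)
        return(sum(dnorm(X[, l], mlog_l, sqrt(s2_l), log = TRUE)))
      dt <- ages[idx$edge[, 1]] - ages[idx$edge[, 2]]
      v <- s2_l * dt
      sum(dnorm(X[idx$edge[, 2], l],
                X[idx$edge[, 1], l] - v / 2, sqrt(v), log = TRUE)) +
        dnorm(X[root, l], mlog_l, sqrt(s2_l), log = TRUE)
    }
    rp <- vapply(seq_len(L), rate_log_prior_locus, numeric(1))
  } else {
    mu <- s2 <- mlog <- numeric(0)
    rp <- numeric(0); ll <- numeric(0)
  }

  # steps and bookkeeping
  step_age <- pmax(ages[intn] * 0.1, 0.05)
  names(step_age) <- intn
  step_rate <- 0.5; step_mu <- 0.4; step_s2 <- 0.6; step_mix <- 0.1
  step_ls <- 0.2; step_lmu <- 0.3; step_s2j <- 0.4
  keys <- c("age", "rate", "mu", "s2", "lscale", "lmu", "s2j", "mix")
  acc <- setNames(numeric(length(keys)), keys)
  try_n <- acc
  acc_age_node <- setNames(numeric(length(intn)), intn)
  try_age_node <- acc_age_node

  n_burn <- floor(n_iter * burn_in)
  if (is.null(thin))
    thin <- max(1L, floor((n_iter - n_burn) / 2000))
  keep_at <- seq(n_burn + thin, n_iter, by = thin)
  age_names <- paste0("t_n", intn)
  cn <- c("logpost", "loglik", age_names,
          if (L > 0) c(paste0("mu_", seq_len(L)), paste0("sigma2_", seq_len(L))))
  draws <- matrix(NA_real_, length(keep_at), length(cn),
                  dimnames = list(NULL, cn))
  k_out <- 0L

  gbm_edge_terms <- function(rows, t, l_all = seq_len(L)) {
    # GBM rate-prior contribution of given edges, all loci (matrix rows x L)
    dt <- t[idx$edge[rows, 1]] - t[idx$edge[rows, 2]]
    out <- matrix(0, length(rows), length(l_all))
    for (a in seq_along(rows)) {
      v <- s2[l_all] * dt[a]
      out[a, ] <- dnorm(X[idx$edge[rows[a], 2], l_all],
                        X[idx$edge[rows[a], 1], l_all] - v / 2, sqrt(v),
                        log = TRUE)
    }
    out
  }

  reflect <- function(x, lo, hi) {
    for (r in 1:100) {
      if (x < lo) x <- 2 * lo - x
      else if (is.finite(hi) && x > hi) x <- 2 * hi - x
      else return(x)
    }
    (lo + min(hi, lo + 1)) / 2
  }

  for (it in seq_len(n_iter)) {
    ## -- age moves -------------------------------------------------------
    for (j in seq_along(intn)) {
      n <- intn[j]
      kids <- idx$children[[n]]
      lo <- max(ages[kids])
      hi <- if (n == root) Inf else ages[idx$parent[n]]
      tn <- reflect(ages[n] + step_age[j] * (2 * runif(1) - 1), lo, hi)
      try_age_node[j] <- try_age_node[j] + 1
      # prior delta
      if (n == root) {
        t_new <- ages; t_new[n] <- tn
        dlp <- age_log_prior_all(t_new) - age_log_prior_all(ages)
      } else {
        dlp <- age_log_prior_node(n, tn, ages[root]) -
               age_log_prior_node(n, ages[n], ages[root])
      }
      rows <- c(if (n != root) idx$parent_edge[n] + 1L,
                idx$child_edges[[n]] + 1L)
      if (L > 0) {
        dt_old <- ages[idx$edge[rows, 1]] - ages[idx$edge[rows, 2]]
        t_new <- ages; t_new[n] <- tn
        dt_new <- t_new[idx$edge[rows, 1]] - t_new[idx$edge[rows, 2]]
        if (gbm) {
          rmean <- 0.5 * (exp(X[idx$edge[rows, 1], , drop = FALSE]) +
                          exp(X[idx$edge[rows, 2], , drop = FALSE]))
          delta <- rmean * (dt_new - dt_old)
          drp <- colSums(gbm_edge_terms(rows, t_new)) -
                 colSums(gbm_edge_terms(rows, ages))
        } else {
          delta <- exp(X[rows, , drop = FALSE]) * (dt_new - dt_old)
          drp <- 0
        }
        dll <- ll_delta_edges(rows - 1L, delta, gmat, Hd, Hlist)
        tot <- dlp + sum(dll) + sum(drp)
      } else { dll <- numeric(0); drp <- 0; tot <- dlp }
      if (is.finite(tot) && log(runif(1)) < tot) {
        if (L > 0) {
          apply_delta_edges(rows - 1L, delta, dmat, Hd, Hlist, ll, dll)
          if (gbm) rp <- rp + drp
        }
        ages[n] <- tn
        acc_age_node[j] <- acc_age_node[j] + 1
      }
    }

    ## -- rate sweep ------------------------------------------------------
    if (L > 0) {
      dt <- ages[idx$edge[, 1]] - ages[idx$edge[, 2]]
      nr <- if (gbm)
        gbm_sweep(X, dmat, Hd, ll, gmat, Hlist, dt,
                  idx$edge[, 1] - 1L, idx$edge[, 2] - 1L,
                  idx$parent_edge, idx$child_edges, mlog, s2,
                  step_rate, root - 1L)
      else
        iln_sweep(X, dmat, Hd, ll, gmat, Hlist, dt, mlog, s2, step_rate)
      acc["rate"] <- acc["rate"] + nr
      try_n["rate"] <- try_n["rate"] + length(X)
      rp <- vapply(seq_len(L), rate_log_prior_locus, numeric(1))

      ## -- hyperparameter and whole-locus moves (C++, one call/sweep):
      ## mu and sigma2 random walks, whole-locus rate scale, joint
      ## (mu, rates) scale, and for ILN the joint (sigma2, rates) rescale
      hp_vec <- c(hyper$alpha_r, hyper$beta_r, hyper$alpha_s, hyper$beta_s)
      steps <- c(step_mu, step_s2, step_ls, step_lmu, step_s2j)
      nacc <- if (gbm)
        gbm_hyper_sweep(X, dmat, Hd, ll, gmat, Hlist, bhat, dt,
                        idx$edge[, 1] - 1L, idx$edge[, 2] - 1L,
                        mu, s2, mlog, rp, hp_vec, steps, root - 1L)
      else
        iln_hyper_sweep(X, dmat, Hd, ll, gmat, Hlist, bhat, dt,
                        mu, s2, mlog, rp, hp_vec, steps)
      hk <- c("mu", "s2", "lscale", "lmu", "s2j")
      acc[hk] <- acc[hk] + nacc
      try_n[hk] <- try_n[hk] + c(L, L, L, L, if (gbm) 0 else L)
    }

    ## -- mixing move: ages x c, rates / c (b invariant) ------------------
    ce <- exp(step_mix * (runif(1) - 0.5))
    t_new <- ages; t_new[intn] <- ages[intn] * ce
    dlp <- age_log_prior_all(t_new) - age_log_prior_all(ages)
    lj <- length(intn) * log(ce)
    if (L > 0) {
      mu_new <- mu / ce
      X_new <- X - log(ce)
      dlp <- dlp + sum(lg_mu(mu_new) - lg_mu(mu))
      lj <- lj - L * log(ce)
      if (gbm) {
        X_old <- X; ages_old <- ages
        X <- X_new; ages <- t_new
        mlog_new <- log(mu_new) - s2 / 2
        rp_new <- vapply(seq_len(L), function(l)
          rate_log_prior_locus(l, mlog_l = mlog_new[l]), numeric(1))
        X <- X_old; ages <- ages_old
        dlp <- dlp + sum(rp_new - rp)
      } else rp_new <- rp # ILN rate prior invariant under the joint rescale
    }
    try_n["mix"] <- try_n["mix"] + 1
    if (is.finite(dlp) && log(runif(1)) < dlp + lj) {
      ages <- t_new
      if (L > 0) {
        mu <- mu_new; X <- X_new; mlog <- log(mu) - s2 / 2; rp <- rp_new
      }
      acc["mix"] <- acc["mix"] + 1
    }

    ## -- tuning during burn-in -------------------------------------------
    if (it <= n_burn && it %% 50 == 0) {
      rt <- acc_age_node / pmax(try_age_node, 1)
      step_age <- pmin(pmax(step_age * exp(rt - 0.3), 1e-4), 50)
      acc_age_node[] <- 0; try_age_node[] <- 0
      adj <- function(step, key) {
        r <- acc[key] / max(try_n[key], 1)
        min(max(step * exp(r - 0.3), 1e-3), 20)
      }
      if (L > 0) {
        step_rate <- adj(step_rate, "rate")
        step_mu <- adj(step_mu, "mu")
        step_s2 <- adj(step_s2, "s2")
        step_ls <- adj(step_ls, "lscale")
        step_lmu <- adj(step_lmu, "lmu")
        if (!gbm) step_s2j <- adj(step_s2j, "s2j")
      }
      step_mix <- adj(step_mix, "mix")
      acc["age"] <- sum(acc_age_node)
      reset <- setdiff(names(acc), "age")
      acc[reset] <- 0
      try_n[reset] <- 0
    }

    ## -- record -----------------------------------------------------------
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      k_out <- k_out + 1L
      lp <- age_log_prior_all(ages) + sum(rp) + sum(ll) +
        (if (L > 0) sum(lg_mu(mu)) + sum(lg_s2(s2)) else 0)
      draws[k_out, ] <- c(lp, sum(ll), ages[intn],
                          if (L > 0) c(mu, s2))
    }
  }

  acc_rate <- acc / pmax(try_n, 1)
  acc_rate["age"] <- sum(acc_age_node) / max(sum(try_age_node), 1)

  # cache-consistency audit of the incremental likelihood state
  if (L > 0) {
    ll_chk <- numeric(L); d_chk <- matrix(0, B, L); Hd_chk <- matrix(0, B, L)
    refresh_state(b_from_state(), bhat, gmat, Hlist, d_chk, Hd_chk, ll_chk)
    if (max(abs(ll_chk - ll)) > 1e-6)
      warning("incremental likelihood cache drifted by ",
              format(max(abs(ll_chk - ll))))
  }

  node_labels <- character(length(intn))
  if (!is.null(phy$node.label))
    node_labels <- phy$node.label[intn - idx$ntip]
  structure(list(draws = draws, tree = tree, internal_nodes = intn,
                 node_labels = node_labels, clock = clock$model,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, n_loci = L, acceptance = acc_rate,
                 final_state = list(ages = ages,
                                    mu = mu, sigma2 = s2)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", nrow(x$draws), "draws,", x$clock, "clock,",
      x$n_loci, "loci, seed", x$seed, "\n")
  cat("acceptance:", paste(names(x$acceptance),
                           sprintf("%.2f", x$acceptance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Shortest (highest-density) posterior interval
#'
#' Order-statistic method: the shortest contiguous interval containing
#' `prob` of the sorted draws.
#'
#' @param x Numeric draws.
#' @param prob Interval mass.
#' @return Length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  n <- length(x)
  xs <- sort(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(xs[1], xs[n]))
  w <- xs[k:n] - xs[seq_len(n - k + 1)]
  i <- which.min(w)
  c(xs[i], xs[i + k - 1])
}

#' Effective sample size by autocorrelation time
#'
#' `n / (1 + 2 * sum(rho_k))`, summing autocorrelations until the first
#' non-positive lag.
#'
#' @param x Numeric draws.
#' @return Effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  max(1, min(n, n / (1 + 2 * sum(rho))))
}

#' Summarize a posterior sample
#'
#' Posterior mean, 95% HPD and ESS per parameter. Node ages are reported in
#' Ma; other parameters on their natural scale.
#'
#' @param ps A `posterior_samples` object.
#' @param prob HPD mass.
#' @return Data frame with columns `param`, `label`, `mean`, `lower`,
#'   `upper`, `ess`.
#' @export
summarize_posterior <- function(ps, prob = 0.95) {
  stopifnot(inherits(ps, "posterior_samples"))
  if (nrow(ps$draws) < 100)
    stop("need at least 100 post-burn-in draws, have ", nrow(ps$draws))
  cols <- setdiff(colnames(ps$draws), c("logpost", "loglik"))
  out <- lapply(cols, function(cl) {
    x <- ps$draws[, cl]
    is_age <- startsWith(cl, "t_n")
    if (is_age) x <- unit_to_ma(x)
    h <- hpd_interval(x, prob)
    lab <- ""
    if (is_age) {
      n <- as.integer(sub("t_n", "", cl))
      lab <- ps$node_labels[match(n, ps$internal_nodes)]
    }
    data.frame(param = cl, label = lab, mean = mean(x),
               lower = h[1], upper = h[2], ess = ess(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

split_rhat <- function(chains) {
  # chains: list of numeric vectors; each split in half.
  # identical sample sets are 1 by convention.
  if (length(chains) == 2 && identical(chains[[1]], chains[[2]]))
    return(1)
  n <- min(lengths(chains))
  if (n < 4) return(NA_real_)
  halves <- unlist(lapply(chains, function(x) {
    x <- x[seq_len(n)]
    h <- n %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  W <- mean(vapply(halves, var, numeric(1)))
  Bv <- nn * var(vapply(halves, mean, numeric(1)))
  if (W == 0) return(if (Bv == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + Bv / nn) / W)
}

#' Convergence report across two chains
#'
#' Per-parameter split-R-hat over the two chains (each split in half), plus
#' a mean-vs-mean comparison. `rhat_flag` marks parameters with split-R-hat
#' above `rhat_limit`; `mean_flag` marks parameters whose posterior means
#' differ by more than half the pooled posterior standard deviation (a
#' practical-equivalence check, deliberately coarser than Monte-Carlo
#' error); `flag` is their union.
#'
#' @param run_a,run_b `posterior_samples` from independent seeds of the
#'   same model.
#' @param rhat_limit Flagging threshold for split-R-hat.
#' @return Data frame with `param`, `rhat`, `mean_a`, `mean_b`,
#'   `rhat_flag`, `mean_flag`, `flag`, and attribute `regression`
#'   (intercept/slope of mean_b on mean_a over age parameters).
#' @export
check_convergence <- function(run_a, run_b, rhat_limit = 1.01) {
  stopifnot(inherits(run_a, "posterior_samples"),
            inherits(run_b, "posterior_samples"))
  ca <- setdiff(colnames(run_a$draws), c("logpost", "loglik"))
  cb <- setdiff(colnames(run_b$draws), c("logpost", "loglik"))
  if (!identical(ca, cb))
    stop("parameter sets differ between runs")
  rows <- lapply(ca, function(cl) {
    xa <- run_a$draws[, cl]; xb <- run_b$draws[, cl]
    rh <- split_rhat(list(xa, xb))
    psd <- sd(c(xa - mean(xa), xb - mean(xb)))
    dmean <- abs(mean(xa) - mean(xb))
    rf <- is.na(rh) || rh > rhat_limit
    mf <- psd > 0 && dmean > 0.5 * psd
    data.frame(param = cl, rhat = rh, mean_a = mean(xa), mean_b = mean(xb),
               rhat_flag = rf, mean_flag = mf, flag = rf || mf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  agep <- startsWith(out$param, "t_n")
  if (sum(agep) >= 2) {
    fit <- lm(out$mean_b[agep] ~ out$mean_a[agep])
    attr(out, "regression") <- coef(fit)
  }
  out
}
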