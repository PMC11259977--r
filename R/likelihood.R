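# Amino-acid alphabet in the order used throughout (PAML/codeml order).
AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Amino-acid substitution model
#'
#' Builds a reversible 20-state rate matrix scaled to one expected
#' substitution per site at stationarity, with optional discrete-gamma
#' among-site rate heterogeneity (median-of-category discretization,
#' normalized to mean rate 1). `Poisson` is the equal-rates/equal-frequency
#' model with closed-form transition probabilities, used for analytic
#' checks; `WAG`, `LG` and `JTT` use the standard empirical exchangeability
#' matrices (as shipped with phangorn).
#'
#' @param name One of `"Poisson"`, `"WAG"`, `"LG"`, `"JTT"`.
#' @param gamma_k Number of discrete gamma categories (1 = homogeneous).
#' @param gamma_shape Gamma shape parameter `a` (required if `gamma_k > 1`).
#' @return An object of class `aa_model`.
#' @export
aa_model <- function(name = c("Poisson", "WAG", "LG", "JTT"),
                     gamma_k = 1L, gamma_shape = NULL) {
  name <- match.arg(name)
  if (name == "Poisson") {
    freqs <- rep(1 / 20, 20)
    exch <- matrix(1, 20, 20)
  } else {
    bf <- NULL; Q <- NULL
    getmod <- utils::getFromNamespace("getModelAA", "phangorn")
    getmod(name, bf = TRUE, Q = TRUE)
    freqs <- as.numeric(bf)
    exch <- matrix(0, 20, 20)
    exch[lower.tri(exch)] <- Q
    exch <- exch + t(exch)
  }
  names(freqs) <- AA_ORDER
  Qm <- exch * rep(freqs, each = 20)
  diag(Qm) <- 0
  diag(Qm) <- -rowSums(Qm)
  Qm <- Qm / sum(freqs * -diag(Qm)) # 1 expected substitution/site
  dimnames(Qm) <- list(AA_ORDER, AA_ORDER)
  sq <- sqrt(freqs)
  B <- Qm * (sq %o% (1 / sq)) # similarity transform -> symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U1 <- eig$vectors / sq      # rows scaled by 1/sqrt(pi)
  U2 <- t(eig$vectors) * rep(sq, each = 20)
  if (gamma_k > 1L) {
    if (is.null(gamma_shape) || gamma_shape <= 0)
      stop("gamma_shape must be positive when gamma_k > 1")
    r <- qgamma((seq_len(gamma_k) - 0.5) / gamma_k,
                shape = gamma_shape, rate = gamma_shape)
    r <- r / mean(r)
  } else r <- 1
  structure(list(name = name, Q = Qm, freqs = freqs,
                 eigenvalues = eig$values, U1 = U1, U2 = U2,
                 gamma_k = as.integer(gamma_k), gamma_shape = gamma_shape,
                 gamma_rates = r),
            class = "aa_model")
}

#' Transition probability matrix
#'
#' @param model An [aa_model()].
#' @param d Branch length (expected substitutions/site).
#' @return 20x20 matrix `P(d) = exp(Q d)`.
#' @export
transition_matrix <- function(model, d) {
  stopifnot(inherits(model, "aa_model"), d >= 0)
  P <- model$U1 %*% (exp(model$eigenvalues * d) * model$U2)
  P[P < 0] <- 0
  P
}

encode_sequence <- function(s) {
  idx <- match(strsplit(s, "")[[1]], AA_ORDER)
  idx[is.na(idx)] <- 0L # gap / ? / X / ambiguity -> missing
  idx
}

# Site-pattern compression over the tips of phy. Returns integer matrix
# (tips x n_patterns, 0 = missing) and pattern weights.
compress_patterns <- function(aln, phy) {
  tips <- phy$tip.label
  un_tree <- setdiff(tips, names(aln$seqs))
  un_aln <- setdiff(names(aln$seqs), tips)
  if (length(un_tree) || length(un_aln))
    stop("leaf/alignment label mismatch in locus ", aln$id,
         if (length(un_tree)) paste0("; tree-only: ",
                                     paste(un_tree, collapse = ", ")),
         if (length(un_aln)) paste0("; alignment-only: ",
                                    paste(un_aln, collapse = ", ")))
  M <- vapply(aln$seqs[tips], encode_sequence, integer(aln$n_sites))
  M <- t(matrix(M, nrow = aln$n_sites)) # tips x sites (n_sites may be 1)
  key <- apply(M, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(patterns = M[, first, drop = FALSE], weights = w)
}

# Core pruning over one set of patterns for one gamma-category rate.
prune_once <- function(patterns, phy_post, Plist, freqs) {
  ntip <- length(phy_post$tip.label)
  nnode <- phy_post$Nnode
  S <- ncol(patterns)
  L <- vector("list", ntip + nnode)
  partial <- matrix(1, 20, S)
  for (i in seq_len(ntip)) {
    Li <- matrix(1, 20, S)
    obs <- patterns[i, ] > 0
    if (any(obs)) {
      Li[, obs] <- 0
      Li[cbind(patterns[i, obs], which(obs))] <- 1
    }
    L[[i]] <- Li
  }
  edge <- phy_post$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    contrib <- Plist[[k]] %*% L[[ch]]
    L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
  }
  colSums(freqs * L[[ntip + 1L]])
}

#' Felsenstein pruning log-likelihood
#'
#' Exact amino-acid likelihood of an alignment on a fixed topology with
#' given branch lengths. Gaps and `?`/`X` contribute partial likelihood 1
#' over all residues; gamma rate heterogeneity is averaged over categories.
#'
#' @param aln A `locus_alignment`.
#' @param phy Topology (`phylo` or `timetree`); tip labels must match the
#'   alignment.
#' @param b Branch lengths in canonical order ([canonical_edges()]).
#' @param model An [aa_model()].
#' @return Total log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(aln, phy, b, model) {
  if (inherits(phy, "timetree")) phy <- phy$phy
  stopifnot(inherits(aln, "locus_alignment"), inherits(model, "aa_model"))
  if (any(b < 0)) stop("negative branch length")
  post <- ape::reorder.phylo(phy, "postorder")
  if (length(b) != nrow(post$edge))
    stop("branch-length vector has length ", length(b), ", expected ",
         nrow(post$edge))
  cp <- compress_patterns(aln, post)
  site_lik <- 0
  for (k in seq_len(model$gamma_k)) {
    Plist <- lapply(b * model$gamma_rates[k],
                    function(d) transition_matrix(model, d))
    site_lik <- site_lik +
      prune_once(cp$patterns, post, Plist, model$freqs) / model$gamma_k
  }
  if (any(site_lik <= 0)) return(-Inf)
  sum(cp$weights * log(site_lik))
}

#' Branch-length normal approximation for one locus
#'
#' Holds the MLE branch lengths with the gradient and Hessian of the
#' log-likelihood at the MLE, in canonical branch order, each branch
#' identified by the sorted tip set of its child clade (so the object can
#' be re-matched to an identically shaped dating tree).
#'
#' @param id Locus id.
#' @param phy Topology the branches refer to.
#' @param bhat MLE branch lengths.
#' @param g Gradient at `bhat`.
#' @param H Hessian at `bhat` (symmetrized if asymmetry is below `1e-8`,
#'   with a warning otherwise).
#' @param loglik Optional log-likelihood at the MLE.
#' @return An object of class `blen_approx`.
#' @export
blen_approx <- function(id, phy, bhat, g, H, loglik = NA_real_) {
  if (inherits(phy, "timetree")) phy <- phy$phy
  edge <- canonical_edges(phy)
  B <- nrow(edge)
  stopifnot(length(bhat) == B, length(g) == B,
            is.matrix(H), all(dim(H) == B))
  asym <- max(abs(H - t(H)))
  if (asym > 1e-8)
    warning("Hessian asymmetry ", format(asym), " in locus ", id,
            "; symmetrizing")
  H <- (H + t(H)) / 2
  structure(list(id = as.character(id), tips = phy$tip.label,
                 clades = edge_clades(phy, edge),
                 bhat = as.numeric(bhat), g = as.numeric(g), H = H,
                 loglik = loglik),
            class = "blen_approx")
}

edge_clades <- function(phy, edge = canonical_edges(phy)) {
  ntip <- ape::Ntip(phy)
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(edge))) { # postorder: children before parents
    p <- edge[k, 1]; ch <- edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(edge[, 2], function(nd) paste(sort(desc[[nd]]), collapse = "|"),
         character(1))
}

#' Estimate MLE branch lengths with gradient and Hessian
#'
#' Multi-start box-constrained quasi-Newton (L-BFGS-B) maximization of
#' [pruning_loglik()], with a branch-length floor keeping the optimum
#' interior so the quadratic approximation is valid. Gradient and Hessian
#' are computed by scale-aware central finite differences
#' (`h_i = max(1e-4, 1e-2 * bhat_i)`).
#'
#' @param aln A `locus_alignment`.
#' @param phy Topology (`phylo` or `timetree`).
#' @param model An [aa_model()].
#' @param floor Lower box bound on branch lengths.
#' @param starts Numeric vector of flat starting branch lengths.
#' @param grad_tol Warn if the interior gradient sup-norm exceeds this.
#' @return A [blen_approx()].
#' @export
estimate_brlens_and_hessian <- function(aln, phy, model, floor = 1e-6,
                                        starts = c(0.05, 0.2),
                                        grad_tol = 0.05) {
  if (inherits(phy, "timetree")) phy <- phy$phy
  if (length(aln$seqs) < 2L) stop("need at least 2 sequences")
  B <- nrow(canonical_edges(phy))
  f <- function(b) -pruning_loglik(aln, phy, b, model)
  best <- NULL
  for (s in starts) {
    fit <- optim(rep(s, B), f, method = "L-BFGS-B",
                 lower = floor, upper = 20,
                 control = list(maxit = 1000, factr = 1e6))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best point (flat directions make L-BFGS-B stop early);
  # a failed line search at this tolerance is ignorable
  fit <- optim(best$par, f, method = "L-BFGS-B", lower = floor, upper = 20,
               control = list(maxit = 1000, factr = 1e5))
  if (fit$convergence == 0 && fit$value <= best$value) best <- fit
  if (best$convergence != 0)
    stop("branch-length optimization did not converge (code ",
         best$convergence, ", best -loglik ", format(best$value), ")")
  bhat <- best$par
  # scale-aware central steps; near the box floor the step shrinks so the
  # lower point stays a valid (possibly zero) branch length
  h <- pmax(1e-4, 1e-2 * bhat)
  h <- pmin(h, bhat)
  g <- numeric(B)
  for (i in seq_len(B)) {
    up <- bhat; up[i] <- bhat[i] + h[i]
    dn <- bhat; dn[i] <- bhat[i] - h[i]
    g[i] <- (f(dn) - f(up)) / (up[i] - dn[i]) # central diff of +loglik
  }
  # first-order optimality, scaled: a residual slope only matters if the
  # log-likelihood gain achievable within the feasible region is resolvable
  interior <- bhat > floor * 1.5
  gain <- abs(g) * pmax(bhat, h)
  if (any(interior & abs(g) > grad_tol & gain > 0.01))
    warning("gradient sup-norm ", format(max(abs(g[interior]))),
            " at interior MLE of locus ", aln$id)
  f0 <- -best$value
  H <- matrix(0, B, B)
  fp <- numeric(B); fm <- numeric(B)
  for (i in seq_len(B)) {
    up <- bhat; up[i] <- bhat[i] + h[i]
    dn <- bhat; dn[i] <- bhat[i] - h[i]
    fp[i] <- -f(up); fm[i] <- -f(dn)
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / h[i]^2
  }
  for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    pp <- bhat; pp[c(i, j)] <- bhat[c(i, j)] + h[c(i, j)]
    mm <- bhat; mm[c(i, j)] <- bhat[c(i, j)] - h[c(i, j)]
    fpp <- -f(pp); fmm <- -f(mm)
    H[i, j] <- H[j, i] <-
      (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h[i] * h[j])
  }
  blen_approx(aln$id, phy, bhat, g, H, loglik = f0)
}

#' Normal-approximation log-likelihood difference
#'
#' Second-order Taylor expansion of the log-likelihood around the per-locus
#' MLE branch lengths:
#' `g'(b - bhat) + (b - bhat)' H (b - bhat) / 2`.
#'
#' @param b Proposed branch lengths, canonical order of the approximation.
#' @param approx A [blen_approx()].
#' @return Approximate `loglik(b) - loglik(bhat)`.
#' @export
approx_loglik <- function(b, approx) {
  stopifnot(inherits(approx, "blen_approx"))
  if (length(b) != length(approx$bhat))
    stop("dimension mismatch: ", length(b), " vs ", length(approx$bhat))
  d <- b - approx$bhat
  sum(approx$g * d) + 0.5 * drop(crossprod(d, approx$H %*% d))
}

#' Match a branch-length approximation to a dating tree
#'
#' Reorders branches of `approx` so they follow the canonical edge order of
#' `tt`, matching branches by the sorted tip set of their child clades.
#'
#' @param approx A [blen_approx()].
#' @param tt A `timetree` (or `phylo`) with the same tips and topology.
#' @return A reordered `blen_approx`.
#' @export
match_blen_approx <- function(approx, tt) {
  phy <- if (inherits(tt, "timetree")) tt$phy else tt
  if (!setequal(phy$tip.label, approx$tips))
    stop("tip sets differ between approximation '", approx$id,
         "' and dating tree")
  target <- edge_clades(phy)
  perm <- match(target, approx$clades)
  if (anyNA(perm))
    stop("branch mismatch: clade {", gsub("\\|", ", ",
                                          target[which(is.na(perm))[1]]),
         "} of the dating tree absent from approximation '", approx$id, "'")
  approx$clades <- approx$clades[perm]
  approx$bhat <- approx$bhat[perm]
  approx$g <- approx$g[perm]
  approx$H <- approx$H[perm, perm, drop = FALSE]
  approx$tips <- phy$tip.label
  approx
}

fmt12 <- function(x) sprintf("%.12g", x)

#' Write branch-length approximations to a BV file
#'
#' Plain-text, versioned dialect: per locus a header (id, tips, branch
#' clades), then the MLE branch lengths, the gradient, and the Hessian
#' block, all to 12 significant digits.
#'
#' @param approxes List of [blen_approx()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bv <- function(approxes, path) {
  if (inherits(approxes, "blen_approx")) approxes <- list(approxes)
  con <- file(path, "wb")
  on.exit(close(con))
  out <- c("#wgdchronos-BV v1", paste("nloci", length(approxes)))
  for (a in approxes) {
    stopifnot(inherits(a, "blen_approx"))
    B <- length(a$bhat)
    out <- c(out,
             paste("locus", a$id),
             paste("tips", paste(a$tips, collapse = "\t")),
             paste("nbranch", B),
             paste("clades", paste(a$clades, collapse = "\t")),
             paste("blens", paste(fmt12(a$bhat), collapse = "\t")),
             paste("grad", paste(fmt12(a$g), collapse = "\t")),
             "hessian",
             apply(a$H, 1, function(r) paste(fmt12(r), collapse = "\t")))
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a BV file
#'
#' @param path Path written by [write_bv()].
#' @return List of [blen_approx()] objects.
#' @export
read_bv <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "#wgdchronos-BV")) stop("not a BV file: ", path)
  nloci <- as.integer(strsplit(ln[2], " ")[[1]][2])
  i <- 3L
  out <- vector("list", nloci)
  grab <- function(line, key) {
    parts <- strsplit(line, "[ \t]")[[1]]
    if (parts[1] != key) stop("BV parse error: expected '", key,
                              "', found '", parts[1], "'")
    parts[-1]
  }
  for (l in seq_len(nloci)) {
    id <- grab(ln[i], "locus"); i <- i + 1L
    tips <- grab(ln[i], "tips"); i <- i + 1L
    B <- as.integer(grab(ln[i], "nbranch")); i <- i + 1L
    clades <- grab(ln[i], "clades"); i <- i + 1L
    bhat <- as.numeric(grab(ln[i], "blens")); i <- i + 1L
    g <- as.numeric(grab(ln[i], "grad")); i <- i + 1L
    if (ln[i] != "hessian") stop("BV parse error: expected 'hessian'")
    i <- i + 1L
    H <- matrix(NA_real_, B, B)
    for (r in seq_len(B)) {
      row <- as.numeric(strsplit(ln[i], "\t")[[1]])
      if (length(row) != B)
        stop("BV parse error: Hessian row ", r, " of locus ", id,
             " has ", length(row), " entries, expected ", B)
      H[r, ] <- row
      i <- i + 1L
    }
    if (length(bhat) != B || length(g) != B || length(clades) != B)
      stop("BV parse error: vector lengths disagree with nbranch in locus ",
           id)
    a <- structure(list(id = id, tips = tips, clades = clades,
                        bhat = bhat, g = g, H = H, loglik = NA_real_),
                   class = "blen_approx")
    asym <- max(abs(H - t(H)))
    if (asym > 1e-8) {
      warning("Hessian asymmetry ", format(asym), " in locus ", id,
              "; symmetrizing")
      a$H <- (H + t(H)) / 2
    }
    out[[l]] <- a
  }
  out
}
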