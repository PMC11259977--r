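test_that("substitution models are valid scaled reversible generators", {
  for (nm in c("Poisson", "LG", "WAG", "JTT")) {
    m <- aa_model(nm)
    expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
    expect_equal(sum(m$freqs), 1, tolerance = 1e-9)
    expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-9)
    P <- transition_matrix(m, 0.37)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
    expect_true(all(P >= 0))
    # detailed balance: pi_i P_ij = pi_j P_ji
    expect_equal(m$freqs * P, t(m$freqs * P), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  g <- aa_model("LG", gamma_k = 4, gamma_shape = 0.5)
  expect_equal(mean(g$gamma_rates), 1, tolerance = 1e-12)
  expect_error(aa_model("LG", gamma_k = 4), "gamma_shape")
})

test_that("pruning likelihood matches closed forms on two sequences", {
  m <- aa_model("Poisson")
  n <- 7L
  aln <- locus_alignment("id", c(A = strrep("A", n), B = strrep("A", n)))
  tt <- parse_newick("(A:0,B:0);")
  expect_equal(pruning_loglik(aln, tt, c(0, 0), m), n * log(1 / 20),
               tolerance = 1e-9)
  # one difference at one site, total distance d
  aln1 <- locus_alignment("id", c(A = "A", B = "R"))
  d <- 0.4
  # closed-form off-diagonal transition of the 20-state equal-rates model
  p_change_each <- (1 / 20) * (1 - exp(-20 * d / 19))
  expect_equal(pruning_loglik(aln1, tt, c(d / 2, d / 2), m),
               log((1 / 20) * p_change_each), tolerance = 1e-9)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  m <- aa_model("Poisson")
  mg <- aa_model("LG", gamma_k = 2, gamma_shape = 0.8)
  set.seed(5)
  cases <- list(
    list(nwk = "((A,B),C);", seqs = c(A = "ARN", B = "A-N", C = "RRN")),
    list(nwk = "((A,B),(C,D));", seqs = c(A = "AR", B = "AR", C = "ND",
                                          D = "N?")),
    list(nwk = "(((A,B),C),(D,E));",
         seqs = c(A = "AL", B = "AL", C = "RL", D = "KI", E = "KI")))
  for (cs in cases) {
    phy <- ape::read.tree(text = cs$nwk)
    aln <- locus_alignment("x", cs$seqs)
    b <- runif(nrow(canonical_edges(phy)), 0.02, 0.5)
    for (model in list(m, mg)) {
      expect_equal(pruning_loglik(aln, phy, b, model),
                   enumeration_loglik(aln, phy, b, model),
                   tolerance = 1e-9)
    }
  }
})

test_that("pruning agrees with an independent phylogenetic likelihood", {
  set.seed(6)
  phy <- ape::read.tree(text = "((A:0.2,B:0.1):0.15,(C:0.3,D:0.25):0.05);")
  tt <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  cfg <- clock_config("ILN", mu_r = 0.1, sigma2 = 0.05)
  aln <- simulate_locus(tt, cfg, 120, mode = "alignment",
                        model = aa_model("LG"), id = "cmp")
  b <- runif(6, 0.05, 0.4)
  mine <- pruning_loglik(aln, tt, b, aa_model("LG"))
  # phangorn as the independent oracle
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  pd <- phangorn::phyDat(mat, type = "AA")
  oracle_tree <- tt$phy
  ce <- canonical_edges(tt)
  key_mine <- apply(ce, 1, paste, collapse = "-")
  key_orig <- apply(oracle_tree$edge, 1, paste, collapse = "-")
  oracle_tree$edge.length <- b[match(key_orig, key_mine)]
  fit <- phangorn::pml(oracle_tree, pd, model = "LG")
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("likelihood is invariant under re-rooting for reversible models", {
  set.seed(7)
  tt <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  aln <- simulate_locus(tt, clock_config("ILN", mu_r = 0.1), 60,
                        mode = "alignment", id = "rr")
  m <- aa_model("Poisson")
  b <- runif(6, 0.05, 0.3)
  ll1 <- pruning_loglik(aln, tt, b, m)
  # re-root along the internal edge: same unrooted tree, new root position
  phy <- tt$phy
  phy$edge.length <- b[match(apply(phy$edge, 1, paste, collapse = "-"),
                             apply(canonical_edges(phy), 1,
                                   paste, collapse = "-"))]
  re <- ape::root(ape::unroot(phy), outgroup = "C", resolve.root = TRUE)
  b2 <- re$edge.length[match(apply(canonical_edges(re), 1, paste,
                                   collapse = "-"),
                             apply(re$edge, 1, paste, collapse = "-"))]
  ll2 <- pruning_loglik(aln, re, b2, m)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("branch-length MLE matches the pairwise closed form", {
  m <- aa_model("Poisson")
  n <- 50L; k <- 10L
  aln <- locus_alignment("two", c(
    X = strrep("A", n),
    Y = paste0(strrep("A", n - k), strrep("R", k))))
  phy <- ape::read.tree(text = "(X:1,Y:1);")
  fit <- suppressWarnings(estimate_brlens_and_hessian(aln, phy, m))
  closed <- -(19 / 20) * log(1 - (20 / 19) * (k / n))
  expect_equal(sum(fit$bhat), closed, tolerance = 1e-4)
  expect_lte(max(eigen((fit$H + t(fit$H)) / 2)$values),
             1e-4 * max(abs(eigen(fit$H)$values)))
})

test_that("branch-length MLEs recover simulated lengths within error", {
  set.seed(8)
  tt <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):0.5,(E:2,F:2):0.5);")
  cfg <- clock_config("ILN", mu_r = 0.08, sigma2 = 0.05)
  loc <- simulate_locus(tt, cfg, 1200, mode = "alignment", id = "rec")
  b_true <- attr(loc, "truth")$b
  fit <- suppressWarnings(estimate_brlens_and_hessian(loc, tt, aa_model("Poisson")))
  edge <- canonical_edges(tt)
  root <- 7L
  root_rows <- which(edge[, 1] == root)
  Hplus <- MASS::ginv(-fit$H) # pseudo-inverse: root split is flat
  se <- sqrt(pmax(diag(Hplus), 1e-12))
  inner <- setdiff(seq_len(nrow(edge)), root_rows)
  expect_true(all(abs(fit$bhat - b_true)[inner] < 3.5 * se[inner] + 0.01))
  # only the sum of the two root-adjacent branches is identifiable
  expect_lt(abs(sum(fit$bhat[root_rows]) - sum(b_true[root_rows])), 0.05)
  # second-order optimality: no meaningfully positive curvature
  ev <- eigen((fit$H + t(fit$H)) / 2)$values
  expect_lte(max(ev), 1e-3 * max(abs(ev)))
})

test_that("quadratic approximation expands around the MLE", {
  set.seed(9)
  tt <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  loc <- simulate_locus(tt, clock_config("ILN", mu_r = 0.1), 800,
                        mode = "alignment", id = "apx")
  m <- aa_model("Poisson")
  fit <- suppressWarnings(estimate_brlens_and_hessian(loc, tt, m))
  expect_equal(approx_loglik(fit$bhat, fit), 0)
  # pure quadratic is symmetric when g = 0
  fit0 <- fit; fit0$g <- rep(0, length(fit$g))
  d <- c(0.01, -0.02, 0.015, 0, 0.005, -0.01)
  expect_equal(approx_loglik(fit0$bhat + d, fit0),
               approx_loglik(fit0$bhat - d, fit0), tolerance = 1e-12)
  expect_error(approx_loglik(fit$bhat[-1], fit), "dimension")
  # tracks the exact log-likelihood within 2 SE of the MLE
  se <- sqrt(pmax(diag(MASS::ginv(-fit$H)), 1e-12))
  worst <- 0
  for (r in 1:5) {
    b <- pmax(fit$bhat + rnorm(6, 0, se), 1e-6)
    exact <- pruning_loglik(loc, tt, b, m) - fit$loglik
    worst <- max(worst, abs(approx_loglik(b, fit) - exact))
  }
  expect_lt(worst, 0.5)
})

test_that("BV files round-trip to 12 significant digits", {
  set.seed(10)
  tt <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  mk <- function(id) {
    B <- 6L
    H <- -crossprod(matrix(rnorm(B * B), B))
    blen_approx(id, tt$phy, runif(B, 0.01, 0.5), rnorm(B, 0, 1e-4), H)
  }
  approxes <- list(mk("locA"), mk("locB"))
  p <- tempfile(fileext = ".bv")
  write_bv(approxes, p)
  back <- read_bv(p)
  for (i in 1:2) {
    expect_equal(back[[i]]$bhat, approxes[[i]]$bhat, tolerance = 1e-11)
    expect_equal(back[[i]]$g, approxes[[i]]$g, tolerance = 1e-11)
    expect_equal(back[[i]]$H, approxes[[i]]$H, tolerance = 1e-11)
    expect_equal(back[[i]]$clades, approxes[[i]]$clades)
  }
  # write(read(x)) is stable
  p2 <- tempfile(fileext = ".bv")
  write_bv(back, p2)
  expect_identical(readLines(p), readLines(p2))

  # corrupt Hessian block: row count mismatch
  ln <- readLines(p)
  writeLines(ln[-12], p2)
  expect_error(suppressWarnings(read_bv(p2)), "BV parse error")

  # asymmetric Hessian triggers warning + symmetrization
  bad <- approxes[[1]]
  bad$H[1, 2] <- bad$H[1, 2] + 1e-3
  write_bv(list(bad), p2)
  expect_warning(res <- read_bv(p2), "asymmetry")
  expect_equal(res[[1]]$H, t(res[[1]]$H))
})

test_that("approximations re-match to differently numbered trees", {
  set.seed(11)
  tt <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  B <- 6L
  a <- blen_approx("x", tt$phy, runif(B, 0.05, 0.4), rep(0, B),
                   -diag(B))
  # same topology entered in a rotated order
  tt2 <- parse_newick("((C:1,D:1):1,(B:1,A:1):1);")
  m <- match_blen_approx(a, tt2)
  expect_equal(m$clades, wgdchronos:::edge_clades(tt2$phy))
  ce1 <- wgdchronos:::edge_clades(tt$phy)
  expect_equal(m$bhat, a$bhat[match(m$clades, ce1)])
  tt3 <- parse_newick("((A:1,E:1):1,(C:1,D:1):1);")
  expect_error(match_blen_approx(a, tt3), "tip sets differ")
})
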