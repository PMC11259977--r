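test_that("simulated chronograms respect order and calibrations", {
  des <- study_design()
  tt <- simulate_chronogram(des, seed = 21)
  d <- branch_durations(tt)
  expect_true(all(d > 0))
  expect_equal(tt$ages[attr(tt, "wgd_node")], des$t_wgd)
  cal <- attr(tt, "calibrations")
  for (nd in names(cal)) {
    expect_gte(tt$ages[as.integer(nd)], cal[[nd]]$t_min)
    expect_lte(tt$ages[as.integer(nd)], cal[[nd]]$t_max)
  }
  # determinism
  tt2 <- simulate_chronogram(des, seed = 21)
  expect_identical(tt$ages, tt2$ages)
})

test_that("free node ages are kernel draws (rank-matching keeps marginals)", {
  # one-duplicated-taxon design: a single free internal node
  des1 <- study_design(
    duplicated_taxa = "Danio",
    outgroup_taxa = c("Polypterus", "Amia"),
    species_newick = "((Polypterus,Amia),Danio);",
    calibration_table = data.frame(
      clade_label = "root", taxonA = "Polypterus", taxonB = "Danio_1",
      min_Ma = 365, max_Ma = 425, stringsAsFactors = FALSE),
    t_wgd = 2.77)
  set.seed(22)
  draws <- replicate(1500, {
    tt <- simulate_chronogram(des1, root_age = 4)
    tt$ages[ape::getMRCA(tt$phy, c("Polypterus", "Amia"))]
  })
  # (Polypterus,Amia) is unconstrained: its marginal is the bare kernel
  ks <- suppressWarnings(stats::ks.test(draws, function(q)
    wgdchronos:::bd_kernel_cdf(q, 4, des1$bd)))
  expect_lt(unname(ks$statistic), 0.04)
})

test_that("alignment simulation matches transition probabilities", {
  # two-leaf tree at known distance: fraction of identical sites
  tt <- parse_newick("(A:1,B:1);")
  cfg <- clock_config("ILN", mu_r = 0.1, sigma2 = 0) # strict clock: b known
  set.seed(23)
  aln <- simulate_locus(tt, cfg, 3e4, mode = "alignment", id = "p")
  d <- 2 * 0.1 * 1 # total path length between the tips
  p_same_exp <- 1 / 20 + (19 / 20) * exp(-20 * d / 19)
  a <- strsplit(aln$seqs[["A"]], "")[[1]]
  b <- strsplit(aln$seqs[["B"]], "")[[1]]
  p_hat <- mean(a == b)
  se <- sqrt(p_same_exp * (1 - p_same_exp) / 3e4)
  expect_lt(abs(p_hat - p_same_exp), 4 * se)
})

test_that("branch-length surrogates degenerate to the truth at zero noise", {
  des <- small_design()
  tt <- simulate_chronogram(des, seed = 24)
  loc <- simulate_locus(tt, clock_config("ILN"), 500,
                        mode = "brlen_approx", noise_scale = 0, id = "z")
  expect_equal(loc$bhat, attr(loc, "truth")$b, tolerance = 1e-12)
  expect_equal(loc$g, rep(0, length(loc$g)))
  expect_true(all(diag(loc$H) < 0))
  expect_error(simulate_locus(tt, clock_config("ILN"), 0,
                              mode = "brlen_approx"), "n_sites")
})

test_that("rediploidization simulator has the stated limits and mean", {
  p0 <- wgd_sim_params(t_wgd = 2.8, t_r = 2.0, c_conv = 0)
  r0 <- simulate_wgd_rediploidization(p0, 500, seed = 25)
  expect_true(all(r0$ages == 2.8)) # no homogenization

  pbig <- wgd_sim_params(2.8, 2.0, c_conv = 500)
  rbig <- simulate_wgd_rediploidization(pbig, 2000, seed = 26)
  expect_lt(mean(rbig$ages) - 2.0, 0.01) # instant homogenization to t_r

  expect_error(wgd_sim_params(2.0, 2.8, 1), "t_r")

  # mean age vs a brute-force Monte-Carlo oracle of the event process
  pc <- wgd_sim_params(2.8, 2.0, c_conv = 1)
  rc <- simulate_wgd_rediploidization(pc, 4e4, seed = 27)
  set.seed(28)
  delta <- 0.8
  oracle <- replicate(4e4, {
    k <- rpois(1, 1 * delta)
    if (k == 0) 2.8 else 2.0 + min(runif(k, 0, delta))
  })
  expect_lt(abs(mean(rc$ages) - mean(oracle)),
            4 * sd(oracle) / sqrt(4e4) * 2)
  # sequence divergence tracks the per-site ages
  a <- strsplit(rc$seq_a, "")[[1]]
  b <- strsplit(rc$seq_b, "")[[1]]
  p_same <- mean(a == b)
  d_exp <- 2 * pc$rate * mean(rc$ages)
  p_exp <- mean(1 / 20 + (19 / 20) * exp(-20 * (2 * pc$rate * rc$ages) / 19))
  expect_lt(abs(p_same - p_exp), 0.02)
})

test_that("the default fixture mirrors the intended study shape", {
  fx <- default_fixture()
  expect_equal(length(fx$loci), 30L)
  n_seqs <- sum(vapply(fx$loci, function(l) length(l$seqs), integer(1)))
  expect_equal(n_seqs, 537L) # 30 x 18 - 3
  roster <- fx$chronogram$phy$tip.label
  complete <- vapply(fx$loci, function(l)
    all(roster %in% names(l$seqs)), logical(1))
  expect_equal(sum(complete), 27L)
  expect_true(all(vapply(fx$loci, function(l) l$n_sites, integer(1)) >= 100))
  # files exist and screen passes on the emitted gene trees
  expect_true(file.exists(file.path(fx$dir, "calibrations.tsv")))
  gt <- parse_newick(readLines(file.path(fx$dir, "gene_trees",
                                         "locus_01.nwk")))
  dup <- fish_duplicated()
  expect_true(screen_orthogroup(gt, dup)$pass)
  # truth file round-trips through the written tree
  tr <- read.delim(file.path(fx$dir, "truth_nodes.tsv"))
  back <- parse_newick(readLines(file.path(fx$dir, "dated_tree.nwk")))
  expect_equal(back$ages[tr$node] * 100, tr$age_Ma, tolerance = 1e-4)
})

test_that("fixture regeneration with the same seed is byte-identical", {
  des <- small_design(n_loci = 3L, len_mean = 120)
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture(des, d1, seed = 5)
  make_fixture(des, d2, seed = 5)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  d3 <- file.path(tempdir(), "fxc")
  unlink(d3, recursive = TRUE)
  make_fixture(des, d3, seed = 6)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "dated_tree.nwk"))),
                         unname(tools::md5sum(file.path(d3, "dated_tree.nwk")))))
})
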