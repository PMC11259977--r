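#' Synthetic study design
#'
#' Defaults emulate the sampling design of a teleost 3R dating study:
#' 12 ray-finned fish (6 teleosts contributing an ohnologue pair each, 6
#' non-teleost actinopterygian outgroups contributing one gene each, so 18
#' expected sequences per locus), 30 loci with lengths of at least 100
#' columns, 3 genes missing across 3 loci (537 sequences, 27 complete
#' loci), a WGD age in the early Permian, and soft-bounded calibrations on
#' the root, Neopterygii and both mirrored crown-teleost nodes.
#'
#' @param duplicated_taxa Taxa of the WGD clade (2 copies each).
#' @param outgroup_taxa Non-duplicated taxa (1 gene each).
#' @param species_newick Species-tree topology over all 12 taxa.
#' @param copy_suffixes Ohnologue copy suffixes.
#' @param n_loci Number of loci.
#' @param len_min,len_mean Minimum and mean alignment length (columns).
#' @param n_missing_genes Genes deleted, one per affected locus.
#' @param t_wgd True WGD age (100 Myr).
#' @param clock_model,mu_r,sigma2 Relaxed-clock generating model.
#' @param subst_model Substitution model name for sequence simulation.
#' @param bd Birth-death prior used as the node-age generator.
#' @param hyper Hyperpriors from which per-locus `mu`/`sigma2` are drawn.
#' @param calibration_table Data frame in [read_calibration_table()] layout.
#' @param max_tries Rejection-sampling cap for constrained chronograms.
#' @return An object of class `study_design`.
#' @export
study_design <- function(
    duplicated_taxa = c("Scleropages", "Elops", "Danio", "Esox",
                        "Gasterosteus", "Takifugu"),
    outgroup_taxa = c("Polypterus", "Erpetoichthys", "Acipenser",
                      "Polyodon", "Lepisosteus", "Amia"),
    species_newick = paste0(
      "((Polypterus,Erpetoichthys),((Acipenser,Polyodon),((Lepisosteus,",
      "Amia),(Scleropages,(Elops,(Danio,(Esox,(Gasterosteus,",
      "Takifugu))))))));"),
    copy_suffixes = c("_1", "_2"),
    n_loci = 30L, len_min = 100L, len_mean = 576, n_missing_genes = 3L,
    t_wgd = 2.77,
    clock_model = "ILN", mu_r = 0.05, sigma2 = 0.1,
    subst_model = "Poisson",
    bd = birth_death_prior(1, 1, 0.1),
    hyper = rate_hyperpriors(),
    calibration_table = NULL,
    max_tries = 50000L) {
  if (is.null(calibration_table))
    calibration_table <- data.frame(
      clade_label = c("crown_Actinopterygii", "Neopterygii",
                      "crown_Teleostei_1", "crown_Teleostei_2"),
      taxonA = c("Polypterus", "Lepisosteus",
                 paste0("Scleropages", copy_suffixes[1]),
                 paste0("Scleropages", copy_suffixes[2])),
      taxonB = c("Amia", paste0("Danio", copy_suffixes[1]),
                 paste0("Takifugu", copy_suffixes[1]),
                 paste0("Takifugu", copy_suffixes[2])),
      min_Ma = c(365, 300, 226, 226),
      max_Ma = c(425, 360, 310, 310),
      stringsAsFactors = FALSE)
  structure(list(duplicated_taxa = duplicated_taxa,
                 outgroup_taxa = outgroup_taxa,
                 species_newick = species_newick,
                 copy_suffixes = copy_suffixes,
                 n_loci = as.integer(n_loci), len_min = as.integer(len_min),
                 len_mean = len_mean,
                 n_missing_genes = as.integer(n_missing_genes),
                 t_wgd = t_wgd, clock_model = clock_model, mu_r = mu_r,
                 sigma2 = sigma2, subst_model = subst_model, bd = bd,
                 hyper = hyper, calibration_table = calibration_table,
                 max_tries = as.integer(max_tries)),
            class = "study_design")
}

# Count, per node, the free (unpinned, internal, non-tip) nodes in its
# subtree (itself included).
free_counts <- function(idx, pinned_nodes) {
  cnt <- integer(idx$n_all)
  intn <- (idx$ntip + 1L):idx$n_all
  cnt[intn] <- ifelse(intn %in% pinned_nodes, 0L, 1L)
  for (k in seq_len(nrow(idx$edge)))
    cnt[idx$edge[k, 1]] <- cnt[idx$edge[k, 1]] + cnt[idx$edge[k, 2]]
  cnt
}

# Rank-matching allocation of a pool of iid kernel ages onto the topology:
# each free node takes the maximum of the values allotted to its subtree;
# the remainder is split at random between the child subtrees. Pinned nodes
# keep their fixed ages and bound the values that may enter their subtree.
allocate_ages <- function(idx, pool, pinned) {
  ages <- numeric(idx$n_all)
  pinned_nodes <- as.integer(names(pinned))
  cnt <- free_counts(idx, pinned_nodes)
  ok <- TRUE
  assign_node <- function(node, vals) {
    if (!ok) return(invisible())
    if (node <= idx$ntip) return(invisible())
    if (node %in% pinned_nodes) {
      a <- pinned[[as.character(node)]]
      if (length(vals) && max(vals) >= a) { ok <<- FALSE; return(invisible()) }
    } else {
      i <- which.max(vals)
      a <- vals[i]
      vals <- vals[-i]
    }
    ages[node] <<- a
    kids <- idx$children[[node]]
    n1 <- cnt[kids[1]]
    pick <- if (n1 > 0 && length(vals) > 0)
      sample(seq_along(vals), n1) else integer(0)
    assign_node(kids[1], vals[pick])
    assign_node(kids[2], if (length(pick)) vals[-pick] else vals)
    invisible()
  }
  assign_node(idx$root, pool)
  if (!ok) return(NULL)
  ages
}

#' Simulate a chronogram under the study design
#'
#' Draws the root age from its calibration, the remaining internal ages iid
#' from the birth-death kernel conditional on the root age, and
#' order-constrains them onto the duplicated topology by rank-matching. The
#' WGD node is pinned at the design's `t_wgd`; draws violating the age
#' order or a calibration window are rejected and resampled.
#'
#' @param design A [study_design()].
#' @param seed Optional integer seed.
#' @param root_age Optional fixed root age (100 Myr).
#' @return A dated `timetree` with attributes `wgd_node`, `calibrations`
#'   and `design`.
#' @export
simulate_chronogram <- function(design, seed = NULL, root_age = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sp <- parse_newick(design$species_newick)
  dup <- build_duplicated_topology(sp, design$duplicated_taxa,
                                   design$copy_suffixes)
  idx <- tree_indexing(dup$phy)
  cal <- calibrations_for_tree(dup, design$calibration_table)
  if (is.null(cal[[as.character(idx$root)]]))
    stop("the design's calibration table must calibrate the root")
  wgd <- attr(dup, "wgd_node")
  cal_nodes <- as.integer(names(cal))
  for (try in seq_len(design$max_tries)) {
    t_root <- if (!is.null(root_age)) root_age
      else rcalibration(1, cal[[as.character(idx$root)]])
    if (t_root <= design$t_wgd) next
    pinned <- stats::setNames(list(t_root, design$t_wgd),
                              c(idx$root, wgd))
    n_free <- dup$phy$Nnode - length(pinned)
    pool <- rbd_kernel(n_free, t_root, design$bd)
    ages <- allocate_ages(idx, pool, pinned)
    if (is.null(ages)) next
    bad <- FALSE
    for (n in cal_nodes) {
      cl <- cal[[as.character(n)]]
      if (ages[n] < cl$t_min || ages[n] > cl$t_max) { bad <- TRUE; break }
    }
    if (bad) next
    d <- ages[idx$edge[, 1]] - ages[idx$edge[, 2]]
    if (any(d <= 0)) next
    out <- dup
    out$ages <- ages
    validate_ages(out)
    attr(out, "calibrations") <- cal
    attr(out, "design") <- design
    return(out)
  }
  stop("could not simulate a chronogram satisfying the calibrations in ",
       design$max_tries, " tries")
}

# Diagonal per-branch Fisher information for branch length b under the
# 20-state equal-rates model with n sites: I(b) = n p'(b)^2 / (p(1-p)),
# p(b) = (19/20)(1 - exp(-20 b / 19)).
poisson_branch_info <- function(b, n_sites) {
  b <- pmax(b, 1e-8)
  e <- exp(-20 * b / 19)
  p <- (19 / 20) * (1 - e)
  n_sites * e^2 / (p * (1 - p))
}

#' Simulate one locus on a dated tree
#'
#' Rates are drawn from the configured relaxed clock and combined with
#' branch durations into true branch lengths. In `alignment` mode,
#' sequences are evolved site-wise down the tree under the substitution
#' model. In `brlen_approx` mode the locus is returned directly as a
#' branch-length approximation: the MLE surrogate is the true length plus
#' curvature-consistent noise (`bhat = b + e`, `e ~ N(0, I(b)^-1)` with the
#' diagonal per-branch Fisher information of the equal-rates model at
#' `n_sites` sites), zero gradient, and `H = -diag(I(bhat))`.
#'
#' @param tt A dated `timetree`.
#' @param cfg A [clock_config()].
#' @param n_sites Alignment length in columns.
#' @param mode `"alignment"` or `"brlen_approx"`.
#' @param model An [aa_model()] (alignment mode).
#' @param noise_scale Scale factor on the `brlen_approx` noise (0 returns
#'   `bhat = b` exactly).
#' @param id Locus id.
#' @param seed Optional integer seed.
#' @return A `locus_alignment` or [blen_approx()], with attribute `truth`
#'   (rates and true branch lengths).
#' @export
simulate_locus <- function(tt, cfg, n_sites, mode = c("alignment",
                                                      "brlen_approx"),
                           model = aa_model("Poisson"), noise_scale = 1,
                           id = "locus", seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tt, "timetree"), inherits(cfg, "clock_config"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rates <- simulate_branch_rates(tt, cfg)
  b <- expected_branch_lengths(tt, rates, cfg)
  truth <- list(rates = rates, b = b)
  if (mode == "brlen_approx") {
    info <- poisson_branch_info(b, n_sites)
    bhat <- b + noise_scale * rnorm(length(b)) / sqrt(info)
    bhat <- pmax(bhat, 1e-6)
    # curvature evaluated at the true lengths keeps the surrogate
    # likelihood consistent with the generating model
    H <- -diag(info, length(b))
    out <- blen_approx(id, tt$phy, bhat, rep(0, length(bhat)), H)
    attr(out, "truth") <- truth
    return(out)
  }
  phy <- tt$phy
  post <- ape::reorder.phylo(phy, "postorder")
  edge <- post$edge
  n_all <- ape::Ntip(phy) + phy$Nnode
  states <- matrix(0L, n_all, n_sites)
  root <- ape::Ntip(phy) + 1L
  states[root, ] <- sample.int(20, n_sites, replace = TRUE,
                               prob = model$freqs)
  site_rate <- if (model$gamma_k > 1L)
    model$gamma_rates[sample.int(model$gamma_k, n_sites, replace = TRUE)]
  else rep(1, n_sites)
  for (k in rev(seq_len(nrow(edge)))) { # parents before children
    p <- edge[k, 1]; ch <- edge[k, 2]
    if (model$gamma_k > 1L) {
      for (rk in seq_len(model$gamma_k)) {
        sel <- site_rate == model$gamma_rates[rk]
        if (!any(sel)) next
        P <- transition_matrix(model, b[k] * model$gamma_rates[rk])
        for (s in unique(states[p, sel])) {
          i <- which(sel & states[p, ] == s)
          states[ch, i] <- sample.int(20, length(i), replace = TRUE,
                                      prob = P[s, ])
        }
      }
    } else {
      P <- transition_matrix(model, b[k])
      for (s in unique(states[p, ])) {
        i <- which(states[p, ] == s)
        states[ch, i] <- sample.int(20, length(i), replace = TRUE,
                                    prob = P[s, ])
      }
    }
  }
  seqs <- apply(states[seq_len(ape::Ntip(phy)), , drop = FALSE], 1,
                function(r) paste(AA_ORDER[r], collapse = ""))
  names(seqs) <- phy$tip.label
  out <- locus_alignment(id, seqs)
  attr(out, "truth") <- truth
  out
}

#' Delayed-rediploidization parameters
#'
#' @param t_wgd WGD age (100 Myr).
#' @param t_r Rediploidization age (100 Myr), `t_r <= t_wgd`.
#' @param c_conv Per-site conversion/homogenization rate during the
#'   tetrasomic phase (events per site per 100 Myr).
#' @param rate Substitution rate (substitutions/site/100 Myr).
#' @return An object of class `wgd_sim_params`.
#' @export
wgd_sim_params <- function(t_wgd, t_r, c_conv, rate = 0.05) {
  if (t_r > t_wgd) stop("t_r must not exceed t_wgd")
  stopifnot(t_r >= 0, c_conv >= 0, rate > 0)
  structure(list(t_wgd = t_wgd, t_r = t_r, c_conv = c_conv, rate = rate),
            class = "wgd_sim_params")
}

#' Simulate ohnologue divergence under delayed rediploidization
#'
#' During the tetrasomic phase `(t_r, t_wgd]` gene conversion arrives per
#' site at rate `c_conv` and homogenizes the two copies; a site's effective
#' divergence age is the age of its most recent conversion event, or
#' `t_wgd` if none occurred (equivalently, `t_r` plus a truncated
#' exponential residual). The two copies then diverge independently from
#' that age under the equal-rates substitution model.
#'
#' @param params A [wgd_sim_params()].
#' @param n_sites Number of sites.
#' @param seed Optional integer seed.
#' @return List with `ages` (per-site divergence ages, 100 Myr), `seq_a`,
#'   `seq_b` (amino-acid strings) and `params`.
#' @export
simulate_wgd_rediploidization <- function(params, n_sites, seed = NULL) {
  stopifnot(inherits(params, "wgd_sim_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  delta <- params$t_wgd - params$t_r
  n_sites <- as.integer(n_sites)
  if (params$c_conv == 0 || delta == 0) {
    ages <- rep(params$t_wgd, n_sites)
  } else {
    none <- runif(n_sites) < exp(-params$c_conv * delta)
    resid <- -log1p(-runif(n_sites) * (1 - exp(-params$c_conv * delta))) /
      params$c_conv
    ages <- ifelse(none, params$t_wgd, params$t_r + resid)
  }
  anc <- sample.int(20, n_sites, replace = TRUE)
  evolve <- function(anc, d) {
    keep <- runif(n_sites) < exp(-20 * d / 19)
    ifelse(keep, anc, sample.int(20, n_sites, replace = TRUE))
  }
  d_site <- params$rate * ages
  list(ages = ages,
       seq_a = paste(AA_ORDER[evolve(anc, d_site)], collapse = ""),
       seq_b = paste(AA_ORDER[evolve(anc, d_site)], collapse = ""),
       params = params)
}

write_lines_bin <- function(lines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Generate a complete on-disk synthetic study
#'
#' Writes, under `dir`: the species tree and the dated duplicated tree
#' (Newick), the calibration table (TSV), per-locus alignments (FASTA,
#' `loci/`), per-locus gene trees pruned of missing genes (`gene_trees/`),
#' a study description (`design.tsv`), and truth files (node ages in Ma;
#' per-locus `mu`/`sigma2`). The default design yields 30 loci and 537
#' sequences with 27 complete loci. Regeneration with the same seed is
#' byte-identical.
#'
#' @param design A [study_design()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the chronogram, loci, truth tables and
#'   file paths.
#' @export
make_fixture <- function(design, dir, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "loci"), showWarnings = FALSE)
  dir.create(file.path(dir, "gene_trees"), showWarnings = FALSE)
  set.seed(as.integer(seed))
  tt <- simulate_chronogram(design)
  phy <- tt$phy
  roster <- phy$tip.label

  lens <- design$len_min +
    rnbinom(design$n_loci, size = 4,
            mu = max(design$len_mean - design$len_min, 1))
  mu_l <- rgamma(design$n_loci, design$hyper$alpha_r,
                 rate = design$hyper$beta_r)
  s2_l <- rgamma(design$n_loci, design$hyper$alpha_s,
                 rate = design$hyper$beta_s)
  model <- aa_model(design$subst_model)

  # genes to delete: one per affected locus, never the only outgroup
  drop_loci <- sort(sample.int(design$n_loci, design$n_missing_genes))
  drop_gene <- vapply(drop_loci, function(l)
    sample(roster, 1), character(1))

  loci <- vector("list", design$n_loci)
  for (l in seq_len(design$n_loci)) {
    cfg <- clock_config(design$clock_model, mu_r = mu_l[l], sigma2 = s2_l[l])
    id <- sprintf("locus_%02d", l)
    aln <- simulate_locus(tt, cfg, lens[l], mode = "alignment",
                          model = model, id = id)
    if (l %in% drop_loci) {
      gene <- drop_gene[match(l, drop_loci)]
      og_left <- setdiff(intersect(names(aln$seqs), design$outgroup_taxa),
                         gene)
      if (length(og_left) >= 1)
        aln <- locus_alignment(id, aln$seqs[names(aln$seqs) != gene])
    }
    loci[[l]] <- aln
    write_locus_fasta(aln, file.path(dir, "loci", paste0(id, ".fasta")))
    gt <- ape::drop.tip(phy, setdiff(roster, names(aln$seqs)))
    gt$edge.length <- NULL
    gt$node.label <- NULL
    write_lines_bin(ape::write.tree(gt),
                    file.path(dir, "gene_trees", paste0(id, ".nwk")))
  }

  write_lines_bin(design$species_newick, file.path(dir, "species_tree.nwk"))
  write_lines_bin(write_newick(tt), file.path(dir, "dated_tree.nwk"))
  ctab <- design$calibration_table
  write_lines_bin(c(paste(names(ctab), collapse = "\t"),
                    apply(ctab, 1, paste, collapse = "\t")),
                  file.path(dir, "calibrations.tsv"))
  write_lines_bin(c(
    paste0("duplicated_taxa\t", paste(design$duplicated_taxa, collapse = ",")),
    paste0("outgroup_taxa\t", paste(design$outgroup_taxa, collapse = ",")),
    paste0("copy_suffixes\t", paste(design$copy_suffixes, collapse = ",")),
    paste0("subst_model\t", design$subst_model),
    paste0("seed\t", seed)),
    file.path(dir, "design.tsv"))

  idx <- tree_indexing(phy)
  intn <- idx$root:idx$n_all
  labs <- phy$node.label
  truth_nodes <- data.frame(node = intn,
                            label = labs,
                            age_Ma = unit_to_ma(tt$ages[intn]))
  write_lines_bin(c("node\tlabel\tage_Ma",
                    sprintf("%d\t%s\t%.6f", truth_nodes$node,
                            truth_nodes$label, truth_nodes$age_Ma)),
                  file.path(dir, "truth_nodes.tsv"))
  write_lines_bin(c("locus\tmu\tsigma2\tn_sites",
                    sprintf("locus_%02d\t%.10g\t%.10g\t%d",
                            seq_len(design$n_loci), mu_l, s2_l,
                            vapply(loci, function(x) x$n_sites, integer(1)))),
                  file.path(dir, "truth_loci.tsv"))

  invisible(list(chronogram = tt, loci = loci,
                 truth_nodes = truth_nodes,
                 truth_loci = data.frame(locus = seq_len(design$n_loci),
                                         mu = mu_l, sigma2 = s2_l),
                 dir = dir))
}
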