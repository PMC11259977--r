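# Shared fixtures and independent oracles, built in code at test time.

fish_species_tree <- function() {
  parse_newick(study_design()$species_newick)
}

fish_duplicated <- function() {
  build_duplicated_topology(fish_species_tree(),
                            study_design()$duplicated_taxa)
}

# Reduced 3+3-taxon design for fast end-to-end runs.
small_design <- function(n_loci = 6L, len_mean = 150, n_missing = 1L) {
  ctab <- data.frame(
    clade_label = c("root", "crown_dup_1", "crown_dup_2"),
    taxonA = c("Bichir", "Zebrafish_1", "Zebrafish_2"),
    taxonB = c("Gar", "Fugu_1", "Fugu_2"),
    min_Ma = c(365, 226, 226),
    max_Ma = c(425, 310, 310),
    stringsAsFactors = FALSE)
  study_design(
    duplicated_taxa = c("Zebrafish", "Pike", "Fugu"),
    outgroup_taxa = c("Bichir", "Sturgeon", "Gar"),
    species_newick =
      "((Bichir,Sturgeon),(Gar,(Zebrafish,(Pike,Fugu))));",
    n_loci = n_loci, len_mean = len_mean, n_missing_genes = n_missing,
    calibration_table = ctab)
}

# Exhaustive-enumeration likelihood oracle: sums over all internal-state
# assignments; independent of the pruning implementation.
enumeration_loglik <- function(aln, phy, b, model) {
  edge <- canonical_edges(phy)
  ntip <- ape::Ntip(phy)
  nint <- phy$Nnode
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  enc <- vapply(aln$seqs[phy$tip.label], function(s) {
    i <- match(strsplit(s, "")[[1]], aa)
    i[is.na(i)] <- 0L
    i
  }, integer(aln$n_sites))
  enc <- matrix(enc, nrow = aln$n_sites)
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  site_lik <- matrix(0, aln$n_sites, model$gamma_k)
  for (cat in seq_len(model$gamma_k)) {
    Plist <- lapply(b * model$gamma_rates[cat],
                    function(d) transition_matrix(model, d))
    for (site in seq_len(aln$n_sites)) {
      lik <- 0
      for (gi in seq_len(nrow(grid))) {
        st <- c(enc[site, ], grid[gi, ])
        pr <- unname(model$freqs[st[ntip + 1L]])
        for (k in seq_len(nrow(edge))) {
          ch_state <- st[edge[k, 2]]
          if (ch_state == 0L) next # missing tip: sums to 1
          pr <- pr * Plist[[k]][st[edge[k, 1]], ch_state]
        }
        lik <- lik + pr
      }
      site_lik[site, cat] <- lik
    }
  }
  sum(log(rowMeans(site_lik)))
}

# cached default-design fixture shared across test files
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "wgdchronos-default-fixture")
    .fixture_cache$fx <- make_fixture(study_design(), dir, seed = 2024L)
  }
  .fixture_cache$fx
}
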